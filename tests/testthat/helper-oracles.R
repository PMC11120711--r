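# Independent oracles and small fixture builders used across the suite.

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (probability-mass rule, relative tolerance as in
# mainstream software).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by full enumeration of label assignments
# (no-tie samples only).
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mid <- na * (n - na) / 2
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(i) sum(rk[i]) - na * (na + 1) / 2)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# Numerically truncated-normal mean and sd (truncation from below at `floor`)
truncnorm_moments <- function(mean, sd, floor) {
  a <- (floor - mean) / sd
  lambda <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  mu <- mean + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  c(mean = mu, sd = sqrt(v))
}

# Grid-search crossing of the two truncated-normal densities weighted by
# class size (oracle for the Youden-optimal threshold).
density_crossing_threshold <- function(n_pos = 24, m_pos = 967, s_pos = 145,
                                       n_neg = 30, m_neg = 751, s_neg = 92,
                                       floor = 520) {
  f <- function(x, m, s)
    stats::dnorm(x, m, s) / stats::pnorm((floor - m) / s, lower.tail = FALSE)
  grid <- seq(m_neg, m_pos, by = 0.5)
  d <- n_pos * f(grid, m_pos, s_pos) - n_neg * f(grid, m_neg, s_neg)
  grid[which(sign(d[-1]) != sign(d[-length(d)]))[1]]
}

# Half-up rounding (the convention of the printed percentages)
round_half_up <- function(x, digits = 0) floor(x * 10^digits + 0.5) / 10^digits

# Small fast system / phantom fixtures
test_system <- function(...) system_config(...)

uniform_pair <- function(seed, modulus_kpa = 200, pressure_step_kpa = 1,
                         noiseless = TRUE, lateral_mm = 0.5, depth_mm = 0.6) {
  sys <- test_system()
  ph <- build_phantom(lateral_extent_mm = lateral_mm, depth_extent_mm = depth_mm,
                      silicone_thickness_um = 0,
                      tissue_modulus_kpa = modulus_kpa,
                      seed = seed, system = sys)
  se <- simulate_compression_series(ph, sys, c(0, pressure_step_kpa),
                                    seed = seed, noiseless = noiseless)
  list(system = sys, phantom = ph, series = se,
       pdm = interframe_phase(se$frames[[1]], se$frames[[2]]),
       true_strain = pressure_step_kpa / modulus_kpa)
}

# Synthetic strain map object for unit tests that bypass the estimator
make_strain_map <- function(values, valid = TRUE, window = c(8L, 8L),
                            frame_pair = c(1L, 2L)) {
  structure(list(values = values,
                 valid_mask = matrix(valid, nrow(values), ncol(values)),
                 coherence = matrix(1, nrow(values), ncol(values)),
                 window = window, frame_pair = frame_pair),
            class = "oce_strain")
}

make_stiffness_map <- function(values, threshold = 520) {
  structure(list(values = values,
                 cancer_mask = values > threshold,
                 reference_mask = matrix(FALSE, nrow(values), ncol(values)),
                 valid_mask = matrix(TRUE, nrow(values), ncol(values)),
                 flagged = matrix(FALSE, nrow(values), ncol(values)),
                 standardization_pressure_kpa = 4,
                 source_frame_pair = c(1L, 2L),
                 calibration = calibration_config()),
            class = "oce_stiffness")
}
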