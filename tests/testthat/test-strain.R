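phase_ramp_pdm <- function(slope, n_z = 120, n_x = 40, mag = 1) {
  z <- matrix(seq_len(n_z) - 1, n_z, n_x)
  structure(list(values = mag * exp(1i * slope * z),
                 frame_pair = c(1L, 2L)),
            class = "oce_phasediff")
}

test_that("interframe phase of identity and globally shifted pairs", {
  set.seed(1)
  a <- matrix(complex(real = rnorm(600), imaginary = rnorm(600)), 30, 20)
  expect_true(all(Arg(interframe_phase(a, a)$values) == 0))
  b <- a * exp(complex(imaginary = 0.5))
  expect_equal(max(abs(Arg(interframe_phase(a, b)$values) - 0.5)), 0,
               tolerance = 1e-12)
  expect_error(interframe_phase(a, a[, 1:10]), "shape")
})

test_that("vector strain inverts a synthetic phase ramp exactly", {
  sys <- test_system()
  s <- vector_strain(phase_ramp_pdm(0.02), c(8, 8), sys)
  expected <- 0.02 * 1.31 / (4 * pi * 1.4 * 5)
  expect_equal(expected, 2.98e-4, tolerance = 1e-2)
  expect_equal(max(abs(s$values - expected)), 0, tolerance = 1e-10)
  # zero-phase map gives exactly zero strain
  s0 <- vector_strain(phase_ramp_pdm(0), c(8, 8), sys)
  expect_true(all(s0$values == 0))
  expect_error(vector_strain(phase_ramp_pdm(0.02, n_z = 6, n_x = 6),
                             c(10, 10), sys), "window")
})

test_that("strain recovery is wrap tolerant on steep ramps", {
  sys <- test_system()
  # total phase over the map spans many multiples of 2 pi
  slope <- 0.6
  s <- vector_strain(phase_ramp_pdm(slope), c(8, 8), sys)
  expected <- slope * 1.31 / (4 * pi * 1.4 * 5)
  expect_equal(max(abs(s$values - expected)), 0, tolerance = 1e-10)
})

test_that("noiseless speckle pair recovers uniform strain pixelwise", {
  fracs <- vapply(1:3, function(seed) {
    u <- uniform_pair(seed, noiseless = TRUE)
    s <- vector_strain(u$pdm, c(20, 20), u$system)
    err <- abs(s$values[s$valid_mask] / u$true_strain - 1)
    mean(err <= 0.05)
  }, numeric(1))
  expect_gte(mean(fracs), 0.95)
})

test_that("strain bias at SNR 25 dB stays below 2 percent of the true strain", {
  bias <- vapply(1:5, function(seed) {
    u <- uniform_pair(seed, noiseless = FALSE)
    s <- vector_strain(u$pdm, c(8, 8), u$system)
    mean(s$values[s$valid_mask]) / u$true_strain - 1
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.02)
  expect_lt(max(abs(bias)), 0.02)
})

test_that("recovered strain is linear in the applied strain", {
  sys <- test_system()
  ph <- build_phantom(lateral_extent_mm = 0.5, depth_extent_mm = 0.6,
                      silicone_thickness_um = 0, tissue_modulus_kpa = 400,
                      seed = 9, system = sys)
  mean_strain <- function(step) {
    se <- simulate_compression_series(ph, sys, c(0, step), seed = 9,
                                      noiseless = TRUE)
    s <- vector_strain(interframe_phase(se$frames[[1]], se$frames[[2]]),
                       c(8, 8), sys)
    mean(s$values[s$valid_mask])
  }
  s1 <- mean_strain(1); s2 <- mean_strain(2)
  expect_equal(s2 / s1, 2, tolerance = 0.05)
})

test_that("strain variance is non-increasing in window area on noisy input", {
  vars <- sapply(1:20, function(seed) {
    u <- uniform_pair(seed, noiseless = FALSE)
    vapply(list(c(4, 4), c(8, 8), c(16, 16)), function(w) {
      s <- vector_strain(u$pdm, w, u$system)
      stats::var(as.vector(s$values[s$valid_mask]))
    }, numeric(1))
  })
  avg <- rowMeans(vars)
  expect_true(all(diff(avg) <= 0))
})

test_that("cumulative strain is the running sum of interframe strains", {
  sys <- test_system()
  ph <- build_phantom(lateral_extent_mm = 0.4, depth_extent_mm = 0.5,
                      silicone_thickness_um = 0, tissue_modulus_kpa = 300,
                      seed = 10, system = sys)
  se <- simulate_compression_series(ph, sys, c(0, 1, 2, 3), seed = 10,
                                    noiseless = TRUE)
  ss <- accumulate_strain(se, c(8, 8), sys)
  expect_length(ss$cumulative, 3)
  expect_equal(ss$cumulative[[2]]$values,
               ss$incremental[[1]]$values + ss$incremental[[2]]$values,
               tolerance = 1e-12)
  expect_equal(ss$cumulative[[3]]$values,
               Reduce(`+`, lapply(ss$incremental, `[[`, "values")),
               tolerance = 1e-12)

  # identical frames: all cumulative maps are exactly zero
  se0 <- simulate_compression_series(ph, sys, c(0, 0, 0), seed = 10,
                                     noiseless = TRUE)
  ss0 <- accumulate_strain(se0, c(8, 8), sys)
  expect_true(all(vapply(ss0$cumulative,
                         function(s) all(s$values == 0), logical(1))))
  expect_error(accumulate_strain(list(frames = se$frames[1])), "frames")
})

test_that("cumulative strain tracks ground truth through a sweep", {
  sys <- test_system()
  ph <- build_phantom(lateral_extent_mm = 0.5, depth_extent_mm = 0.6,
                      silicone_thickness_um = 0, tissue_modulus_kpa = 500,
                      seed = 11, system = sys)
  se <- simulate_compression_series(ph, sys, seq(0, 5, length.out = 11),
                                    seed = 11, noiseless = TRUE)
  ss <- accumulate_strain(se, c(8, 8), sys)
  for (k in c(3, 6, 10)) {
    truth <- se$pressures[k + 1] / 500
    got <- stats::median(ss$cumulative[[k]]$values[ss$cumulative[[k]]$valid_mask])
    expect_equal(got, truth, tolerance = 0.05)
  }
})
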