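# Sliding-window box sum with partial (renormalized) windows at the edges.
# Works for complex matrices; window = c(axial_px, lateral_px).
boxsum <- function(m, window) {
  wz <- window[1]; wx <- window[2]
  n_z <- nrow(m); n_x <- ncol(m)
  cs <- function(a) apply(a, 2, cumsum)
  pad <- function(a) rbind(0, a)
  # axial pass
  C <- pad(cs(m))
  lo <- pmax(seq_len(n_z) - floor(wz / 2), 1L)
  hi <- pmin(lo + wz - 1L, n_z)
  lo <- pmax(hi - wz + 1L, 1L)
  mz <- C[hi + 1L, , drop = FALSE] - C[lo, , drop = FALSE]
  # lateral pass
  C2 <- t(pad(cs(t(mz))))
  lo2 <- pmax(seq_len(n_x) - floor(wx / 2), 1L)
  hi2 <- pmin(lo2 + wx - 1L, n_x)
  lo2 <- pmax(hi2 - wx + 1L, 1L)
  C2[, hi2 + 1L, drop = FALSE] - C2[, lo2, drop = FALSE]
}

#' Interframe phase-difference map
#'
#' Pixelwise conjugate product of two sequential complex frames. Its argument
#' is the wrapped interframe phase difference (proportional to the axial
#' displacement between the frames) and its magnitude carries the correlation
#' weight used downstream by the vector strain estimator.
#'
#' @param frame_a,frame_b Complex matrices of equal shape (rows = depth).
#' @param frame_pair Optional integer pair identifying the frames.
#' @return An object of class `oce_phasediff`: the complex product
#'   `frame_b * Conj(frame_a)` with the frame pair attached.
#' @export
interframe_phase <- function(frame_a, frame_b, frame_pair = c(1L, 2L)) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have identical shape", call. = FALSE)
  structure(list(values = frame_b * Conj(frame_a),
                 frame_pair = as.integer(frame_pair)),
            class = "oce_phasediff")
}

#' Axial strain from a phase-difference map (vector method)
#'
#' Wrap-tolerant phase-gradient estimation by windowed complex-vector
#' averaging of axial lag products. A coarse slope comes from the windowed
#' single-pixel (lag-1) products; it is wrap-safe but biased toward zero by
#' the real-valued speckle autocorrelation cross-term that contaminates
#' products at lags inside the speckle correlation length. The final
#' estimate therefore combines lag products at lags 2..L — beyond the
#' correlation length, where the cross-term vanishes — each unwrapped about
#' the coarse slope and weighted by `lag^2 * |vector sum|` (inverse-variance
#' weighting: the speckle phase noise is independent of lag while the signal
#' phase grows linearly with it). L adapts to the aliasing limit so that the
#' largest lag phase stays below ~0.7 pi. The resulting phase-difference
#' gradient (rad/pixel) converts to strain through
#' `strain = gradient * lambda0 / (4 pi n dz)`. Compressive strain is
#' positive: under compression the optical path to every scatterer shortens,
#' which with the analytic-signal phase convention of
#' [simulate_compression_series()] gives an interframe phase of
#' `+(4 pi n / lambda0) * delta_u(z)` and hence a positive phase-depth
#' slope. Pixels whose normalized lag-1 vector magnitude falls below the
#' correlation floor are marked invalid.
#'
#' @param pdm An [interframe_phase()] map.
#' @param window Sliding window in pixels, `c(axial, lateral)`; at least 3x3.
#'   The default 8x8 (40 x 60 um) matches an output resolution roughly 4x
#'   coarser than the native OCT resolution.
#' @param system An [system_config()] object.
#' @param correlation_floor Normalized vector-magnitude floor in `[0, 1]`
#'   below which pixels are flagged invalid.
#' @param max_lag Largest axial lag (pixels) considered by the multi-lag
#'   combination.
#' @return An object of class `oce_strain`: `values` (dimensionless axial
#'   strain, rows = depth, one row fewer than the frame), `valid_mask`,
#'   `coherence`, `window`, `frame_pair`.
#' @export
vector_strain <- function(pdm, window = c(8L, 8L), system = system_config(),
                          correlation_floor = 0.3, max_lag = 8L) {
  v <- pdm$values
  window <- as.integer(window)
  if (any(window < 3L)) stop("window must be at least 3x3 px", call. = FALSE)
  if (window[1] > nrow(v) - 1L || window[2] > ncol(v))
    stop("window larger than frame", call. = FALSE)
  n <- nrow(v)
  eps <- .Machine$double.eps
  lagprod <- function(l) v[(1L + l):n, , drop = FALSE] *
    Conj(v[1:(n - l), , drop = FALSE])
  # align an (n - l)-row lag map to the common (n - 1)-row grid: the product
  # of rows (i, i + l) is centred at depth i + l/2, so pad (l - 1)/2 rows at
  # the top and clamp the remainder at the bottom
  align_rows <- function(m, l) {
    pad_top <- (l - 1L) %/% 2L
    if (pad_top > 0L)
      m <- rbind(m[rep(1L, pad_top), , drop = FALSE], m)
    if (nrow(m) < n - 1L)
      m <- rbind(m, m[rep(nrow(m), n - 1L - nrow(m)), , drop = FALSE])
    m
  }
  q1 <- lagprod(1L)
  Q1 <- boxsum(q1, window)
  den1 <- boxsum(Mod(q1), window)
  coh <- Mod(Q1) / pmax(den1, eps)
  s_coarse <- Arg(Q1)                                # rad / pixel, wrap-safe
  # adaptive largest lag: keep the lag-L phase below ~0.7 pi
  s_scale <- max(stats::quantile(abs(s_coarse), 0.9, na.rm = TRUE), 1e-6)
  L <- max(1L, min(as.integer(max_lag), floor(0.7 * pi / s_scale)))
  if (L >= 2L) {
    QL <- align_rows(boxsum(lagprod(L), window), L)
    s_ref <- Arg(QL * exp(complex(imaginary = -L * s_coarse))) / L + s_coarse
    num <- 0; den <- 0
    for (l in 2:L) {
      Ql <- align_rows(boxsum(lagprod(l), window), l)
      sl <- Arg(Ql * exp(complex(imaginary = -l * s_ref))) / l + s_ref
      w <- l^2 * Mod(Ql)
      num <- num + w * sl
      den <- den + w
    }
    grad <- num / pmax(den, eps)
  } else {
    grad <- s_coarse
  }
  strain <- grad * system$center_wavelength_um /
    (4 * pi * system$refractive_index * system$axial_pixel_pitch_um)
  structure(list(values = strain,
                 valid_mask = coh >= correlation_floor,
                 coherence = coh,
                 window = window,
                 frame_pair = pdm$frame_pair),
            class = "oce_strain")
}

#' Cumulative strain maps over a compression sweep
#'
#' Computes interframe strain on every consecutive frame pair and returns the
#' running (cumulative) sums, one map per pair: cumulative strain at step k is
#' the sum of the first k interframe strains. Pairs whose expected interframe
#' phase change across one axial resolution cell exceeds pi (phase aliasing)
#' abort with an error naming the offending pairs.
#'
#' @param series An [simulate_compression_series()] object.
#' @param window Estimator window, see [vector_strain()].
#' @param system System configuration; defaults to the series' own.
#' @param correlation_floor See [vector_strain()].
#' @return A list of class `oce_strain_series`: `cumulative` and
#'   `incremental` lists of `oce_strain` maps (one per consecutive pair).
#' @export
accumulate_strain <- function(series, window = c(8L, 8L),
                              system = series$system,
                              correlation_floor = 0.3) {
  K <- length(series$frames)
  if (K < 2) stop("need at least 2 frames", call. = FALSE)
  flagged <- which(as.logical(series$ground_truth$alias_flag))
  if (length(flagged))
    stop("aliased frame pairs: ", paste(flagged, collapse = ", "), call. = FALSE)
  inc <- vector("list", K - 1L)
  cum <- vector("list", K - 1L)
  run <- NULL
  for (k in seq_len(K - 1L)) {
    pdm <- interframe_phase(series$frames[[k]], series$frames[[k + 1L]],
                            frame_pair = c(k, k + 1L))
    s <- vector_strain(pdm, window, system, correlation_floor)
    # detected aliasing guard: median |phase step| per resolution cell
    med_step <- stats::median(abs(Arg(pdm$values[-1, ] *
                                        Conj(pdm$values[-nrow(pdm$values), ]))))
    if (med_step * system$axial_resolution_um / system$axial_pixel_pitch_um > pi / 2)
      stop("aliased frame pair detected: ", k, call. = FALSE)
    inc[[k]] <- s
    run <- if (is.null(run)) s$values else run + s$values
    cum[[k]] <- structure(list(values = run, valid_mask = s$valid_mask,
                               coherence = s$coherence, window = s$window,
                               frame_pair = c(1L, k + 1L)),
                          class = "oce_strain")
  }
  structure(list(cumulative = cum, incremental = inc, window = window),
            class = "oce_strain_series")
}
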