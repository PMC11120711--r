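#' Segment the reference silicone layer
#'
#' Locates the contiguous top band of the strain map occupied by the
#' reference silicone. The silicone, being much softer than tumor tissue,
#' carries a distinct and laterally homogeneous strain; per column, the
#' boundary is placed at the peak of the axial strain gradient (the centre
#' of the silicone-tissue strain transition, which stays unbiased under the
#' estimator's window blur), searched within +/- 30% of the thickness hint.
#' A column's boundary counts as detected only when the strain change across
#' it exceeds `contrast` (relative to the top-band level); undetected
#' columns fall back to the median detected boundary, and if no column shows
#' contrast the top band of hint thickness is returned with a
#' `"low-contrast"` warning.
#'
#' @param strain An `oce_strain` map (interframe or cumulative).
#' @param silicone_thickness_hint_um Expected layer thickness, um.
#' @param system An [system_config()] object (pixel pitch).
#' @param contrast Relative strain deviation defining the boundary.
#' @return Logical matrix of the same shape as `strain$values`; `TRUE` on
#'   silicone pixels. Per column the mask is a simply connected top band.
#' @export
segment_reference_layer <- function(strain, silicone_thickness_hint_um,
                                    system = system_config(),
                                    contrast = 0.3) {
  if (silicone_thickness_hint_um <= 0)
    stop("silicone_thickness_hint_um must be positive", call. = FALSE)
  v <- strain$values
  dz <- system$axial_pixel_pitch_um
  hint_px <- silicone_thickness_hint_um / dz
  lo <- max(2L, floor(hint_px * 0.7))
  hi <- min(nrow(v) - 1L, ceiling(hint_px * 1.3))
  top_rows <- seq_len(max(2L, floor(hint_px / 2)))
  ref_level <- stats::median(v[top_rows, ], na.rm = TRUE)
  if (!is.finite(ref_level) || abs(ref_level) < .Machine$double.eps)
    ref_level <- .Machine$double.eps
  boundary <- vapply(seq_len(ncol(v)), function(j) {
    grad <- abs(diff(v[, j]))
    k <- as.integer(lo - 1L + which.max(grad[lo:hi]))
    # detected only if the strain actually changes across the transition
    below <- stats::median(v[seq(min(k + 3L, nrow(v)), min(k + 8L, nrow(v))), j],
                           na.rm = TRUE)
    if (is.finite(below) &&
        abs(below - ref_level) > contrast * abs(ref_level)) k else NA_integer_
  }, integer(1))
  n_found <- sum(!is.na(boundary))
  if (n_found == 0) {
    warning("low-contrast reference layer: falling back to hint thickness",
            call. = FALSE)
    boundary[] <- round(hint_px)
  } else if (n_found < ncol(v)) {
    boundary[is.na(boundary)] <- round(stats::median(boundary, na.rm = TRUE))
  }
  # the layer is laterally continuous: smooth per-column outliers away
  if (length(boundary) >= 5)
    boundary <- as.integer(stats::runmed(boundary, 5))
  mask <- matrix(FALSE, nrow(v), ncol(v))
  for (j in seq_len(ncol(v))) if (boundary[j] >= 1) mask[seq_len(boundary[j]), j] <- TRUE
  mask
}

#' Select the pressure-standardized frame pair
#'
#' The reference silicone acts as a local pressure sensor: at step k the
#' local pressure equals the reference modulus times the median cumulative
#' silicone strain. Returns the first step whose silicone-inferred pressure
#' falls inside the standardization window `target +/- tolerance`.
#'
#' @param cumulative A list of cumulative `oce_strain` maps (e.g.
#'   `accumulate_strain(...)$cumulative`).
#' @param ref_mask Logical silicone mask from [segment_reference_layer()].
#' @param cal An [calibration_config()] object.
#' @return A list: `pair_index` (step k, i.e. frames 1..k+1 accumulated),
#'   `achieved_pressure_kpa`, and the full `pressures_kpa` profile.
#' @export
select_pressure_standard_pair <- function(cumulative, ref_mask,
                                          cal = calibration_config()) {
  if (!length(cumulative)) stop("need at least one cumulative map", call. = FALSE)
  m <- ref_mask[seq_len(nrow(cumulative[[1]]$values)), , drop = FALSE]
  pressures <- vapply(cumulative, function(s) {
    use <- m & s$valid_mask
    cal$reference_modulus_kpa * stats::median(s$values[use], na.rm = TRUE)
  }, numeric(1))
  in_win <- which(abs(pressures - cal$target_pressure_kpa) <=
                    cal$pressure_tolerance_kpa)
  if (!length(in_win))
    stop(sprintf(paste0("no compression step reaches the standardized pressure ",
                        "%.3g +/- %.3g kPa (achieved range %.3g to %.3g kPa)"),
                 cal$target_pressure_kpa, cal$pressure_tolerance_kpa,
                 min(pressures), max(pressures)), call. = FALSE)
  k <- in_win[1]
  list(pair_index = k, achieved_pressure_kpa = pressures[k],
       pressures_kpa = pressures)
}

#' Young's modulus map from a strain map
#'
#' Converts tissue strain to absolute Young's modulus through the reference
#' layer: `E_tissue = E_ref * eps_silicone / eps_tissue` (equal stress in the
#' silicone and the tissue column under uniaxial compression). The silicone
#' strain is the global median over the reference mask by default, or a
#' per-column median for tilted contact. Moduli are capped at
#' `cal$modulus_cap_kpa`; pixels with near-zero tissue strain are set to the
#' cap and flagged rather than raising an error. The tumor-cell mask marks
#' pixels above `cal$cancer_mask_threshold_kpa`.
#'
#' @param strain An `oce_strain` map (the incremental map at the
#'   pressure-standardized pair).
#' @param ref_mask Logical silicone mask.
#' @param cal An [calibration_config()] object.
#' @param silicone_strain `"global_median"` or `"per_column"`.
#' @param standardization_pressure_kpa Optional achieved pressure recorded in
#'   the result.
#' @return An object of class `oce_stiffness`: `values` (kPa),
#'   `cancer_mask`, `reference_mask`, `valid_mask`, `flagged` (capped
#'   pixels), `standardization_pressure_kpa`, `source_frame_pair`.
#' @export
stiffness_from_strain <- function(strain, ref_mask,
                                  cal = calibration_config(),
                                  silicone_strain = c("global_median", "per_column"),
                                  standardization_pressure_kpa = NA_real_) {
  silicone_strain <- match.arg(silicone_strain)
  v <- strain$values
  m <- ref_mask[seq_len(nrow(v)), , drop = FALSE]
  if (!any(m)) stop("reference mask is empty", call. = FALSE)
  if (silicone_strain == "global_median") {
    eps_s <- matrix(stats::median(v[m & strain$valid_mask], na.rm = TRUE),
                    nrow(v), ncol(v))
  } else {
    col_med <- vapply(seq_len(ncol(v)), function(j) {
      use <- m[, j] & strain$valid_mask[, j]
      stats::median(v[use, j], na.rm = TRUE)
    }, numeric(1))
    bad <- !is.finite(col_med)
    col_med[bad] <- stats::median(col_med[!bad])
    eps_s <- matrix(col_med, nrow(v), ncol(v), byrow = TRUE)
  }
  floor_eps <- .Machine$double.eps^0.5 * abs(eps_s)
  tiny <- abs(v) <= floor_eps
  E <- cal$reference_modulus_kpa * eps_s / v
  E[tiny | !is.finite(E) | E < 0] <- cal$modulus_cap_kpa
  flagged <- tiny | E > cal$modulus_cap_kpa
  E[E > cal$modulus_cap_kpa] <- cal$modulus_cap_kpa
  structure(list(values = E,
                 cancer_mask = (E > cal$cancer_mask_threshold_kpa) & !m,
                 reference_mask = m,
                 valid_mask = strain$valid_mask,
                 flagged = flagged,
                 standardization_pressure_kpa = standardization_pressure_kpa,
                 source_frame_pair = strain$frame_pair,
                 calibration = cal),
            class = "oce_stiffness")
}

# polygon (list(x=, z=), 0-based pixel coords) -> logical mask, even-odd rule
polygon_mask <- function(n_z, n_x, poly) {
  px <- poly$x; pz <- poly$z
  n <- length(px)
  xs <- rep((seq_len(n_x) - 1), each = n_z)
  zs <- rep((seq_len(n_z) - 1), times = n_x)
  inside <- rep(FALSE, n_z * n_x)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((pz[i] > zs) != (pz[j] > zs)) &
      (xs < (px[j] - px[i]) * (zs - pz[i]) / (pz[j] - pz[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, n_z, n_x)
}

#' Mean ROI stiffness under the tumor-cell mask
#'
#' Stiffness of a region of interest is quantified only over pixels above the
#' tumor-cell threshold (the `cancer_mask`), excluding the reference layer.
#'
#' @param stiff An `oce_stiffness` map.
#' @param roi Either a logical matrix of the map's shape, or a polygon
#'   `list(x =, z =)` in 0-based pixel coordinates.
#' @return A list: `mean_stiffness_kpa` (`NA` when no ROI pixel passes the
#'   mask), `masked_fraction` (fraction of ROI pixels above threshold, the
#'   reference layer excluded from the denominator), `n_pixels`.
#' @export
quantify_roi <- function(stiff, roi) {
  v <- stiff$values
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dim(v))) stop("ROI mask shape mismatch", call. = FALSE)
    rmask <- roi
  } else if (is.list(roi) && !is.null(roi$x) && !is.null(roi$z)) {
    rmask <- polygon_mask(nrow(v), ncol(v), roi)
  } else stop("roi must be a logical mask or a polygon list(x=, z=)", call. = FALSE)
  rmask <- rmask & !stiff$reference_mask
  if (!any(rmask)) stop("ROI does not intersect the tissue image", call. = FALSE)
  use <- rmask & stiff$cancer_mask
  frac <- sum(use) / sum(rmask)
  list(mean_stiffness_kpa = if (any(use)) mean(v[use]) else NA_real_,
       masked_fraction = frac,
       n_pixels = sum(rmask))
}
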