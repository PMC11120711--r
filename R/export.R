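#' Export maps as TIFF / colorized PNG
#'
#' `export_map_tiff` writes a strain or stiffness map as a 32-bit float TIFF
#' with values rescaled to `[0, 1]`; the original value range, units and the
#' map's window / frame-pair metadata go to a JSON sidecar (`<path>.json`)
#' so the physical values can be reconstructed exactly. An optional
#' validity-mask TIFF can be written alongside. `export_stiffness_png`
#' writes the color-coded rendering used for visual reading: red (soft)
#' through yellow, green and blue to dark blue (stiff), with the 520 kPa
#' tumor-cell threshold at the yellow boundary. The colormap anchors are a
#' display convention, not a scientific claim.
#'
#' @param map An `oce_strain` or `oce_stiffness` object.
#' @param path Output file path.
#' @param mask_path Optional path for the validity-mask TIFF.
#' @param units Unit string recorded in the sidecar.
#' @param cap_kpa Stiffness mapped to the dark-blue end.
#' @return The output path, invisibly.
#' @export
export_map_tiff <- function(map, path, mask_path = NULL, units = "") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  v <- map$values
  rng <- range(v[is.finite(v)])
  span <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((v - rng[1]) / span, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(value_min = rng[1], value_max = rng[2], units = units,
               window = map$window, frame_pair = map$source_frame_pair %||%
                 map$frame_pair)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(mask_path) && !is.null(map$valid_mask))
    tiff::writeTIFF(matrix(as.numeric(map$valid_mask), nrow(v)), mask_path,
                    bits.per.sample = 8L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname export_map_tiff
#' @export
export_stiffness_png <- function(map, path, cap_kpa = 2000) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  v <- pmin(map$values, cap_kpa)
  # anchors: 0 red -> 520 yellow -> green -> blue -> cap dark blue
  anchors_kpa <- c(0, 520, (520 + cap_kpa) / 2, cap_kpa * 0.85, cap_kpa)
  cols <- grDevices::colorRamp(c("#d7191c", "#ffff66", "#1a9641",
                                 "#2c7fb8", "#0b1d51"))
  t01 <- stats::approx(anchors_kpa, seq(0, 1, length.out = 5),
                       xout = as.numeric(v), rule = 2)$y
  rgb <- cols(t01) / 255
  arr <- array(rgb, dim = c(nrow(v), ncol(v), 3))
  png::writePNG(arr, path)
  invisible(path)
}
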