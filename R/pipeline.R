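#' Run the full in-silico study pipeline
#'
#' Mirrors the study design end to end: sample a cohort with the study's
#' case/ROI structure, summarize stiffness by pattern and by mutation status
#' with pairwise Mann-Whitney tests, run Fisher's exact tests on the grade
#' and pattern mutation-frequency contrasts, evaluate stiffness as a
#' mutation marker (ROC, Youden threshold, confusion metrics at the fixed
#' any-driver and KRAS thresholds) against the pattern-as-marker baselines,
#' and flag heterogeneous cases. Optionally runs the image-level chain on a
#' two-block phantom (phantom -> strain -> stiffness -> ROI quantification)
#' and reports the recovered block medians.
#'
#' @param seed Integer seed used for every stochastic step.
#' @param spec An [cohort_spec()] object.
#' @param calibration An [calibration_config()] object.
#' @param classifier An [classifier_config()] object.
#' @param image_chain If `TRUE`, include the phantom image-level chain.
#' @param image_noiseless Simulate the image chain without noise.
#' @param output_dir If non-`NULL`, write the report JSON and the cohort /
#'   summary CSVs there.
#' @return An `oce_report` list with elements `provenance`,
#'   `group_summaries`, `u_tests`, `fisher_tests`, `roc_results`,
#'   `confusion_metrics`, `heterogeneity_flags` and (optionally)
#'   `image_chain`.
#' @export
run_pipeline <- function(seed = 1L,
                         spec = cohort_spec(),
                         calibration = calibration_config(),
                         classifier = classifier_config(),
                         image_chain = FALSE,
                         image_noiseless = TRUE,
                         output_dir = NULL) {
  seed <- as.integer(seed)
  cohort <- sample_cohort(spec, seed = seed)
  cases <- cohort_case_table(cohort)

  by_pattern <- summarize_groups(cohort, "pattern")
  by_mutation <- summarize_groups(cohort, "mutation")

  fisher_tests <- list(
    grade = list(table = grade_mutation_table(cohort),
                 p = fisher_exact(grade_mutation_table(cohort))),
    pattern = list(table = pattern_mutation_table(cohort),
                   p = fisher_exact(pattern_mutation_table(cohort))))

  any_labels <- cohort$mutation != "wt"
  kras_labels <- cohort$mutation == "KRAS"
  roc_any <- roc_curve(cohort$stiffness_kpa, any_labels)
  roc_kras <- roc_curve(cohort$stiffness_kpa, kras_labels)
  youden_any <- youden_threshold(roc_any)
  youden_kras <- youden_threshold(roc_kras)

  confusion <- list(
    any_driver_fixed = metrics_at_threshold(cohort$stiffness_kpa, any_labels,
                                            classifier$threshold_any_driver_kpa),
    kras_fixed = metrics_at_threshold(cohort$stiffness_kpa, kras_labels,
                                      classifier$threshold_kras_kpa),
    any_driver_youden = metrics_at_threshold(cohort$stiffness_kpa, any_labels,
                                             youden_any$threshold_kpa),
    kras_youden = metrics_at_threshold(cohort$stiffness_kpa, kras_labels,
                                       youden_kras$threshold_kpa),
    pattern_complex_tubular = pattern_marker_metrics(cohort, "complex_tubular"),
    pattern_solid = pattern_marker_metrics(cohort, "solid"))

  report <- list(
    provenance = list(seed = seed, package_version =
                        as.character(utils::packageVersion("elastoce"))),
    cohort = cohort,
    cases = cases,
    group_summaries = list(pattern = by_pattern$summary,
                           mutation = by_mutation$summary),
    u_tests = list(pattern = by_pattern$tests, mutation = by_mutation$tests),
    fisher_tests = fisher_tests,
    roc_results = list(any_driver = roc_any, kras = roc_kras),
    youden = list(any_driver = youden_any, kras = youden_kras),
    confusion_metrics = confusion,
    heterogeneity_flags = flag_heterogeneous_cases(cohort, classifier))

  if (image_chain) {
    report$image_chain <- run_image_chain(seed = seed, calibration = calibration,
                                          noiseless = image_noiseless)
  }
  report$provenance$config_hash <- config_hash(list(spec = spec,
                                                    calibration = calibration,
                                                    classifier = classifier,
                                                    seed = seed))
  class(report) <- "oce_report"

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir) &&
        !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", output_dir, call. = FALSE)
    write_cohort_csv(cohort, file.path(output_dir, "cohort.csv"))
    utils::write.csv(by_pattern$summary,
                     file.path(output_dir, "summary_by_pattern.csv"),
                     row.names = FALSE)
    write_report(report, file.path(output_dir, "report.json"))
  }
  report
}

#' Image-level recovery chain on a two-block phantom
#'
#' Simulates a compression sweep over a phantom with a 100 kPa silicone
#' reference layer above two tissue blocks, estimates strain, selects the
#' pressure-standardized pair, maps stiffness and quantifies each block.
#'
#' @param seed Integer seed.
#' @param calibration An [calibration_config()] object.
#' @param block_moduli_kpa Moduli of the left and right tissue blocks, kPa.
#' @param noiseless Simulate without noise.
#' @param n_steps,max_pressure_kpa Compression sweep: number of frames and
#'   final surface pressure.
#' @param window Strain-estimator window (pixels).
#' @param lateral_extent_mm,depth_extent_mm,silicone_thickness_um Geometry.
#' @param system An [system_config()] object.
#' @return A list with the selected pair, achieved pressure, recovered block
#'   medians and the ground-truth moduli.
#' @export
run_image_chain <- function(seed = 1L,
                            calibration = calibration_config(),
                            block_moduli_kpa = c(600, 1000),
                            noiseless = TRUE,
                            n_steps = 21L,
                            max_pressure_kpa = 10,
                            window = c(8L, 8L),
                            lateral_extent_mm = 1,
                            depth_extent_mm = 1.2,
                            silicone_thickness_um = 300,
                            system = system_config()) {
  half_um <- lateral_extent_mm * 1000 / 2
  blocks <- function(x_um, z_um)
    ifelse(x_um < half_um, block_moduli_kpa[1], block_moduli_kpa[2])
  ph <- build_phantom(lateral_extent_mm = lateral_extent_mm,
                      depth_extent_mm = depth_extent_mm,
                      silicone_thickness_um = silicone_thickness_um,
                      tissue_modulus_kpa = blocks,
                      seed = seed, system = system)
  series <- simulate_compression_series(
    ph, system, surface_pressures = seq(0, max_pressure_kpa,
                                        length.out = n_steps),
    seed = seed, noiseless = noiseless)
  ss <- accumulate_strain(series, window = window, system = system)
  # pressure inference uses the near-uncompressed mask; the stiffness map is
  # formed with the mask re-segmented at the selected pair (the interface
  # moves toward the probe as the silicone compresses)
  ref0 <- segment_reference_layer(ss$cumulative[[1L]],
                                  silicone_thickness_um, system)
  sel <- select_pressure_standard_pair(ss$cumulative, ref0, calibration)
  ref <- segment_reference_layer(ss$cumulative[[sel$pair_index]],
                                 silicone_thickness_um, system)
  stiff <- stiffness_from_strain(ss$incremental[[sel$pair_index]], ref,
                                 calibration,
                                 standardization_pressure_kpa =
                                   sel$achieved_pressure_kpa)
  g <- series$grid
  n_z <- nrow(stiff$values); n_x <- ncol(stiff$values)
  margin_z <- ceiling(2 * system$axial_resolution_um / g$dz)
  top <- ceiling(silicone_thickness_um / g$dz) + margin_z
  margin_x <- ceiling(2 * system$lateral_resolution_um / g$dx)
  half_px <- floor(n_x / 2)
  tissue_rows <- seq(top, n_z - margin_z)
  left_cols <- seq(1 + margin_x, half_px - margin_x)
  right_cols <- seq(half_px + margin_x, n_x - margin_x)
  med <- function(cols) {
    sub <- stiff$values[tissue_rows, cols]
    ok <- stiff$valid_mask[tissue_rows, cols]
    stats::median(sub[ok])
  }
  left_roi <- matrix(FALSE, n_z, n_x); left_roi[tissue_rows, left_cols] <- TRUE
  right_roi <- matrix(FALSE, n_z, n_x); right_roi[tissue_rows, right_cols] <- TRUE
  list(pair_index = sel$pair_index,
       achieved_pressure_kpa = sel$achieved_pressure_kpa,
       applied_pressure_kpa = series$pressures[sel$pair_index + 1L],
       block_medians_kpa = c(left = med(left_cols), right = med(right_cols)),
       block_truth_kpa = c(left = block_moduli_kpa[1],
                           right = block_moduli_kpa[2]),
       roi_quant = list(left = quantify_roi(stiff, left_roi),
                        right = quantify_roi(stiff, right_roi)),
       stiffness = stiff)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

# strip heavy / non-serializable members before writing
report_payload <- function(report) {
  out <- unclass(report)
  out$roc_results <- lapply(out$roc_results, unclass)
  out$confusion_metrics <- lapply(out$confusion_metrics, unclass)
  if (!is.null(out$image_chain)) out$image_chain$stiffness <- NULL
  out$cohort <- as.data.frame(out$cohort)
  out
}

#' Write / read an analysis report as JSON
#'
#' @param report An `oce_report` from [run_pipeline()].
#' @param path Output file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the parsed list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
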