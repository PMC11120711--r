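two_layer_pair <- function(seed, pressures = c(0, 0.2), noiseless = TRUE,
                           tissue_kpa = 600) {
  sys <- test_system()
  ph <- build_phantom(lateral_extent_mm = 1, depth_extent_mm = 1.2,
                      silicone_thickness_um = 300, silicone_modulus_kpa = 100,
                      tissue_modulus_kpa = tissue_kpa, seed = seed,
                      system = sys)
  se <- simulate_compression_series(ph, sys, pressures, seed = seed,
                                    noiseless = noiseless)
  s <- vector_strain(interframe_phase(se$frames[[1]], se$frames[[2]]),
                     c(4, 16), sys)
  list(system = sys, series = se, strain = s)
}

test_that("reference layer segmentation recovers the known geometry", {
  # near-zero load: interface essentially at its resting depth (row 60)
  tl <- two_layer_pair(seed = 3)
  b <- colSums(segment_reference_layer(tl$strain, 300, tl$system))
  expect_true(all(abs(b - 60) <= 2))
  expect_gt(mean(abs(b - 60) <= 1), 0.7)
})

test_that("segmentation falls back with a warning when there is no layer contrast", {
  u <- uniform_pair(seed = 12, noiseless = TRUE, depth_mm = 0.8)
  s <- vector_strain(u$pdm, c(4, 16), u$system)
  expect_warning(m <- segment_reference_layer(s, 300, u$system),
                 "low-contrast")
  expect_true(all(colSums(m) == 60))
})

test_that("segmentation tracks the compressed interface within one resolution cell", {
  fr <- vapply(1:10, function(seed) {
    tl <- two_layer_pair(seed, pressures = c(2, 2.5), noiseless = FALSE)
    b <- colSums(segment_reference_layer(tl$strain, 300, tl$system))
    # the silicone-tissue interface sits at 300 um minus 3 um/kPa of travel
    truth <- (300 - 3 * 2.25) / 5 - 0.5
    mean(abs(b - truth) <= 2)
  }, numeric(1))
  expect_gte(mean(fr), 0.9)
})

test_that("pressure-standard pair selection follows the first-in-window rule", {
  cal <- calibration_config()
  n_z <- 40; n_x <- 20
  ref <- rbind(matrix(TRUE, 20, n_x), matrix(FALSE, n_z - 20, n_x))
  cum <- lapply(c(0.01, 0.03, 0.05), function(e)
    make_strain_map(matrix(e, n_z, n_x)))
  sel <- select_pressure_standard_pair(cum, ref, cal)
  expect_identical(sel$pair_index, 2L)
  expect_equal(sel$achieved_pressure_kpa, 3)
  expect_equal(sel$pressures_kpa, c(1, 3, 5))

  low <- lapply(c(0.001, 0.002), function(e)
    make_strain_map(matrix(e, n_z, n_x)))
  expect_error(select_pressure_standard_pair(low, ref, cal), "standardized")
})

test_that("stiffness map is the calibrated silicone-to-tissue strain ratio", {
  cal <- calibration_config()
  n_z <- 60; n_x <- 20
  ref <- rbind(matrix(TRUE, 20, n_x), matrix(FALSE, 40, n_x))
  vals <- rbind(matrix(0.01, 20, n_x), matrix(0.005, 40, n_x))
  st <- stiffness_from_strain(make_strain_map(vals), ref, cal)
  expect_equal(unique(st$values[!ref]), 200, tolerance = 1e-12)
  expect_false(any(st$cancer_mask[!ref]))

  # tissue strain identical to silicone strain: uniform 100 kPa
  st1 <- stiffness_from_strain(make_strain_map(matrix(0.01, n_z, n_x)), ref, cal)
  expect_equal(unique(st1$values[!ref]), 100, tolerance = 1e-12)

  # scale invariance: the ratio cancels any common strain factor
  st3 <- stiffness_from_strain(make_strain_map(3.7 * vals), ref, cal)
  expect_equal(st3$values, st$values, tolerance = 1e-12)

  # near-zero tissue strain is capped and flagged, not an error
  vz <- vals; vz[30, 5] <- 1e-12
  stz <- stiffness_from_strain(make_strain_map(vz), ref, cal)
  expect_equal(stz$values[30, 5], cal$modulus_cap_kpa)
  expect_true(stz$flagged[30, 5])
  expect_error(stiffness_from_strain(make_strain_map(vals),
                                     matrix(FALSE, n_z, n_x), cal), "empty")
})

test_that("silicone evaluated as tissue reads back its own 100 kPa modulus", {
  sys <- test_system()
  ph <- build_phantom(lateral_extent_mm = 1, depth_extent_mm = 1.2,
                      silicone_thickness_um = 300, tissue_modulus_kpa = 600,
                      seed = 5, system = sys)
  se <- simulate_compression_series(ph, sys, c(0, 0.5), seed = 5,
                                    noiseless = TRUE)
  s <- vector_strain(interframe_phase(se$frames[[1]], se$frames[[2]]),
                     c(20, 20), sys)
  # silicone interior, away from the interface and window margins
  ref <- matrix(FALSE, nrow(s$values), ncol(s$values))
  ref[1:48, ] <- TRUE
  st <- stiffness_from_strain(s, ref, calibration_config())
  sil <- st$values[15:45, ][s$valid_mask[15:45, ]]
  expect_equal(stats::median(sil), 100, tolerance = 0.05)
  expect_gt(mean(abs(sil - 100) <= 10), 0.9)
})

test_that("ROI quantification respects the tumor-cell mask semantics", {
  st <- make_stiffness_map(matrix(700, 40, 30))
  roi <- matrix(FALSE, 40, 30); roi[10:30, 5:25] <- TRUE
  q <- quantify_roi(st, roi)
  expect_equal(q$mean_stiffness_kpa, 700)
  expect_equal(q$masked_fraction, 1)

  half <- matrix(rep(c(400, 800), each = 20), 40, 30)
  q2 <- quantify_roi(make_stiffness_map(half), roi)
  expect_equal(q2$mean_stiffness_kpa, 800)
  expect_equal(q2$masked_fraction, mean(half[roi] > 520))

  q3 <- quantify_roi(make_stiffness_map(matrix(300, 40, 30)), roi)
  expect_true(is.na(q3$mean_stiffness_kpa))
  expect_equal(q3$masked_fraction, 0)

  # polygon ROI (0-based pixel coordinates)
  qp <- quantify_roi(st, list(x = c(4, 24, 24, 4), z = c(9, 9, 29, 29)))
  expect_equal(qp$mean_stiffness_kpa, 700)
  expect_error(quantify_roi(st, roi[1:10, ]), "shape")
})

test_that("two-block phantom recovers block moduli and stiffness ordering", {
  ic <- run_image_chain(seed = 1, noiseless = TRUE)
  expect_true(ic$achieved_pressure_kpa >= 3 && ic$achieved_pressure_kpa <= 5)
  expect_lt(abs(ic$achieved_pressure_kpa / ic$applied_pressure_kpa - 1), 0.1)
  expect_lt(abs(ic$block_medians_kpa[["left"]] / 600 - 1), 0.1)
  expect_lt(abs(ic$block_medians_kpa[["right"]] / 1000 - 1), 0.1)
  # monotonicity: the stiffer block is never mapped softer
  expect_lt(ic$block_medians_kpa[["left"]], ic$block_medians_kpa[["right"]])
  # both blocks are above the tumor-cell threshold, so the mask covers them
  expect_gt(ic$roi_quant$left$masked_fraction, 0.5)
  expect_gt(ic$roi_quant$right$masked_fraction, 0.9)
})
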