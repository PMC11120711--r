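#' OCT system configuration
#'
#' Describes the imaging system that the phantom generator emulates: a
#' 1310 nm spectral-domain OCT device with 10 um axial and 15 um lateral
#' resolution and 2 mm imaging depth. The refractive index is the group index
#' used to convert interframe phase to axial displacement; it cancels in the
#' stiffness ratio, so only the realism of simulated phases depends on it.
#'
#' @param center_wavelength_um Central wavelength, micrometres.
#' @param axial_resolution_um Axial resolution (in air), micrometres.
#' @param lateral_resolution_um Lateral resolution, micrometres.
#' @param imaging_depth_mm Imaging depth, millimetres.
#' @param axial_pixel_pitch_um Axial pixel pitch, micrometres. Must satisfy
#'   Nyquist sampling of the axial resolution cell (pitch <= resolution / 2).
#' @param lateral_pixel_pitch_um Lateral pixel pitch, micrometres.
#' @param refractive_index Group refractive index of the medium.
#' @param snr_db Signal-to-noise ratio of simulated frames, dB.
#' @return An object of class `oce_system`.
#' @export
system_config <- function(center_wavelength_um = 1.31,
                          axial_resolution_um = 10,
                          lateral_resolution_um = 15,
                          imaging_depth_mm = 2,
                          axial_pixel_pitch_um = 5,
                          lateral_pixel_pitch_um = 7.5,
                          refractive_index = 1.4,
                          snr_db = 25) {
  lens <- c(center_wavelength_um, axial_resolution_um, lateral_resolution_um,
            imaging_depth_mm, axial_pixel_pitch_um, lateral_pixel_pitch_um)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all system lengths must be positive and finite", call. = FALSE)
  if (axial_pixel_pitch_um > axial_resolution_um / 2)
    stop("axial_pixel_pitch_um must be <= axial_resolution_um / 2 ",
         "(Nyquist sampling of the resolution cell)", call. = FALSE)
  if (refractive_index < 1) stop("refractive_index must be >= 1", call. = FALSE)
  structure(list(center_wavelength_um = center_wavelength_um,
                 axial_resolution_um = axial_resolution_um,
                 lateral_resolution_um = lateral_resolution_um,
                 imaging_depth_mm = imaging_depth_mm,
                 axial_pixel_pitch_um = axial_pixel_pitch_um,
                 lateral_pixel_pitch_um = lateral_pixel_pitch_um,
                 refractive_index = refractive_index,
                 snr_db = snr_db),
            class = "oce_system")
}

#' Stiffness calibration configuration
#'
#' Parameters of the reference-layer calibration: the pre-calibrated Young's
#' modulus of the silicone layer, the standardized local pressure at which
#' stiffness maps are formed (the silicone acts as a pressure sensor), the
#' stiffness threshold above which pixels are considered tumor cells, and a
#' display/stability cap on reported moduli.
#'
#' @param reference_modulus_kpa Young's modulus of the reference silicone, kPa.
#' @param target_pressure_kpa Standardized local pressure, kPa.
#' @param pressure_tolerance_kpa Acceptance half-window around the target, kPa.
#' @param cancer_mask_threshold_kpa Stiffness threshold for the tumor-cell
#'   mask, kPa; quantification is restricted to pixels above it.
#' @param modulus_cap_kpa Upper cap on mapped moduli, kPa.
#' @return An object of class `oce_calibration`.
#' @export
calibration_config <- function(reference_modulus_kpa = 100,
                               target_pressure_kpa = 4,
                               pressure_tolerance_kpa = 1,
                               cancer_mask_threshold_kpa = 520,
                               modulus_cap_kpa = 2000) {
  vals <- c(reference_modulus_kpa, target_pressure_kpa, pressure_tolerance_kpa,
            cancer_mask_threshold_kpa, modulus_cap_kpa)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all calibration parameters must be positive", call. = FALSE)
  if (pressure_tolerance_kpa >= target_pressure_kpa)
    stop("pressure_tolerance_kpa must be smaller than target_pressure_kpa",
         call. = FALSE)
  structure(list(reference_modulus_kpa = reference_modulus_kpa,
                 target_pressure_kpa = target_pressure_kpa,
                 pressure_tolerance_kpa = pressure_tolerance_kpa,
                 cancer_mask_threshold_kpa = cancer_mask_threshold_kpa,
                 modulus_cap_kpa = modulus_cap_kpa),
            class = "oce_calibration")
}

#' Stiffness-threshold classifier configuration
#'
#' Stiffness cut-offs used to call mutation status from per-ROI stiffness:
#' above 803 kPa for any KRAS/NRAS/BRAF driver mutation, above 850 kPa for a
#' KRAS mutation specifically, and 857 kPa for differentiating solid from
#' complex tubular growth patterns. The positive rule is strict: a ROI is
#' called positive when its stiffness is strictly above the threshold.
#'
#' @param threshold_any_driver_kpa Cut-off for any driver mutation, kPa.
#' @param threshold_kras_kpa Cut-off for KRAS mutation, kPa.
#' @param threshold_solid_vs_tubular_kpa Cut-off separating solid from complex
#'   tubular patterns, kPa.
#' @return An object of class `oce_classifier_config`.
#' @export
classifier_config <- function(threshold_any_driver_kpa = 803,
                              threshold_kras_kpa = 850,
                              threshold_solid_vs_tubular_kpa = 857) {
  th <- c(threshold_any_driver_kpa, threshold_kras_kpa,
          threshold_solid_vs_tubular_kpa)
  if (any(!is.finite(th)) || any(th <= 520))
    stop("classifier thresholds must exceed the 520 kPa tumor-cell floor",
         call. = FALSE)
  structure(list(threshold_any_driver_kpa = threshold_any_driver_kpa,
                 threshold_kras_kpa = threshold_kras_kpa,
                 threshold_solid_vs_tubular_kpa = threshold_solid_vs_tubular_kpa),
            class = "oce_classifier_config")
}
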