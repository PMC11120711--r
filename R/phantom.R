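#' Build a scatterer phantom with a reference silicone layer
#'
#' Constructs the ground-truth geometry and elasticity of a two-layer medium:
#' a reference silicone slab of known Young's modulus on top of tissue whose
#' modulus may vary laterally and in depth. Sub-resolution scatterers are
#' placed i.i.d. uniformly over the domain with complex circular-Gaussian
#' reflectivities (unit-mean exponential intensities), which yields fully
#' developed Rayleigh speckle at sufficient density.
#'
#' @param lateral_extent_mm Lateral extent of the phantom, mm.
#' @param depth_extent_mm Depth extent, mm.
#' @param silicone_thickness_um Thickness of the reference layer, um. May be 0
#'   for a pure-tissue phantom.
#' @param silicone_modulus_kpa Young's modulus of the reference layer, kPa.
#' @param tissue_modulus_kpa Either a single modulus (kPa) or a vectorized
#'   function `f(x_um, z_um)` returning the tissue modulus at each position.
#' @param scatterer_density Mean number of scatterers per resolution cell;
#'   at least 6 for fully developed speckle.
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @param system An [system_config()] object (defines the resolution cell).
#' @return An object of class `oce_phantom`.
#' @export
build_phantom <- function(lateral_extent_mm = 1,
                          depth_extent_mm = 1.5,
                          silicone_thickness_um = 300,
                          silicone_modulus_kpa = 100,
                          tissue_modulus_kpa = 600,
                          scatterer_density = 10,
                          seed = 1L,
                          system = system_config()) {
  if (lateral_extent_mm <= 0 || depth_extent_mm <= 0)
    stop("phantom extents must be positive", call. = FALSE)
  if (silicone_thickness_um < 0 ||
      silicone_thickness_um >= depth_extent_mm * 1000)
    stop("silicone_thickness_um must lie in [0, depth_extent)", call. = FALSE)
  if (silicone_modulus_kpa <= 0)
    stop("silicone_modulus_kpa must be positive", call. = FALSE)
  if (is.numeric(tissue_modulus_kpa)) {
    if (any(tissue_modulus_kpa <= 0))
      stop("tissue_modulus_kpa must be positive", call. = FALSE)
    Et <- tissue_modulus_kpa[1]
    modulus_fun <- function(x_um, z_um) rep(Et, length(x_um))
  } else if (is.function(tissue_modulus_kpa)) {
    modulus_fun <- tissue_modulus_kpa
  } else stop("tissue_modulus_kpa must be a number or a function", call. = FALSE)
  if (scatterer_density < 6)
    stop("scatterer_density must be >= 6 (fully developed speckle)",
         call. = FALSE)

  lx_um <- lateral_extent_mm * 1000
  lz_um <- depth_extent_mm * 1000
  n_cells <- floor(lx_um / system$lateral_resolution_um) *
    floor(lz_um / system$axial_resolution_um)
  n_scat <- round(scatterer_density * n_cells)

  set.seed(as.integer(seed))
  x <- stats::runif(n_scat, 0, lx_um)
  z <- stats::runif(n_scat, 0, lz_um)
  # circular complex Gaussian reflectivity: |r|^2 ~ Exp(mean 1)
  r <- complex(real = stats::rnorm(n_scat, sd = sqrt(0.5)),
               imaginary = stats::rnorm(n_scat, sd = sqrt(0.5)))

  structure(list(lateral_extent_mm = lateral_extent_mm,
                 depth_extent_mm = depth_extent_mm,
                 silicone_thickness_um = silicone_thickness_um,
                 silicone_modulus_kpa = silicone_modulus_kpa,
                 tissue_modulus_fun = modulus_fun,
                 scatterer_density = scatterer_density,
                 scatterers = data.frame(x_um = x, z_um = z,
                                         reflectivity = r),
                 seed = as.integer(seed),
                 system = system),
            class = "oce_phantom")
}

#' Ground-truth Young's modulus of a phantom
#'
#' @param phantom An `oce_phantom`.
#' @param x_um,z_um Positions, um (vectors of equal length or recyclable).
#' @return Modulus in kPa at each position (silicone above the layer
#'   boundary, tissue below).
#' @export
phantom_modulus <- function(phantom, x_um, z_um) {
  n <- max(length(x_um), length(z_um))
  x_um <- rep_len(x_um, n); z_um <- rep_len(z_um, n)
  E <- phantom$tissue_modulus_fun(x_um, z_um)
  E <- rep_len(E, n)
  E[z_um < phantom$silicone_thickness_um] <- phantom$silicone_modulus_kpa
  E
}

# pixel-grid geometry shared by the simulator and the estimators
phantom_grid <- function(phantom, system) {
  dz <- system$axial_pixel_pitch_um
  dx <- system$lateral_pixel_pitch_um
  n_z <- floor(phantom$depth_extent_mm * 1000 / dz) + 1L
  n_x <- floor(phantom$lateral_extent_mm * 1000 / dx) + 1L
  list(n_z = n_z, n_x = n_x, dz = dz, dx = dx,
       z_um = (seq_len(n_z) - 1) * dz, x_um = (seq_len(n_x) - 1) * dx)
}

#' Simulate a compression series of complex OCT frames
#'
#' Forward model inverted by the strain estimator. The medium is a uniaxial
#' stress column under quasi-static compression applied through the probe:
#' at surface pressure P each layer carries strain `eps = P / E` (linear
#' elasticity, equal stress in silicone and tissue). Depth is measured from
#' the probe contact, which is the fixed boundary of the probe frame; a
#' scatterer initially at depth z appears at the compressed depth
#' `z - P * integral_0^z dz'/E(z')`. Each frame is the complex speckle image
#' of the displaced scatterers under a separable Gaussian PSF (axial FWHM
#' `axial_resolution / n`, lateral FWHM `lateral_resolution`) plus additive
#' complex white Gaussian noise at the configured SNR. Scatterer phase
#' follows the analytic-signal convention `exp(-i (4 pi n / lambda0) d)` for
#' optical depth d, so the interframe phase at depth z equals
#' `+(4 pi n / lambda0) * delta_u(z)` where `delta_u` is the interframe
#' displacement toward the probe; the phase-depth slope is positive for
#' compressive strain.
#'
#' @param phantom An [build_phantom()] object.
#' @param system An [system_config()] object.
#' @param surface_pressures Strictly increasing vector of surface pressures
#'   (kPa), one per frame; typically starting at 0.
#' @param seed Integer seed for the frame noise.
#' @param noiseless If `TRUE`, no noise is added regardless of the SNR.
#' @return An object of class `oce_series`: a list of complex frames
#'   (rows = depth, cols = lateral), the pressures, the system, and a
#'   `ground_truth` record with per-step strain and displacement fields and
#'   per-pair aliasing flags.
#' @export
simulate_compression_series <- function(phantom, system = phantom$system,
                                        surface_pressures = seq(0, 10, length.out = 21),
                                        seed = 1L, noiseless = FALSE) {
  if (length(surface_pressures) < 1 || any(surface_pressures < 0))
    stop("surface_pressures must be >= 0", call. = FALSE)
  if (length(surface_pressures) > 1 && any(diff(surface_pressures) < 0))
    stop("surface_pressures must be non-decreasing", call. = FALSE)

  g <- phantom_grid(phantom, system)
  lam <- system$center_wavelength_um
  n_idx <- system$refractive_index
  k4pn <- 4 * pi * n_idx / lam

  # strain per unit pressure on the pixel grid (n_z x n_x)
  Emat <- matrix(phantom_modulus(phantom,
                                 x_um = rep(g$x_um, each = g$n_z),
                                 z_um = rep(g$z_um, times = g$n_x)),
                 nrow = g$n_z, ncol = g$n_x)
  S <- 1 / Emat                                   # strain / kPa
  # displacement toward the probe per unit pressure: u1(z) = int_0^z dz'/E
  U1 <- apply(S, 2, function(col) cumsum(col) * g$dz) # um / kPa
  U1 <- rbind(0, U1[-g$n_z, , drop = FALSE]) + S * g$dz / 2  # midpoint rule

  # per-scatterer compliance, nearest image column
  sc <- phantom$scatterers
  col_idx <- pmin(pmax(round(sc$x_um / g$dx) + 1L, 1L), g$n_x)
  zi <- sc$z_um / g$dz
  zlo <- pmin(pmax(floor(zi) + 1L, 1L), g$n_z)
  zhi <- pmin(zlo + 1L, g$n_z)
  wz <- zi - (zlo - 1L)
  u1_s <- (1 - wz) * U1[cbind(zlo, col_idx)] + wz * U1[cbind(zhi, col_idx)]

  sigma_z <- (system$axial_resolution_um / n_idx) / (2 * sqrt(2 * log(2)))
  sigma_x <- system$lateral_resolution_um / (2 * sqrt(2 * log(2)))

  set.seed(as.integer(seed))
  frames <- vector("list", length(surface_pressures))
  sig_pow <- NA_real_
  for (k in seq_along(surface_pressures)) {
    P <- surface_pressures[k]
    z_k <- sc$z_um - P * u1_s
    amp <- sc$reflectivity * exp(complex(imaginary = -k4pn * z_k))
    img <- deposit_scatterers(sc$x_um, z_k, amp, g$n_z, g$n_x,
                              g$dz, g$dx, sigma_z, sigma_x)
    if (!noiseless && is.finite(system$snr_db)) {
      if (is.na(sig_pow)) sig_pow <- mean(Mod(img)^2)
      nsd <- sqrt(sig_pow * 10^(-system$snr_db / 10) / 2)
      img <- img + matrix(complex(real = stats::rnorm(length(img), sd = nsd),
                                  imaginary = stats::rnorm(length(img), sd = nsd)),
                          nrow = g$n_z)
    }
    frames[[k]] <- img
  }

  # ground truth per compression step (absolute, from zero load)
  strain_steps <- lapply(surface_pressures, function(P) P * S)
  disp_steps <- lapply(surface_pressures, function(P) P * U1)
  # aliasing per consecutive pair: interframe phase change across one axial
  # resolution cell must stay below pi
  dP <- diff(surface_pressures)
  alias <- vapply(seq_along(dP), function(k) {
    max(k4pn * dP[k] * S * system$axial_resolution_um) > pi
  }, logical(1))

  structure(list(frames = frames,
                 pressures = surface_pressures,
                 system = system,
                 seed = as.integer(seed),
                 ground_truth = list(strain = strain_steps,
                                     displacement_um = disp_steps,
                                     applied_pressure_kpa = surface_pressures,
                                     modulus_kpa = Emat,
                                     alias_flag = alias),
                 grid = g),
            class = "oce_series")
}
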