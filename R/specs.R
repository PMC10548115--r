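#' Swept-source PS-OCT system description
#'
#' Captures the acquisition parameters of the simulated probe: a 1310 nm
#' swept source at 50 kHz with two alternating launch polarization states,
#' so that consecutive A-lines of the same launch state are separated by
#' `state_period_T = 2 / sweep_rate` (40 us at the default rate). The
#' needle-tip reflection sits at a fixed depth pixel `tip_pixel`; tissue
#' occupies the pixels below it at `axial_pitch_tissue` micrometres per
#' pixel.
#'
#' The depth window actually reconstructed is `k_samples / 2` pixels, i.e.
#' `(k_samples / 2 - tip_pixel) * axial_pitch_tissue` micrometres of
#' tissue below the tip; `tissue_range` is an upper bound on the window
#' and is clipped to what the sampling supports.
#'
#' @param center_wavelength_um source center wavelength (um).
#' @param k_samples wavenumber samples per sweep (even).
#' @param sweep_rate A-line rate in Hz. Launch states alternate every
#'   sweep, so the same-state period is `2 / sweep_rate` seconds.
#' @param tissue_range_um requested tissue depth allocation (um).
#' @param axial_pitch_tissue_um depth pixel pitch in tissue (um/pixel).
#' @param tissue_index_n bulk tissue group refractive index.
#' @param tip_pixel zero-based depth pixel index of the needle-tip
#'   reflection.
#' @param resolution_um_air axial resolution (FWHM, in air) implied by the
#'   source spectral envelope; sets the simulated Gaussian source
#'   bandwidth.
#' @param tip_reflectivity amplitude of the needle-tip reflection relative
#'   to the mean tissue scatterer amplitude.
#' @return object of class `system_spec`.
#' @export
system_spec <- function(center_wavelength_um = 1.310,
                        k_samples = 1024L,
                        sweep_rate = 50e3,
                        tissue_range_um = 4700,
                        axial_pitch_tissue_um = 1.87,
                        tissue_index_n = 1.37,
                        tip_pixel = 8L,
                        resolution_um_air = 10.6,
                        tip_reflectivity = 10) {
  k_samples <- as.integer(k_samples)
  if (k_samples < 16L || k_samples %% 2L != 0L)
    stop_field("k_samples", "must be an even integer >= 16")
  if (sweep_rate <= 0) stop_field("sweep_rate", "must be positive")
  tip_pixel <- as.integer(tip_pixel)
  npix <- k_samples %/% 2L
  if (tip_pixel < 0L || tip_pixel >= npix)
    stop_field("tip_pixel", "must lie within the reconstructed depth range")
  if (axial_pitch_tissue_um <= 0) stop_field("axial_pitch_tissue_um", "> 0")
  if (tissue_index_n < 1) stop_field("tissue_index_n", "must be >= 1")
  s <- list(
    center_wavelength_um = center_wavelength_um,
    k_samples = k_samples,
    sweep_rate = sweep_rate,
    state_period_T = 2 / sweep_rate,
    tissue_range_um = tissue_range_um,
    axial_pitch_tissue_um = axial_pitch_tissue_um,
    tissue_index_n = tissue_index_n,
    tip_pixel = tip_pixel,
    resolution_um_air = resolution_um_air,
    tip_reflectivity = tip_reflectivity
  )
  class(s) <- "system_spec"
  s
}

# number of reconstructed depth pixels
n_depth_pixels <- function(sys) sys$k_samples %/% 2L

# tissue window (um) imaged below the needle tip
tissue_window_um <- function(sys) {
  win <- (n_depth_pixels(sys) - sys$tip_pixel - 1L) * sys$axial_pitch_tissue_um
  min(win, sys$tissue_range_um)
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<system_spec> %.0f nm, %d k-samples, %.0f kHz sweep, ",
           "T = %.0f us, pitch = %.2f um, n = %.2f, tip pixel %d, ",
           "tissue window %.0f um\n"),
    x$center_wavelength_um * 1e3, x$k_samples, x$sweep_rate / 1e3,
    x$state_period_T * 1e6, x$axial_pitch_tissue_um, x$tissue_index_n,
    x$tip_pixel, tissue_window_um(x)))
  invisible(x)
}

#' Noise model for the fringe simulator
#'
#' @param detector_noise_rel additive Gaussian fringe noise, standard
#'   deviation relative to the mean scatterer amplitude.
#' @param jitter_prob probability per A-line of a common-mode laser phase
#'   glitch.
#' @param jitter_magnitude_rad glitch magnitude (radians); must exceed the
#'   Doppler gate (2.5 rad) so glitches remain gateable.
#' @param drift_rad_per_s slow common-mode phase drift rate.
#' @param seed RNG seed for all noise draws.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(detector_noise_rel = 0.05,
                       jitter_prob = 0.005,
                       jitter_magnitude_rad = 3.0,
                       drift_rad_per_s = 0.1,
                       seed = 1L) {
  if (detector_noise_rel < 0) stop_field("detector_noise_rel", ">= 0")
  if (jitter_prob < 0 || jitter_prob > 1) stop_field("jitter_prob", "in [0,1]")
  if (jitter_prob > 0 && jitter_magnitude_rad <= 2.5)
    stop_field("jitter_magnitude_rad",
               "must exceed 2.5 rad so glitches can be gated")
  if (drift_rad_per_s < 0) stop_field("drift_rad_per_s", ">= 0")
  n <- list(detector_noise_rel = detector_noise_rel,
            jitter_prob = jitter_prob,
            jitter_magnitude_rad = jitter_magnitude_rad,
            drift_rad_per_s = drift_rad_per_s,
            seed = as.integer(seed))
  class(n) <- "noise_spec"
  n
}

#' Zero-noise convenience spec
#' @param seed RNG seed (unused when all noise terms are zero, kept for
#'   reproducibility bookkeeping).
#' @return a `noise_spec` with every noise term set to zero.
#' @export
noise_free <- function(seed = 1L) {
  noise_spec(detector_noise_rel = 0, jitter_prob = 0,
             jitter_magnitude_rad = 3.0, drift_rad_per_s = 0, seed = seed)
}

#' Doppler odometry parameters
#'
#' Houses the constants of the phase-to-motion conversion
#' `v = lambda_c * dphi / (4 pi n T)` and `d = v * T`, together with the
#' processing chain settings: the jitter gate, the causal sliding median
#' window, and the depth span of the below-tip mean.
#'
#' `guard_px` positions the start of the depth-averaging span below the
#' needle-tip reflection peak: the tip response has a finite axial point
#' spread (several pixels at 10.6 um resolution), and pixels inside the
#' static tip response carry no tissue motion. The averaging span is
#' pixels `tip_pixel + guard_px + 1` through
#' `tip_pixel + guard_px + depth_span`.
#'
#' @param center_wavelength_um source center wavelength (um).
#' @param tissue_index_n assumed tissue refractive index (1.37 for all
#'   tissues; adipose deviates by up to ~7 percent).
#' @param state_period_T time between consecutive same-launch-state
#'   A-lines (s).
#' @param gate_rad phase differences with magnitude above this are
#'   classified as laser phase jitter and set to zero (2.5 rad).
#' @param median_window causal sliding median length in same-state
#'   intervals (72).
#' @param depth_span number of pixels averaged below the tip surface (46,
#'   i.e. 86 um at 1.87 um pitch).
#' @param tip_pixel zero-based depth pixel of the tip reflection.
#' @param guard_px pixels skipped below the tip-reflection peak before the
#'   averaging span begins.
#' @param state launch state (0 or 1) whose A-line stream feeds the
#'   Doppler estimate.
#' @param channel `"weighted"` combines both detection channels by their
#'   power; `"best"` uses the channel with higher mean power.
#' @return object of class `doppler_params`.
#' @export
doppler_params <- function(center_wavelength_um = 1.310,
                           tissue_index_n = 1.37,
                           state_period_T = 40e-6,
                           gate_rad = 2.5,
                           median_window = 72L,
                           depth_span = 46L,
                           tip_pixel = 8L,
                           guard_px = 8L,
                           state = 0L,
                           channel = c("weighted", "best")) {
  if (gate_rad <= 0 || gate_rad >= pi)
    stop_field("gate_rad", "must lie in (0, pi): no unwrapping is performed")
  if (median_window < 1) stop_field("median_window", ">= 1")
  if (depth_span < 1) stop_field("depth_span", ">= 1")
  if (guard_px < 0) stop_field("guard_px", ">= 0")
  p <- list(center_wavelength_um = center_wavelength_um,
            tissue_index_n = tissue_index_n,
            state_period_T = state_period_T,
            gate_rad = gate_rad,
            median_window = as.integer(median_window),
            depth_span = as.integer(depth_span),
            tip_pixel = as.integer(tip_pixel),
            guard_px = as.integer(guard_px),
            state = as.integer(state),
            channel = match.arg(channel))
  class(p) <- "doppler_params"
  p
}

#' Doppler parameters matched to a system spec
#' @param sys a [system_spec()].
#' @param ... overrides passed to [doppler_params()].
#' @return a `doppler_params` sharing the system's wavelength, index,
#'   same-state period and tip pixel.
#' @export
doppler_params_for <- function(sys, ...) {
  args <- list(center_wavelength_um = sys$center_wavelength_um,
               tissue_index_n = sys$tissue_index_n,
               state_period_T = sys$state_period_T,
               tip_pixel = sys$tip_pixel)
  over <- list(...)
  args[names(over)] <- over
  do.call(doppler_params, args)
}

#' Velocity corresponding to the jitter gate
#'
#' The axial speed at which the same-state phase step equals the gate:
#' any faster apparent motion is classified as laser phase jitter.
#'
#' @param params a [doppler_params()].
#' @return gate velocity in um/s.
#' @export
gate_velocity <- function(params) {
  to_velocity(params$gate_rad, params)
}
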