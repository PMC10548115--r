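# Shared fixture builders. All fixtures are generated in code; sizes are
# kept small (decimated sweep rates, 128 k-samples) so the suite stays
# fast while exercising the full fringe-level chain.

quick_sys <- function(decimation = 5, k_samples = 128L, tip_pixel = 8L, ...) {
  system_spec(k_samples = k_samples, sweep_rate = 50e3 / decimation,
              tip_pixel = tip_pixel, ...)
}

uniform_phantom <- function(depth_um = 1500, dn = 0, axis = 0, seed = 2,
                            spacing = 5, att = 0.8, refl = 1) {
  build_phantom("custom", seed = seed,
                layers = list(layer_spec(depth_um, refl, att, dn, axis)),
                scatterer_spacing_um = spacing)
}

stationary_motion <- function(duration_s = 0.05) {
  make_motion("custom", breakpoints = cbind(c(0, duration_s), c(0, 0)))
}

constant_motion <- function(speed_um_s, duration_s) {
  make_motion("custom",
              breakpoints = cbind(c(0, duration_s),
                                  c(0, speed_um_s * duration_s)))
}

# minimal synthetic tomogram for unit tests that bypass the simulator
fake_tomogram <- function(H, V = H, sys = quick_sys(k_samples = 2L * nrow(H)),
                          dt = sys$state_period_T / 2) {
  n <- ncol(H)
  structure(list(full = list(H = H, V = V), bins = NULL, nbins = 1L,
                 state = as.integer((seq_len(n) - 1) %% 2L),
                 time = (seq_len(n) - 1) * dt, sys = sys),
            class = "binned_tomogram")
}

fake_series <- function(dphi, interval_s = 40e-6) {
  structure(list(dphi = dphi,
                 time = seq_len(ncol(dphi)) * interval_s,
                 interval_s = interval_s, state = 0L),
            class = "phase_difference_series")
}

# minimal polarimetry profiles for mapping tests
fake_profiles <- function(intensity, retardation = intensity * 0,
                          axis = intensity * 0, mask = NULL,
                          time = NULL, pitch = 1.87, tip_pixel = 0L) {
  structure(list(intensity_db = intensity, retardation = retardation,
                 axis_deg = axis,
                 mask = mask %||% (intensity > -Inf),
                 time = time %||% (seq_len(ncol(intensity)) * 1e-3),
                 pitch_um = pitch, tip_pixel = as.integer(tip_pixel),
                 reference_pixel = as.integer(tip_pixel), nbins = 1L),
            class = "polarimetry_profiles")
}

fake_track <- function(p_um, time, params = doppler_params()) {
  d <- c(p_um[1], diff(p_um))
  structure(list(dphi_tip = d * 4 * pi * 1.37 / 1.310,
                 velocity_um_s = d / diff(time[1:2]),
                 displacement_um = d, tip_depth_um = p_um,
                 time = time, gate_hit_rate = 0, params = params),
            class = "tip_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
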