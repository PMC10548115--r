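#' Same-state phase-difference series
#'
#' For one launch state, computes per depth pixel the wrapped phase of the
#' product of each complex A-line with the conjugate of its same-state
#' predecessor (full-spectrum tomogram). The two detection channels are
#' either combined by their power (Kasai-style weighted sum of the pair
#' products) or the stronger channel alone is used.
#'
#' @param tom a [reconstruct_tomogram()] output.
#' @param state launch state (0 or 1) to difference.
#' @param channel `"weighted"` or `"best"`.
#' @return object of class `phase_difference_series`: `$dphi` (matrix,
#'   depth pixels x intervals, radians in (-pi, pi\]), `$time` (s, at the
#'   later A-line of each interval), `$interval_s`.
#' @export
phase_difference <- function(tom, state = 0L,
                             channel = c("weighted", "best")) {
  channel <- match.arg(channel)
  idx <- which(tom$state == state)
  if (length(idx) < 2)
    stop_field("tom", "need at least 2 A-lines of the chosen launch state")
  H <- tom$full$H[, idx, drop = FALSE]
  V <- tom$full$V[, idx, drop = FALSE]
  m <- length(idx)
  ppH <- H[, -1, drop = FALSE] * Conj(H[, -m, drop = FALSE])
  ppV <- V[, -1, drop = FALSE] * Conj(V[, -m, drop = FALSE])
  pp <- switch(channel,
    weighted = ppH + ppV,
    best = if (mean(Mod(H)^2) >= mean(Mod(V)^2)) ppH else ppV)
  out <- list(dphi = Arg(pp),
              time = tom$time[idx][-1],
              interval_s = tom$time[idx][2] - tom$time[idx][1],
              state = as.integer(state))
  class(out) <- "phase_difference_series"
  out
}

#' Jitter gate
#'
#' Phase differences whose magnitude exceeds `gate_rad` correspond to
#' apparent motion faster than the needle can move and are classified as
#' laser phase jitter: they are set to exactly zero. Values at the gate
#' are retained (strict inequality); gating is on the magnitude, since
#' retraction produces negative phase differences of equal physical
#' meaning.
#'
#' @param series a [phase_difference()] output.
#' @param gate_rad gate threshold (radians, default 2.5).
#' @return the series with gated entries zeroed.
#' @export
jitter_gate <- function(series, gate_rad = 2.5) {
  series$dphi[abs(series$dphi) > gate_rad] <- 0
  series
}

#' Causal sliding temporal median
#'
#' Per depth pixel independently, replaces each sample by the median of
#' the most recent `window` intervals (the window always consists of past
#' samples up to and including the current one; start-up positions with a
#' shorter history use all available past samples). This removes the
#' zeroes injected by the jitter gate while retaining real changes in the
#' motion-induced phase difference.
#'
#' @param series a phase-difference series.
#' @param window window length in same-state intervals (default 72,
#'   i.e. 2.88 ms at the 40 us same-state period).
#' @return the filtered series.
#' @export
temporal_median <- function(series, window = 72L) {
  series$dphi <- causal_median_mat(series$dphi, as.integer(window))
  series
}

#' Tip-reference phase-drift correction
#'
#' The needle-tip reflection sits at a constant delay, so any phase
#' difference observed there is common-mode drift; it is subtracted from
#' the phase difference at every depth at or below the tip pixel (rows
#' above the tip are left unchanged). The output at the tip pixel is
#' exactly zero.
#'
#' @param series a phase-difference series.
#' @param tip_pixel zero-based depth pixel of the tip reflection.
#' @return the corrected series, rewrapped to (-pi, pi\].
#' @export
tip_reference_correct <- function(series, tip_pixel) {
  npix <- nrow(series$dphi)
  if (tip_pixel < 0 || tip_pixel >= npix)
    stop_field("tip_pixel", "outside the depth range")
  r <- tip_pixel + 1L
  rows <- r:npix
  ref <- series$dphi[r, ]
  series$dphi[rows, ] <- wrap_pi(series$dphi[rows, , drop = FALSE] -
                                   rep(ref, each = length(rows)))
  series
}

#' Depth-averaged tip phase difference
#'
#' Arithmetic mean of the phase difference over `depth_span` pixels
#' immediately below the tip pixel (pixels `tip_pixel + 1` through
#' `tip_pixel + depth_span`), one value per same-state interval. All
#' tissue in this shallow span moves with the needle-relative flow, so the
#' mean trades depth resolution for phase SNR.
#'
#' @param series a phase-difference series.
#' @param tip_pixel zero-based reference pixel; averaging starts one pixel
#'   below it.
#' @param depth_span number of pixels averaged (default 46, i.e. 86 um at
#'   1.87 um pitch).
#' @return numeric vector, one mean phase difference per interval.
#' @export
depth_average <- function(series, tip_pixel, depth_span = 46L) {
  npix <- nrow(series$dphi)
  lo <- tip_pixel + 2L           # zero-based tip_pixel + 1, in R indexing
  hi <- tip_pixel + 1L + depth_span
  if (lo < 1 || hi > npix)
    stop_field("depth_span", "averaging span exceeds the depth range")
  colMeans(series$dphi[lo:hi, , drop = FALSE])
}

#' Phase difference to axial velocity
#'
#' `v = lambda_c * dphi / (4 pi n T)`: the relative axial velocity of the
#' needle between two same-state A-lines, signed (positive = insertion).
#'
#' @param dphi phase difference(s), radians.
#' @param params a [doppler_params()].
#' @return velocity in um/s.
#' @export
to_velocity <- function(dphi, params) {
  params$center_wavelength_um * dphi /
    (4 * pi * params$tissue_index_n * params$state_period_T)
}

#' Phase difference to axial displacement
#'
#' `d = lambda_c * dphi / (4 pi n)`: the displacement of the needle over
#' one same-state interval; equals `to_velocity(dphi) * T`.
#'
#' @inheritParams to_velocity
#' @return displacement in um.
#' @export
to_displacement <- function(dphi, params) {
  params$center_wavelength_um * dphi / (4 * pi * params$tissue_index_n)
}

#' Integrate per-interval displacements into tip position
#'
#' Cumulative sum of the per-interval displacements with `p(0) = 0` before
#' the first interval; positive = deeper below the tissue surface.
#'
#' @param d_series per-interval displacements (um).
#' @return cumulative tip depth (um), same length.
#' @export
integrate_position <- function(d_series) cumsum(d_series)

#' Doppler tip tracking
#'
#' The full odometry chain, in order: same-state phase differences, jitter
#' gate, causal sliding temporal median, tip-reference drift correction,
#' depth averaging below the tip, then conversion to velocity and
#' displacement and integration to absolute tip position.
#'
#' @param tom a [reconstruct_tomogram()] output.
#' @param params a [doppler_params()]; `params$tip_pixel` must match the
#'   system's tip pixel and `guard_px` sets where the averaging span
#'   starts below the tip response.
#' @return object of class `tip_track`: per-interval `$dphi_tip` (rad),
#'   `$velocity_um_s`, `$displacement_um`, `$tip_depth_um` (cumulative),
#'   `$time` (s), `$gate_hit_rate`, and the params.
#' @export
track <- function(tom, params = doppler_params_for(tom$sys)) {
  series <- phase_difference(tom, state = params$state,
                             channel = params$channel)
  pre_gate <- series$dphi
  series <- jitter_gate(series, params$gate_rad)
  gate_hit_rate <- mean(series$dphi == 0 & pre_gate != 0)
  series <- temporal_median(series, params$median_window)
  series <- tip_reference_correct(series, params$tip_pixel)
  dphi_tip <- depth_average(series, params$tip_pixel + params$guard_px,
                            params$depth_span)
  v <- to_velocity(dphi_tip, params)
  d <- to_displacement(dphi_tip, params)
  out <- list(dphi_tip = dphi_tip,
              velocity_um_s = v,
              displacement_um = d,
              tip_depth_um = integrate_position(d),
              time = series$time,
              gate_hit_rate = gate_hit_rate,
              params = params)
  class(out) <- "tip_track"
  out
}

#' @export
print.tip_track <- function(x, ...) {
  cat(sprintf(
    "<tip_track> %d intervals, peak depth %.1f um, final %.2f um, gate hits %.2f%%\n",
    length(x$tip_depth_um), max(x$tip_depth_um), tail(x$tip_depth_um, 1),
    100 * x$gate_hit_rate))
  invisible(x)
}
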