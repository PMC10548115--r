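#' Needle motion profile
#'
#' Piecewise-linear true tip position `p(t)` (um below the tissue surface)
#' given as breakpoints. True motion must stay below the Doppler jitter
#' gate's velocity (4.7 mm/s at the default system constants), otherwise
#' real motion would be indistinguishable from laser phase jitter.
#'
#' @param style `"triangle"` for a symmetric insertion/retraction ramp
#'   peaking at `max_depth_um` at `total_time_s / 2`, or `"custom"` with
#'   explicit `breakpoints`.
#' @param total_time_s total duration (s), > 0 (triangle style).
#' @param max_depth_um peak insertion depth (um), >= 0 (triangle style).
#' @param breakpoints two-column matrix or data.frame `(time_s, depth_um)`
#'   with strictly increasing times (custom style).
#' @param max_speed_um_s validation bound on the implied speed; defaults
#'   to the 4.7 mm/s gate velocity.
#' @return object of class `motion_profile`.
#' @export
make_motion <- function(style = c("triangle", "custom"),
                        total_time_s = NULL, max_depth_um = NULL,
                        breakpoints = NULL, max_speed_um_s = 4700) {
  style <- match.arg(style)
  if (style == "triangle") {
    if (is.null(total_time_s) || total_time_s <= 0)
      stop_field("total_time_s", "must be > 0")
    if (is.null(max_depth_um) || max_depth_um < 0)
      stop_field("max_depth_um", "must be >= 0")
    bp <- cbind(time_s = c(0, total_time_s / 2, total_time_s),
                depth_um = c(0, max_depth_um, 0))
  } else {
    if (is.null(breakpoints)) stop_field("breakpoints", "required for custom")
    bp <- as.matrix(breakpoints)
    if (ncol(bp) != 2) stop_field("breakpoints", "need (time_s, depth_um) columns")
    colnames(bp) <- c("time_s", "depth_um")
  }
  if (any(diff(bp[, 1]) <= 0))
    stop_field("breakpoints", "times must be strictly increasing")
  sp <- abs(diff(bp[, 2]) / diff(bp[, 1]))
  if (any(sp >= max_speed_um_s))
    stop_field("speed",
               sprintf("implied speed %.3g mm/s reaches the %.3g mm/s jitter-gate limit",
                       max(sp) / 1e3, max_speed_um_s / 1e3))
  m <- list(breakpoints = bp, style = style, max_speed_um_s = max_speed_um_s)
  class(m) <- "motion_profile"
  m
}

#' Evaluate a motion profile
#' @param motion a [make_motion()] object.
#' @param t_s times (s).
#' @return tip depth p(t) in um (clamped to the profile's time range).
#' @export
motion_position <- function(motion, t_s) {
  bp <- motion$breakpoints
  if (nrow(bp) == 1) return(rep(bp[1, 2], length(t_s)))
  approx(bp[, 1], bp[, 2], xout = t_s, rule = 2)$y
}

# peak |dp/dt| (um/s)
motion_peak_speed <- function(motion) {
  bp <- motion$breakpoints
  if (nrow(bp) == 1) return(0)
  max(abs(diff(bp[, 2]) / diff(bp[, 1])))
}

#' @export
print.motion_profile <- function(x, ...) {
  bp <- x$breakpoints
  cat(sprintf("<motion_profile> %s, %.3g s, peak depth %.0f um, peak speed %.3g mm/s\n",
              x$style, max(bp[, 1]), max(bp[, 2]), motion_peak_speed(x) / 1e3))
  invisible(x)
}
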