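# Robust local retardation slope (rad/um) just below the tip for one
# profile column: median absolute per-pixel circular step over the span.
local_ret_slope <- function(ret_col, tip_pixel, span, pitch_um, guard = 4L) {
  lo <- tip_pixel + 1L + guard
  hi <- min(length(ret_col), tip_pixel + 1L + guard + span)
  seg <- ret_col[lo:hi]
  d <- abs(diff(seg))
  d <- pmin(d, pi - d)      # retardation folds at 0 and pi
  median(d) / pitch_um
}

#' Local birefringence contrast under the needle tip
#'
#' For every state pair, estimates the magnitude of the retardation slope
#' over a shallow span below the tip (median absolute circular step per
#' pixel). Birefringent layers show a slope near
#' `4 pi Delta_n / lambda_c`; non-birefringent layers show ~0.
#'
#' @param profiles a [compute_polarimetry()] output.
#' @param span_px pixels below the tip used for the slope fit.
#' @param guard_px pixels skipped below the tip response.
#' @return numeric vector (per state pair) of |d retardation / dz| in
#'   rad/um.
#' @export
birefringence_contrast <- function(profiles, span_px = 40L, guard_px = 6L) {
  vapply(seq_len(ncol(profiles$retardation)), function(j)
    local_ret_slope(profiles$retardation[, j], profiles$tip_pixel,
                    span_px, profiles$pitch_um, guard_px), 0)
}

#' Apparent optic axis under the needle tip
#'
#' Circular mean (on doubled angles) of the axis estimate over a shallow
#' span below the tip, restricted to masked-in pixels; NA when too few
#' pixels are trustworthy.
#'
#' @inheritParams birefringence_contrast
#' @param min_px minimum trusted pixels required.
#' @return numeric vector (degrees in \[-90, 90)), NA where undefined.
#' @export
tip_axis_deg <- function(profiles, span_px = 40L, guard_px = 6L,
                         min_px = 8L) {
  lo <- profiles$tip_pixel + 2L + guard_px
  hi <- min(nrow(profiles$axis_deg), profiles$tip_pixel + 1L + guard_px + span_px)
  vapply(seq_len(ncol(profiles$axis_deg)), function(j) {
    a <- profiles$axis_deg[lo:hi, j]
    m <- profiles$mask[lo:hi, j]
    if (sum(m) < min_px) return(NA_real_)
    wrap_axis_deg(circ_mean(2 * a[m] * pi / 180) * 90 / pi)
  }, 0)
}

# run-length segmentation of a logical flag over monotone tip depth:
# returns segments with start/end depth and the flag value, merging
# segments shorter than min_len_um
segment_flag <- function(flag, depth_um, min_len_um = 100) {
  ok <- !is.na(flag)
  flag <- flag[ok]; depth_um <- depth_um[ok]
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  seg <- data.frame(value = r$values,
                    from_um = depth_um[starts],
                    to_um = depth_um[ends])
  # merge short runs into their predecessor
  keep <- (seg$to_um - seg$from_um) >= min_len_um
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg$value[i] == merged$value[nrow(merged)])
        merged$to_um[nrow(merged)] <- seg$to_um[i]
      else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  seg
}

#' Classify birefringent/non-birefringent layers along the insertion
#'
#' Thresholds the below-tip birefringence contrast at the midpoint of its
#' low/high quantiles and segments the resulting flag along the tracked
#' tip depth (insertion phase only). Recovers the alternation pattern of
#' retardance-contrast phantoms.
#'
#' @param profiles a [compute_polarimetry()] output.
#' @param track the corresponding [track()] output.
#' @param min_len_um shortest believable layer (um).
#' @param span_px,guard_px passed to [birefringence_contrast()].
#' @return data.frame of segments: `birefringent`, `from_um`, `to_um`.
#' @export
classify_retardance_layers <- function(profiles, track, min_len_um = 120,
                                       span_px = 40L, guard_px = 6L) {
  slope <- birefringence_contrast(profiles, span_px, guard_px)
  p <- approx(track$time, track$tip_depth_um, xout = profiles$time,
              rule = 2)$y
  ins <- seq_len(which.max(p))           # insertion phase
  slope <- slope[ins]; p <- p[ins]
  # temporal smoothing against speckle
  sm <- stats::runmed(slope, 2 * (length(slope) %/% 40) + 1)
  thr <- mean(quantile(sm, c(0.1, 0.9)))
  seg <- segment_flag(sm > thr, p, min_len_um)
  data.frame(birefringent = seg$value, from_um = seg$from_um,
             to_um = seg$to_um)
}

#' Detect optic-axis boundaries along the insertion
#'
#' Finds depths at which the apparent below-tip optic axis jumps by more
#' than `jump_deg`: circular means of the doubled axis angle are compared
#' across a split window scaled to `window_um` of tip travel on each side
#' (the transition region is smeared over roughly the depth-averaging span
#' plus the temporal smoothing, so the window must straddle it). Nearby
#' detections are merged. Recovers the internal boundaries of
#' axis-contrast phantoms.
#'
#' @param profiles a [compute_polarimetry()] output.
#' @param track the corresponding [track()] output.
#' @param jump_deg minimum circular axis jump (degrees).
#' @param window_um tip travel covered by each half-window.
#' @param merge_um detections closer than this are merged.
#' @return numeric vector of boundary depths (um).
#' @export
detect_axis_boundaries <- function(profiles, track, jump_deg = 20,
                                   window_um = 250, merge_um = 300) {
  ax <- tip_axis_deg(profiles)
  p <- approx(track$time, track$tip_depth_um, xout = profiles$time,
              rule = 2)$y
  ins <- seq_len(which.max(p))
  ax <- ax[ins]; p <- p[ins]
  n <- length(ax)
  travel <- max(p) - min(p)
  if (travel <= 0) return(numeric(0))
  half_win <- max(10L, min(n %/% 6L, as.integer(round(window_um * n / travel))))
  if (n < 2 * half_win + 2) return(numeric(0))
  # windowed circular means via cumulative sums (NAs contribute zero)
  s2 <- sin(2 * ax * pi / 180); c2 <- cos(2 * ax * pi / 180)
  s2[is.na(s2)] <- 0; c2[is.na(c2)] <- 0
  cs <- c(0, cumsum(s2)); cc <- c(0, cumsum(c2))
  win_mean <- function(from, to) { # vectors of window ends, inclusive
    atan2(cs[to + 1] - cs[from], cc[to + 1] - cc[from])
  }
  i <- (half_win + 1):(n - half_win)
  l <- win_mean(i - half_win, i - 1)
  r <- win_mean(i, i + half_win - 1)
  d <- abs(l - r) * 90 / pi              # doubled-angle diff -> degrees
  jump <- rep(NA_real_, n)
  jump[i] <- pmin(d, 180 - d)
  cand <- which(jump > jump_deg)
  if (!length(cand)) return(numeric(0))
  # group candidates by tip depth and take the peak-jump depth in each
  bounds <- numeric(0)
  grp_start <- 1
  for (i in seq_along(cand)) {
    last <- i == length(cand)
    if (last || p[cand[i + 1]] - p[cand[i]] > merge_um) {
      grp <- cand[grp_start:i]
      bounds <- c(bounds, p[grp[which.max(jump[grp])]])
      grp_start <- i + 1
    }
  }
  bounds
}

#' Detect void entry (epidural-space archetype)
#'
#' A void crossing is flagged at the first time the intensity at the tip
#' pixel jumps above its running baseline by `spike_db` while the
#' optic-axis information below the tip is lost. Axis loss is measured by
#' the circular coherence (resultant length of the doubled axis angles)
#' over a span below the tip: oriented tissue gives coherence near 1,
#' orderless space near 0. Returns the individual detections and their
#' co-occurrence.
#'
#' @param profiles a [compute_polarimetry()] output.
#' @param spike_db intensity jump over the pre-entry baseline (dB).
#' @param coherence_floor axis coherence below which the polarimetry
#'   signal counts as lost.
#' @param guard_px pixels skipped below the tip response.
#' @param span_px pixels over which axis coherence is evaluated.
#' @return list with `$t_spike`, `$t_axis_loss`, `$t_void` (s; NA when not
#'   detected), the tip-intensity series and the axis-coherence series.
#' @export
detect_void_entry <- function(profiles, spike_db = 8, coherence_floor = 0.6,
                              guard_px = 8L, span_px = 40L) {
  tipr <- profiles$tip_pixel + 1L
  tip_db <- profiles$intensity_db[tipr, ]
  base <- median(tip_db[seq_len(max(3L, length(tip_db) %/% 10))])
  spike <- tip_db > base + spike_db
  lo <- tipr + guard_px
  hi <- min(nrow(profiles$axis_deg), lo + span_px - 1L)
  a2 <- 2 * profiles$axis_deg[lo:hi, , drop = FALSE] * pi / 180
  coh <- sqrt(colMeans(sin(a2))^2 + colMeans(cos(a2))^2)
  lost <- coh < coherence_floor
  t_spike <- if (any(spike)) profiles$time[which(spike)[1]] else NA_real_
  t_lost <- if (any(lost)) profiles$time[which(lost)[1]] else NA_real_
  both <- spike & lost
  list(t_spike = t_spike,
       t_axis_loss = t_lost,
       t_void = if (any(both)) profiles$time[which(both)[1]] else NA_real_,
       tip_intensity_db = tip_db,
       axis_coherence = coh)
}
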