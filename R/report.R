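#' Compare a Doppler track against ground truth
#'
#' Interpolates the true tip trajectory onto the track's interval times
#' and reports the position RMSE, final-position error, peak-depth error,
#' and (when the truth carries layer boundaries) the recovered vs true
#' boundary-crossing times during insertion.
#'
#' @param track a [track()] output.
#' @param truth the `$truth` element of a [synthesize_sequence()] output
#'   (or a compatible list with `time` and `tip_depth_um`).
#' @return object of class `track_report`: `$rmse_um`,
#'   `$final_error_um`, `$peak_error_um`, `$peak_depth_um`,
#'   `$boundaries` (data.frame or NULL).
#' @export
track_report <- function(track, truth) {
  if (is.null(truth$time) || is.null(truth$tip_depth_um))
    stop_field("truth", "needs time and tip_depth_um")
  if (min(track$time) > max(truth$time) || max(track$time) < min(truth$time))
    stop_field("truth", "track and truth time bases do not overlap")
  pt <- approx(truth$time, truth$tip_depth_um, xout = track$time, rule = 2)$y
  err <- track$tip_depth_um - pt
  boundaries <- NULL
  if (!is.null(truth$layer_boundaries_um)) {
    b <- truth$layer_boundaries_um
    b <- b[b < max(pt)]
    if (length(b)) {
      t_true <- vapply(b, function(d) track$time[which(pt >= d)[1]], 0)
      t_rec <- vapply(b, function(d) {
        i <- which(track$tip_depth_um >= d)[1]
        if (is.na(i)) NA_real_ else track$time[i]
      }, 0)
      boundaries <- data.frame(depth_um = b, t_true_s = t_true,
                               t_recovered_s = t_rec,
                               dt_s = t_rec - t_true)
    }
  }
  out <- list(rmse_um = sqrt(mean(err^2)),
              final_error_um = tail(err, 1),
              peak_depth_um = max(track$tip_depth_um),
              peak_error_um = max(track$tip_depth_um) - max(pt),
              n_intervals = length(err),
              boundaries = boundaries)
  class(out) <- "track_report"
  out
}

#' @export
print.track_report <- function(x, ...) {
  cat(sprintf(
    "<track_report> RMSE %.3f um | final error %.3f um | peak %.1f um (err %.3f um) | %d intervals\n",
    x$rmse_um, x$final_error_um, x$peak_depth_um, x$peak_error_um,
    x$n_intervals))
  if (!is.null(x$boundaries)) {
    cat("  boundary crossings (um, s):\n")
    print(x$boundaries, row.names = FALSE)
  }
  invisible(x)
}

#' Write a track report as CSV
#' @param report a [track_report()] output.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- data.frame(metric = c("rmse_um", "final_error_um", "peak_depth_um",
                              "peak_error_um", "n_intervals"),
                   value = c(report$rmse_um, report$final_error_um,
                             report$peak_depth_um, report$peak_error_um,
                             report$n_intervals))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
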