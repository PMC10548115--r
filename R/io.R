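#' Write a spectral sequence to disk
#'
#' Serializes the fringes, state labels, clock, system attributes and
#' ground truth as a single R-native container mirroring the dataset
#' layout `fringes / state / time / truth/*`.
#'
#' @param seq a [synthesize_sequence()] output.
#' @param path output file path (conventionally `.rds`).
#' @return the path, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "spectral_sequence"))
  saveRDS(seq, path)
  invisible(path)
}

#' Read a spectral sequence written by [write_sequence()]
#' @param path file path.
#' @return a `spectral_sequence`.
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  x <- readRDS(path)
  if (!inherits(x, "spectral_sequence"))
    stop_field("path", "file does not contain a spectral sequence")
  x
}

#' Write polarimetry profiles
#' @param profiles a [compute_polarimetry()] output.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "polarimetry_profiles"))
  saveRDS(profiles, path)
  invisible(path)
}

#' Read polarimetry profiles
#' @param path file path.
#' @return a `polarimetry_profiles`.
#' @export
read_profiles <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "polarimetry_profiles"))
    stop_field("path", "file does not contain polarimetry profiles")
  x
}

#' Write a tip track (container + CSV)
#'
#' Writes the track object and, alongside it, a human-readable CSV with
#' columns `time_s, dphi_tip_rad, velocity_mm_s, displacement_um,
#' tip_depth_um`.
#'
#' @param track a [track()] output.
#' @param path output file path (`.rds`); the CSV replaces the extension
#'   with `.csv`.
#' @return the path, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "tip_track"))
  saveRDS(track, path)
  csv <- sub("\\.[^.]*$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  write.csv(data.frame(time_s = track$time,
                       dphi_tip_rad = track$dphi_tip,
                       velocity_mm_s = track$velocity_um_s / 1e3,
                       displacement_um = track$displacement_um,
                       tip_depth_um = track$tip_depth_um),
            csv, row.names = FALSE)
  invisible(path)
}

#' Read a tip track
#' @param path file path.
#' @return a `tip_track`.
#' @export
read_track <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "tip_track"))
    stop_field("path", "file does not contain a tip track")
  x
}
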