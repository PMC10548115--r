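#' Run configuration
#'
#' Bundles every knob of a simulate-process-render run: phantom preset,
#' motion, system and noise parameters, Doppler settings, output paths and
#' a global seed. Configurations are plain lists and can be read from a
#' YAML file; unspecified fields take the defaults below.
#'
#' @param ... fields overriding the defaults, or a single named list.
#' @param file optional YAML file to read first (explicit arguments
#'   override file values).
#' @return object of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    seed = 1L,
    preset = "spine",
    decimation = 5,            # sweep-rate decimation of the 50 kHz default
    k_samples = 128L,
    tip_pixel = 8L,
    motion = list(style = "triangle", total_time_s = 13,
                  max_depth_um = 4000),
    noise = list(detector_noise_rel = 0.05, jitter_prob = 0.005,
                 jitter_magnitude_rad = 3.0, drift_rad_per_s = 0.1),
    bins = 5L,
    frame_stride = 200L,
    out_dir = ".",
    sequence_file = "sequence.rds",
    profiles_file = "profiles.rds",
    track_file = "track.rds",
    frames_dir = "frames",
    verbose = TRUE
  )
  if (!is.null(file)) {
    if (!file.exists(file)) stop_field("file", paste("no such file:", file))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  }
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.list(dots[[1]]))
    dots <- dots[[1]]
  cfg <- utils::modifyList(cfg, dots)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

config_system <- function(cfg) {
  system_spec(k_samples = cfg$k_samples,
              sweep_rate = 50e3 / cfg$decimation,
              tip_pixel = cfg$tip_pixel)
}

config_motion <- function(cfg) {
  m <- cfg$motion
  if (identical(m$style, "custom"))
    make_motion("custom", breakpoints = do.call(rbind, m$breakpoints))
  else
    make_motion("triangle", total_time_s = m$total_time_s,
                max_depth_um = m$max_depth_um)
}

config_noise <- function(cfg) {
  n <- cfg$noise
  noise_spec(detector_noise_rel = n$detector_noise_rel,
             jitter_prob = n$jitter_prob,
             jitter_magnitude_rad = n$jitter_magnitude_rad,
             drift_rad_per_s = n$drift_rad_per_s,
             seed = cfg$seed)
}

cfg_path <- function(cfg, field) file.path(cfg$out_dir, cfg[[field]])

say <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

#' Simulate a sequence from a run configuration
#'
#' Builds the phantom, motion and noise from the configuration, runs the
#' fringe simulator, logs a phantom summary and the gate-margin check, and
#' writes the sequence container.
#'
#' @param cfg a [run_config()].
#' @return the written sequence path, invisibly.
#' @export
cli_simulate <- function(cfg) {
  sys <- config_system(cfg)
  phantom <- build_phantom(cfg$preset, seed = cfg$seed)
  motion <- config_motion(cfg)
  noise <- config_noise(cfg)
  say(cfg, "phantom '%s': %d layers, %.0f um deep", cfg$preset,
      length(phantom$layers), phantom_depth(phantom))
  gate_v <- gate_velocity(doppler_params_for(sys))
  say(cfg, "gate margin: peak speed %.3g mm/s vs gate %.3g mm/s",
      motion_peak_speed(motion) / 1e3, gate_v / 1e3)
  seq <- synthesize_sequence(phantom, motion, sys, noise)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- cfg_path(cfg, "sequence_file")
  write_sequence(seq, path)
  say(cfg, "wrote %s (%d A-lines)", path, ncol(seq$fringes$H))
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the processing pipeline from a sequence file
#'
#' reconstruct -> polarimetry -> track -> maps -> frames, persisting each
#' stage's output and logging a summary (peak depth, final position,
#' boundary-crossing times vs truth when available).
#'
#' @param cfg a [run_config()]; `cfg$sequence_file` must exist (run
#'   [cli_simulate()] first).
#' @param stop_after one of `"reconstruct"`, `"polarimetry"`, `"track"`,
#'   `"render"`: later stages are skipped.
#' @return (invisibly) list with whatever stages produced: `profiles`,
#'   `track`, `report`, `canvas`, `frame_paths`.
#' @export
cli_run <- function(cfg, stop_after = "render") {
  stages <- c("reconstruct", "polarimetry", "track", "render")
  if (!stop_after %in% stages) stop_field("stop_after", "unknown stage")
  path <- cfg_path(cfg, "sequence_file")
  if (!file.exists(path))
    stop_field("sequence_file", paste("no such file:", path))
  seq <- read_sequence(path)
  out <- list()
  tom <- run_stage("reconstruct",
                   reconstruct_tomogram(seq, bins = cfg$bins))
  if (stop_after == "reconstruct") return(invisible(out))
  profiles <- run_stage("polarimetry", compute_polarimetry(tom))
  write_profiles(profiles, cfg_path(cfg, "profiles_file"))
  out$profiles <- profiles
  if (stop_after == "polarimetry") return(invisible(out))
  tr <- run_stage("track", track(tom))
  write_track(tr, cfg_path(cfg, "track_file"))
  out$track <- tr
  say(cfg, "track: peak depth %.0f um, final %.2f um, gate hits %.2f%%",
      max(tr$tip_depth_um), tail(tr$tip_depth_um, 1),
      100 * tr$gate_hit_rate)
  if (!is.null(seq$truth)) {
    rep <- track_report(tr, seq$truth)
    out$report <- rep
    say(cfg, "vs truth: RMSE %.2f um, final error %.2f um", rep$rmse_um,
        rep$final_error_um)
  }
  if (stop_after == "track") return(invisible(out))
  canvas <- run_stage("render",
                      build_surface_canvas(profiles, tr,
                                           stride = cfg$frame_stride))
  frames <- lapply(c("intensity_db", "retardation", "axis_deg"),
                   function(ct) render_frame(canvas, contrast = ct))
  paths <- run_stage("render",
                     export_frames(frames, file.path(cfg$out_dir,
                                                     cfg$frames_dir)))
  out$canvas <- canvas
  out$frame_paths <- paths
  say(cfg, "wrote %d frames to %s", length(paths),
      file.path(cfg$out_dir, cfg$frames_dir))
  invisible(out)
}

#' Compare a stored track with stored truth
#'
#' @param track_file path written by [write_track()].
#' @param truth_file a sequence file (its `$truth` is used).
#' @param csv_out optional CSV path for the metrics table.
#' @return a [track_report()] object.
#' @export
cli_report <- function(track_file, truth_file, csv_out = NULL) {
  if (!file.exists(track_file))
    stop_field("track_file", paste("no such file:", track_file))
  if (!file.exists(truth_file))
    stop_field("truth_file", paste("no such file:", truth_file))
  tr <- read_track(track_file)
  sq <- read_sequence(truth_file)
  rep <- track_report(tr, sq$truth)
  if (!is.null(csv_out)) write_report_csv(rep, csv_out)
  rep
}
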