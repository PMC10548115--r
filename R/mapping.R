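#' Needle-referenced (M-mode) map
#'
#' Pure concatenation of successive polarimetric A-line profiles: time on
#' the horizontal axis, needle-relative depth on the vertical axis. No
#' resampling is performed; column j is the j-th profile verbatim.
#'
#' @param profiles a [compute_polarimetry()] output.
#' @return object of class `needle_map` holding the intensity (dB),
#'   retardation, axis and mask images plus the time base and pixel pitch.
#' @export
needle_referenced_map <- function(profiles) {
  m <- list(intensity_db = profiles$intensity_db,
            retardation = profiles$retardation,
            axis_deg = profiles$axis_deg,
            mask = profiles$mask,
            time = profiles$time,
            pitch_um = profiles$pitch_um,
            tip_pixel = profiles$tip_pixel)
  class(m) <- "needle_map"
  m
}

#' @export
print.needle_map <- function(x, ...) {
  cat(sprintf("<needle_map> %d depth px x %d columns, pitch %.2f um\n",
              nrow(x$retardation), ncol(x$retardation), x$pitch_um))
  invisible(x)
}

#' Surface-referenced canvas from Doppler-tracked profiles
#'
#' Remaps needle-referenced profiles into the reference frame of the
#' tissue surface using the Doppler-tracked tip position. For each time
#' column, the tip row is `round(p(t) / pitch)`; the tissue pixels below
#' the tip are written at absolute depth rows (needle-relative depth plus
#' the tip row), while rows above the current tip are frozen - they carry
#' their last-written values and are never overwritten while they remain
#' above the tip. When the needle retracts, rows re-exposed below the tip
#' resume updating; rows above the (shallower) tip stay frozen. Each
#' canvas column is the snapshot of this evolving record at that time, so
#' dwell time at a position widens the corresponding band along the time
#' axis.
#'
#' @param profiles a [compute_polarimetry()] output.
#' @param track a [track()] output sharing the acquisition time base
#'   (tracked positions are linearly interpolated onto the profile times).
#' @param pitch_um absolute-depth row pitch; defaults to the profile pixel
#'   pitch.
#' @param stride snapshot every `stride` profile columns (the canvas state
#'   still updates at every column).
#' @return object of class `surface_canvas`: matrices
#'   (absolute-depth rows x snapshots) `$intensity_db`, `$retardation`,
#'   `$axis_deg`, `$mask`, plus `$tip_row` (zero-based, per snapshot),
#'   `$time`, `$pitch_um`.
#' @export
build_surface_canvas <- function(profiles, track, pitch_um = NULL,
                                 stride = 1L) {
  pitch_um <- pitch_um %||% profiles$pitch_um
  tt <- track$time; pt <- track$tip_depth_um
  ft <- profiles$time
  if (min(ft) > max(tt) || max(ft) < min(tt))
    stop_field("track", "time bases of track and profiles do not overlap")
  if (abs(length(ft) - length(tt)) > 2 &&
      abs(length(ft) - length(tt)) > 0.1 * length(ft))
    stop_field("track", "track and profiles have incompatible time bases")
  p_cols <- approx(tt, pt, xout = ft, rule = 2)$y
  npix <- nrow(profiles$retardation)
  nwin <- npix - profiles$tip_pixel          # rows written below the tip
  tip_rows <- pmax(0L, as.integer(round(p_cols / pitch_um)))
  nrows <- max(tip_rows) + nwin
  cols <- seq(1L, length(ft), by = as.integer(stride))
  nf <- length(cols)
  cv <- list(intensity_db = matrix(NA_real_, nrows, nf),
             retardation = matrix(NA_real_, nrows, nf),
             axis_deg = matrix(NA_real_, nrows, nf),
             mask = matrix(FALSE, nrows, nf))
  state <- list(intensity_db = rep(NA_real_, nrows),
                retardation = rep(NA_real_, nrows),
                axis_deg = rep(NA_real_, nrows),
                mask = rep(FALSE, nrows))
  src_rows <- (profiles$tip_pixel + 1L):npix    # needle-relative, R indexing
  f <- 0L
  for (j in seq_along(ft)) {
    r0 <- tip_rows[j]                           # zero-based tip row
    dst <- (r0 + 1L):(r0 + nwin)
    state$intensity_db[dst] <- profiles$intensity_db[src_rows, j]
    state$retardation[dst] <- profiles$retardation[src_rows, j]
    state$axis_deg[dst] <- profiles$axis_deg[src_rows, j]
    state$mask[dst] <- profiles$mask[src_rows, j]
    if (f < nf && j == cols[f + 1L]) {
      f <- f + 1L
      cv$intensity_db[, f] <- state$intensity_db
      cv$retardation[, f] <- state$retardation
      cv$axis_deg[, f] <- state$axis_deg
      cv$mask[, f] <- state$mask
    }
  }
  out <- list(intensity_db = cv$intensity_db,
              retardation = cv$retardation,
              axis_deg = cv$axis_deg,
              mask = cv$mask,
              tip_row = tip_rows[cols],
              time = ft[cols],
              pitch_um = pitch_um,
              stride = as.integer(stride))
  class(out) <- "surface_canvas"
  out
}

#' @export
print.surface_canvas <- function(x, ...) {
  cat(sprintf("<surface_canvas> %d rows x %d snapshots, pitch %.2f um, max tip row %d\n",
              nrow(x$retardation), ncol(x$retardation), x$pitch_um,
              max(x$tip_row)))
  invisible(x)
}

#' Rendering style for surface-referenced frames
#'
#' @param db_range intensity display range (dB).
#' @param tip_line_px thickness of the dark tip-boundary line (rows).
#' @param background RGB in \[0,1\] for unwritten cells.
#' @return list of style settings.
#' @export
render_style <- function(db_range = c(-10, 40), tip_line_px = 3L,
                         background = c(0.15, 0.15, 0.15)) {
  list(db_range = db_range, tip_line_px = as.integer(tip_line_px),
       background = background)
}

colorize <- function(x, contrast, style) {
  nr <- nrow(x); nc <- ncol(x)
  rgb_arr <- array(rep(style$background, each = nr * nc), c(nr, nc, 3))
  ok <- is.finite(x)
  if (!any(ok)) return(rgb_arr)
  if (contrast == "intensity_db") {
    v <- clamp((x - style$db_range[1]) / diff(style$db_range), 0, 1)
    for (ch in 1:3) { p <- rgb_arr[, , ch]; p[ok] <- v[ok]; rgb_arr[, , ch] <- p }
  } else if (contrast == "retardation") {
    pal <- t(col2rgb(hcl.colors(256, "Viridis")) / 255)
    idx <- pmin(255L, pmax(0L, as.integer(round(x / pi * 255))))
    for (ch in 1:3) {
      p <- rgb_arr[, , ch]; p[ok] <- pal[idx[ok] + 1L, ch]
      rgb_arr[, , ch] <- p
    }
  } else { # axis: cyclic hue over [-90, 90)
    hue <- ((x[ok] + 90) %% 180) / 180
    col <- col2rgb(hsv(pmin(pmax(hue, 0), 0.9999), 0.9, 0.9)) / 255
    for (ch in 1:3) {
      p <- rgb_arr[, , ch]; p[ok] <- col[ch, ]
      rgb_arr[, , ch] <- p
    }
  }
  rgb_arr
}

#' Render one surface-referenced video frame
#'
#' Renders the canvas history up to snapshot `frame`, mirrors it about the
#' needle's center line (purely for visual symmetry; the mirror carries no
#' information), and draws the tip boundary as a thick dark line
#' separating traversed tissue (above) from tissue still below the tip.
#' Frame width is `2 * frame + 1` columns (history, separator, mirrored
#' history).
#'
#' @param canvas a [build_surface_canvas()] output.
#' @param frame snapshot index (1-based) up to which history is drawn.
#' @param contrast one of `"intensity_db"`, `"retardation"`, `"axis_deg"`.
#' @param style a [render_style()].
#' @param apply_mask gray out cells whose polarimetry mask is FALSE (for
#'   retardation/axis contrasts).
#' @return RGB raster array (rows x (2*frame+1) x 3), values in \[0, 1\].
#' @export
render_frame <- function(canvas, frame = ncol(canvas$retardation),
                         contrast = c("intensity_db", "retardation",
                                      "axis_deg"),
                         style = render_style(), apply_mask = TRUE) {
  contrast <- match.arg(contrast)
  stopifnot(frame >= 1, frame <= ncol(canvas$retardation))
  img <- canvas[[contrast]][, seq_len(frame), drop = FALSE]
  if (apply_mask && contrast != "intensity_db")
    img[!canvas$mask[, seq_len(frame), drop = FALSE]] <- NA_real_
  ras <- colorize(img, contrast, style)
  # tip boundary: dark line at the tip row of each column
  nr <- dim(ras)[1]
  for (j in seq_len(frame)) {
    rows <- canvas$tip_row[j] + seq_len(style$tip_line_px)
    rows <- rows[rows <= nr]
    ras[rows, j, ] <- 0
  }
  sep <- array(0, c(nr, 1, 3))
  mirrored <- ras[, rev(seq_len(frame)), , drop = FALSE]
  out <- array(0, c(nr, 2 * frame + 1, 3))
  out[, seq_len(frame), ] <- mirrored
  out[, frame + 1, ] <- sep
  out[, (frame + 2):(2 * frame + 1), ] <- ras
  out
}

#' Export rendered frames as numbered PNG files
#'
#' @param frames list of RGB raster arrays (as from [render_frame()]).
#' @param directory output directory (created if missing).
#' @param prefix filename prefix.
#' @return (invisibly) character vector of written PNG paths; a
#'   `manifest.txt` listing the frames in time order is written alongside.
#' @export
export_frames <- function(frames, directory, prefix = "frame") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(directory, sprintf("%s_%06d.png", prefix, i))
    png::writePNG(frames[[i]], paths[i])
  }
  manifest <- file.path(directory, "manifest.txt")
  writeLines(basename(paths), manifest)
  invisible(paths)
}
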