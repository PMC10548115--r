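# Rotate vectors (vx,vy,vz) by unit quaternions (qw,qx,qy,qz), elementwise.
quat_rotate <- function(qw, qx, qy, qz, vx, vy, vz) {
  # t = 2 q_vec x v ; v' = v + qw t + q_vec x t
  tx <- 2 * (qy * vz - qz * vy)
  ty <- 2 * (qz * vx - qx * vz)
  tz <- 2 * (qx * vy - qy * vx)
  list(x = vx + qw * tx + (qy * tz - qz * ty),
       y = vy + qw * ty + (qz * tx - qx * tz),
       z = vz + qw * tz + (qx * ty - qy * tx))
}

# Elementwise rotation estimation from two Poincare vector pairs:
# reference pair (a, c) is carried to the depth pair (b, d). Returns the
# rotation angle in [0, pi] and the rotation-axis QU azimuth halved
# (degrees in [-90, 90)). All inputs are equally-shaped arrays.
stokes_rotation <- function(ax, ay, az, bx, by, bz,
                            cx, cy, cz, dx, dy, dz) {
  eps <- 1e-9
  # step 1: rotation taking a -> b about a x b
  ux <- ay * bz - az * by
  uy <- az * bx - ax * bz
  uz <- ax * by - ay * bx
  s <- sqrt(ux^2 + uy^2 + uz^2)
  co <- clamp(ax * bx + ay * by + az * bz, -1, 1)
  a1 <- atan2(s, co)
  ok <- s > eps
  # degenerate: a ~ b -> identity; a ~ -b -> pi about any axis normal to a
  nx <- ifelse(ok, ux / pmax(s, eps), -ay)
  ny <- ifelse(ok, uy / pmax(s, eps), ax)
  nz <- ifelse(ok, uz / pmax(s, eps), 0)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  bad <- !ok & co < 0 & nn < eps    # a along z: use x axis
  nx <- ifelse(bad, 1, nx / pmax(nn, eps))
  ny <- ifelse(bad, 0, ny / pmax(nn, eps))
  nz <- ifelse(bad, 0, nz / pmax(nn, eps))
  a1 <- ifelse(ok, a1, ifelse(co > 0, 0, pi))
  q1w <- cos(a1 / 2); sn <- sin(a1 / 2)
  q1x <- sn * nx; q1y <- sn * ny; q1z <- sn * nz
  # step 2: rotate c, then align its component normal to b with d's
  cp <- quat_rotate(q1w, q1x, q1y, q1z, cx, cy, cz)
  bc <- bx * cp$x + by * cp$y + bz * cp$z
  ex <- cp$x - bc * bx; ey <- cp$y - bc * by; ez <- cp$z - bc * bz
  bd <- bx * dx + by * dy + bz * dz
  fx <- dx - bd * bx; fy <- dy - bd * by; fz <- dz - bd * bz
  cross_b <- bx * (ey * fz - ez * fy) + by * (ez * fx - ex * fz) +
    bz * (ex * fy - ey * fx)
  beta <- atan2(cross_b, ex * fx + ey * fy + ez * fz)
  beta[sqrt(ex^2 + ey^2 + ez^2) < eps | sqrt(fx^2 + fy^2 + fz^2) < eps] <- 0
  q2w <- cos(beta / 2); sb <- sin(beta / 2)
  q2x <- sb * bx; q2y <- sb * by; q2z <- sb * bz
  # compose q = q2 * q1
  qw <- q2w * q1w - q2x * q1x - q2y * q1y - q2z * q1z
  qx <- q2w * q1x + q2x * q1w + q2y * q1z - q2z * q1y
  qy <- q2w * q1y - q2x * q1z + q2y * q1w + q2z * q1x
  qz <- q2w * q1z + q2x * q1y - q2y * q1x + q2z * q1w
  vn <- sqrt(qx^2 + qy^2 + qz^2)
  ret <- 2 * atan2(vn, abs(qw))
  sgn <- ifelse(qw < 0, -1, 1)
  axis_deg <- wrap_axis_deg(atan2(sgn * qy, sgn * qx) * 90 / pi)
  list(retardation = ret, axis_deg = axis_deg)
}

stokes_from_fields <- function(H, V) {
  # analytic-signal convention: conjugate so Jones phases appear upright
  H <- Conj(H); V <- Conj(V)
  I <- Mod(H)^2 + Mod(V)^2
  Q <- Mod(H)^2 - Mod(V)^2
  U <- 2 * Re(H * Conj(V))
  Vs <- 2 * Im(H * Conj(V))
  nrm <- pmax(sqrt(Q^2 + U^2 + Vs^2), 1e-300)
  list(x = Q / nrm, y = U / nrm, z = Vs / nrm, I = I)
}

rep_row <- function(v, nr) matrix(rep(v, each = nr), nr)

#' Polarimetric depth profiles from a binned tomogram
#'
#' For each spectral bin and each consecutive launch-state pair, forms the
#' normalized Stokes vectors of the two launch states at every depth, then
#' estimates the Poincare-sphere rotation that carries the reference-depth
#' (needle-tip) state pair to the depth-z pair. The rotation angle, folded
#' to \[0, pi\], is the cumulative round-trip phase retardation referenced
#' to the tip; half the rotation-axis QU azimuth is the apparent optic-axis
#' orientation in \[-90, 90) degrees (relative - not calibrated through
#' the fiber lead). Bins are combined by circular means on doubled angles.
#'
#' Retardation is invariant under any static unitary fiber transformation;
#' the axis is shifted by a constant offset only. Columns whose reference
#' Stokes pair is nearly degenerate (parallel states) are flagged in the
#' mask rather than raising an error.
#'
#' @param tom a [reconstruct_tomogram()] output (both launch states).
#' @param reference_pixel zero-based depth pixel of the retardation
#'   reference; defaults to the system's needle-tip pixel.
#' @param floor_db intensity noise floor (dB); axis/retardation are masked
#'   where intensity is below `floor_db + mask_margin_db`.
#' @param mask_margin_db dB margin above the floor required to trust
#'   polarimetry.
#' @param ret_floor_rad retardation below which the axis is considered
#'   undefined.
#' @param keep_bins retain per-bin estimates (for diagnostics/testing).
#' @return object of class `polarimetry_profiles` with matrices
#'   (depth pixels x state pairs) `$intensity_db`, `$retardation`,
#'   `$axis_deg`, logical `$mask` (TRUE = trustworthy), plus `$time`,
#'   `$pitch_um`, `$tip_pixel`, `$reference_pixel`.
#' @export
compute_polarimetry <- function(tom, reference_pixel = tom$sys$tip_pixel,
                                floor_db = -60, mask_margin_db = 5,
                                ret_floor_rad = 0.15, keep_bins = FALSE) {
  npix <- nrow(tom$full$H)
  if (reference_pixel < 0 || reference_pixel >= npix)
    stop_field("reference_pixel", "outside the depth range")
  i0 <- pair_indices(tom$state)
  if (!length(i0))
    stop_field("tom", "tomogram must contain both launch states")
  parts <- if (!is.null(tom$bins)) tom$bins else list(tom$full)
  r <- reference_pixel + 1L
  ret_b <- vector("list", length(parts))
  axis_b <- vector("list", length(parts))
  ref_degen <- rep(FALSE, length(i0))
  for (b in seq_along(parts)) {
    s0 <- stokes_from_fields(parts[[b]]$H[, i0, drop = FALSE],
                             parts[[b]]$V[, i0, drop = FALSE])
    s1 <- stokes_from_fields(parts[[b]]$H[, i0 + 1, drop = FALSE],
                             parts[[b]]$V[, i0 + 1, drop = FALSE])
    est <- stokes_rotation(
      rep_row(s0$x[r, ], npix), rep_row(s0$y[r, ], npix),
      rep_row(s0$z[r, ], npix),
      s0$x, s0$y, s0$z,
      rep_row(s1$x[r, ], npix), rep_row(s1$y[r, ], npix),
      rep_row(s1$z[r, ], npix),
      s1$x, s1$y, s1$z)
    ret_b[[b]] <- est$retardation
    axis_b[[b]] <- est$axis_deg
    # reference-pair degeneracy: launch states parallel on the sphere
    cx <- s0$y[r, ] * s1$z[r, ] - s0$z[r, ] * s1$y[r, ]
    cy <- s0$z[r, ] * s1$x[r, ] - s0$x[r, ] * s1$z[r, ]
    cz <- s0$x[r, ] * s1$y[r, ] - s0$y[r, ] * s1$x[r, ]
    ref_degen <- ref_degen | (sqrt(cx^2 + cy^2 + cz^2) < 0.1)
  }
  comb <- combine_bins(retardation = ret_b, axis_deg = axis_b)
  idb <- compute_intensity(tom, floor_db = floor_db)
  mask <- (idb > floor_db + mask_margin_db) &
    (comb$retardation > ret_floor_rad)
  mask[, ref_degen] <- FALSE
  out <- list(intensity_db = idb,
              retardation = comb$retardation,
              axis_deg = comb$axis_deg,
              mask = mask,
              time = tom$time[i0],
              pitch_um = tom$sys$axial_pitch_tissue_um,
              tip_pixel = tom$sys$tip_pixel,
              reference_pixel = as.integer(reference_pixel),
              nbins = length(parts),
              truth = tom$truth)
  if (keep_bins) out$per_bin <- list(retardation = ret_b, axis_deg = axis_b)
  class(out) <- "polarimetry_profiles"
  out
}

#' Combine per-bin polarimetry estimates
#'
#' Spectral-bin estimates of retardation and optic axis are combined by
#' circular means on doubled angles, which respects the mod-pi degeneracy
#' of both quantities. A single-bin input is returned unchanged.
#'
#' @param retardation list of per-bin retardation arrays (radians, in
#'   \[0, pi\]), or NULL.
#' @param axis_deg list of per-bin axis arrays (degrees in \[-90, 90)),
#'   or NULL.
#' @return list with the combined `$retardation` (in \[0, pi\]) and/or
#'   `$axis_deg` (in \[-90, 90)).
#' @export
combine_bins <- function(retardation = NULL, axis_deg = NULL) {
  out <- list()
  if (!is.null(retardation)) {
    if (length(retardation) == 1) out$retardation <- retardation[[1]]
    else {
      m <- circ_mean_mats(lapply(retardation, function(x) 2 * x))
      m[m < 0] <- m[m < 0] + 2 * pi
      out$retardation <- m / 2
    }
  }
  if (!is.null(axis_deg)) {
    if (length(axis_deg) == 1) out$axis_deg <- axis_deg[[1]]
    else {
      m <- circ_mean_mats(lapply(axis_deg, function(x) 2 * x * pi / 180))
      out$axis_deg <- wrap_axis_deg(m * 90 / pi)
    }
  }
  out
}

#' @export
print.polarimetry_profiles <- function(x, ...) {
  cat(sprintf("<polarimetry_profiles> %d depth px x %d pairs, %d bin(s), ref pixel %d\n",
              nrow(x$retardation), ncol(x$retardation), x$nbins,
              x$reference_pixel))
  invisible(x)
}
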