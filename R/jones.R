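#' Jones matrix of a linear retarder
#'
#' One-way Jones matrix of a linear retarder with phase retardance `delta`
#' (radians) and in-plane axis `theta_deg` (degrees). On the Poincare
#' sphere it rotates polarization states by `delta` about the equatorial
#' axis at azimuth `2 * theta_deg`.
#'
#' @param theta_deg axis orientation (degrees).
#' @param delta single-pass phase retardance (radians).
#' @return 2x2 complex unitary, transpose-symmetric matrix.
#' @export
jones_retarder <- function(theta_deg, delta) {
  th <- theta_deg * pi / 180
  c2 <- cos(2 * th); s2 <- sin(2 * th)
  ch <- cos(delta / 2); sh <- sin(delta / 2)
  matrix(c(ch + 1i * sh * c2, 1i * sh * s2,
           1i * sh * s2, ch - 1i * sh * c2), 2, 2)
}

#' One-way Jones matrix from the tissue surface to a depth
#'
#' Composes the phantom's layers as linear retarders in propagation order.
#' Single-pass retardance accumulated in a layer of birefringence Delta-n
#' over path `z` is `2 * pi * Delta_n * z / lambda_c`.
#'
#' @param phantom a [build_phantom()] object.
#' @param depth_um depth below the tissue surface (um).
#' @param wavelength_um vacuum wavelength (um).
#' @return 2x2 complex unitary matrix.
#' @export
jones_oneway <- function(phantom, depth_um, wavelength_um = 1.310) {
  total <- phantom_depth(phantom)
  if (depth_um < 0 || depth_um > total + 1e-9)
    stop_field("depth_um", "outside the phantom depth range")
  b <- c(0, layer_boundaries(phantom))
  J <- diag(2) + 0i
  for (i in seq_along(phantom$layers)) {
    if (depth_um <= b[i]) break
    l <- phantom$layers[[i]]
    dz <- min(depth_um, b[i + 1]) - b[i]
    if (l$birefringence > 0) {
      delta <- 2 * pi * l$birefringence * dz / wavelength_um
      J <- jones_retarder(l$axis_deg, delta) %*% J
    }
  }
  J
}

#' Cumulative round-trip Jones matrix
#'
#' Double-pass (reciprocal) Jones matrix from the tissue surface to
#' `depth_um`: `t(J) %*% J` for the one-way matrix `J`, hence
#' transpose-symmetric. Serves as the exact oracle for the polarimetry
#' reconstruction: its Poincare rotation angle is the cumulative
#' round-trip retardation `4 * pi * Delta_n * z / lambda_c` (for a single
#' layer), and its rotation-axis azimuth is twice the optic-axis
#' orientation.
#'
#' @inheritParams jones_oneway
#' @return 2x2 complex, transpose-symmetric unitary matrix.
#' @export
jones_roundtrip <- function(phantom, depth_um, wavelength_um = 1.310) {
  J <- jones_oneway(phantom, depth_um, wavelength_um)
  t(J) %*% J
}

#' Round-trip Jones matrix between two depths
#'
#' Round-trip response seen from a probe whose tip sits at `from_um`,
#' looking down to `to_um`: the layers above the tip are bypassed.
#'
#' @param phantom a phantom.
#' @param from_um tip depth (um).
#' @param to_um scatterer depth (um), `>= from_um`.
#' @param wavelength_um vacuum wavelength (um).
#' @return 2x2 complex transpose-symmetric unitary matrix.
#' @export
jones_roundtrip_between <- function(phantom, from_um, to_um,
                                    wavelength_um = 1.310) {
  if (to_um < from_um) stop_field("to_um", "must be >= from_um")
  J <- jones_oneway(phantom, to_um, wavelength_um) %*%
    solve(jones_oneway(phantom, from_um, wavelength_um))
  t(J) %*% J
}

#' Poincare rotation angle of a Jones matrix
#'
#' The rotation angle on the Poincare sphere, folded to \[0, pi\] exactly
#' as a retardation measurement folds it (values `delta` and
#' `2 * pi - delta` are indistinguishable).
#'
#' @param M 2x2 complex unitary matrix.
#' @return angle in \[0, pi\] (radians).
#' @export
jones_rotation_angle <- function(M) {
  U <- M / sqrt(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  2 * acos(clamp(abs(Re(U[1, 1] + U[2, 2]) / 2), 0, 1))
}

#' Poincare rotation-axis azimuth of a Jones matrix, as an orientation
#'
#' Extracts the rotation-axis direction of the SU(2)-normalized matrix and
#' returns half its QU-plane azimuth, i.e. the apparent optic-axis
#' orientation in degrees in \[-90, 90). Undefined (NA) when the rotation
#' angle is ~0 or ~pi.
#'
#' @param M 2x2 complex unitary matrix.
#' @return orientation in degrees, or NA when degenerate.
#' @export
jones_axis_deg <- function(M) {
  U <- M / sqrt(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  tr2 <- Re(U[1, 1] + U[2, 2]) / 2
  if (tr2 < 0) U <- -U  # representative with rotation angle in [0, pi]
  s <- sin(acos(clamp(abs(tr2), 0, 1)))
  if (s < 1e-6) return(NA_real_)
  nQ <- Re(1i * (U[1, 1] - U[2, 2]) / (2 * s))
  nU <- Re(1i * (U[1, 2] + U[2, 1]) / (2 * s))
  wrap_axis_deg(atan2(nU, nQ) * 90 / pi)
}
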