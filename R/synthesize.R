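# random SU(2) matrix (Haar-ish) for the fiber-lead transformation
random_unitary2 <- function(seed) {
  with_seed(seed, {
    a <- rnorm(4)
    a <- a / sqrt(sum(a^2))
    matrix(c(a[1] + 1i * a[2], -a[3] + 1i * a[4],
             a[3] + 1i * a[4],  a[1] - 1i * a[2]), 2, 2)
  })
}

# 2x2 complex "matrix series" helpers: each matrix is a list of four
# equal-length complex vectors e11, e12, e21, e22.
mat2_mul <- function(A, B) {
  list(e11 = A$e11 * B$e11 + A$e12 * B$e21,
       e12 = A$e11 * B$e12 + A$e12 * B$e22,
       e21 = A$e21 * B$e11 + A$e22 * B$e21,
       e22 = A$e21 * B$e12 + A$e22 * B$e22)
}

#' Synthesize a PS-OCT spectral fringe sequence from a phantom
#'
#' Generates raw swept-source fringes for a forward-viewing needle probe
#' traversing a layered birefringent phantom along a motion profile. Launch
#' polarization states alternate between successive A-lines (horizontal
#' and 45-degree linear). For every A-line the discrete scatterers below
#' the tip are imaged at their optical delay relative to the needle tip;
#' each carries the round-trip Jones response of the tissue between the
#' tip and its depth, the beam-divergence roll-off, and the cumulative
#' attenuation. The needle-tip reflection sits at a constant delay
#' (`sys$tip_pixel`). Common-mode laser phase jitter and slow drift are
#' applied to whole fringes; detector noise is additive Gaussian.
#'
#' The sweep direction is chosen such that needle insertion (tissue
#' approaching the probe) yields a positive same-state phase difference,
#' hence positive Doppler displacement.
#'
#' @param phantom a [build_phantom()] object; must be at least as deep as
#'   the peak tip depth plus the imaged tissue window.
#' @param motion a [make_motion()] profile; its peak speed must stay below
#'   the system's jitter-gate velocity.
#' @param sys a [system_spec()].
#' @param noise a [noise_spec()]; [noise_free()] for exact runs.
#' @param fiber `NULL` for an identity fiber lead, `"random"` for a seeded
#'   random static unitary applied to launch and (transposed) return, or a
#'   2x2 complex unitary matrix.
#' @param fiber_seed seed used when `fiber = "random"`.
#' @param tip_boost_in_void multiplier on the tip-reflection amplitude
#'   while the tip sits inside a void layer (index-mismatch spike).
#' @param beam_zr_um depth scale of the diverging-beam amplitude roll-off.
#' @param block_size A-lines synthesized per vectorized block (memory/speed
#'   trade-off); `NULL` picks one from `k_samples`.
#' @return object of class `spectral_sequence`: real fringes per detection
#'   channel (`k_samples x n_alines` matrices `$fringes$H`, `$fringes$V`),
#'   `$state` (0/1 per A-line), `$time` (s), the specs, and `$truth` with
#'   the true tip trajectory, ideal retardation/axis depth profiles, layer
#'   boundaries and void-entry time.
#' @export
synthesize_sequence <- function(phantom, motion, sys, noise = noise_spec(),
                                fiber = NULL, fiber_seed = 1L,
                                tip_boost_in_void = 6, beam_zr_um = 400,
                                block_size = NULL) {
  lam <- sys$center_wavelength_um
  n <- sys$tissue_index_n
  K <- sys$k_samples
  npix <- n_depth_pixels(sys)
  pitch <- sys$axial_pitch_tissue_um
  pitch_o <- n * pitch
  Tss <- sys$state_period_T
  dt <- Tss / 2

  # time base and true trajectory
  total_time <- max(motion$breakpoints[, 1])
  N <- max(2L, as.integer(round(total_time / dt)) + 1L)
  times <- (seq_len(N) - 1) * dt
  state <- as.integer((seq_len(N) - 1) %% 2L)
  p <- motion_position(motion, times)

  # the gate must never be tripped by true motion
  gate_v <- lam * 2.5 / (4 * pi * n * Tss) # um/s
  if (motion_peak_speed(motion) >= gate_v)
    stop_field("motion",
               sprintf("peak speed %.3g mm/s reaches the jitter-gate velocity %.3g mm/s at T = %.0f us",
                       motion_peak_speed(motion) / 1e3, gate_v / 1e3, Tss * 1e6))

  win_um <- tissue_window_um(sys)
  if (phantom_depth(phantom) < max(p) + win_um)
    stop_field("phantom",
               sprintf("phantom depth %.0f um < peak tip depth + tissue window (%.0f um)",
                       phantom_depth(phantom), max(p) + win_um))

  # fiber lead
  Fm <- if (is.null(fiber)) diag(2) + 0i
        else if (identical(fiber, "random")) random_unitary2(fiber_seed)
        else fiber
  G <- t(Fm)                       # return path of a reciprocal fiber lead
  e_states <- list(c(1 + 0i, 0), c(1, 1) / sqrt(2))
  h <- lapply(e_states, function(e) as.vector(Fm %*% e))
  tip_out <- lapply(h, function(v) as.vector(G %*% v)) # tip reflection: identity Jones

  # k grid, descending so that insertion gives positive Doppler phase
  kc <- 2 * pi / lam
  dk <- pi / (K * pitch_o)
  kj <- kc - ((0:(K - 1)) - K / 2) * dk
  sigma_k <- 2.355 / (2 * sys$resolution_um_air)
  env <- exp(-(kj - kc)^2 / (2 * sigma_k^2))
  z_off <- pitch_o * sys$tip_pixel # optical delay of the tip reflection

  # scatterer field and per-scatterer tissue response from the surface
  sc <- phantom_scatterers(phantom)
  S <- length(sc$z)
  Q <- vector("list", S)
  for (s in seq_len(S)) {
    J <- jones_oneway(phantom, sc$z[s], lam)
    Q[[s]] <- t(J) %*% J
  }
  att_z <- attenuation_cumulative(phantom, sc$z)
  att_p <- attenuation_cumulative(phantom, p)

  # inverse one-way Jones at the tip depth, per A-line (vectorized by layer)
  bnd <- c(0, layer_boundaries(phantom))
  li <- layer_at(phantom, p)
  prefixes <- lapply(seq_along(phantom$layers), function(i)
    jones_oneway(phantom, bnd[i], lam))
  j11 <- j12 <- j21 <- j22 <- complex(N)
  for (i in unique(li)) {
    idx <- which(li == i)
    l <- phantom$layers[[i]]
    P <- prefixes[[i]]
    delta <- 2 * pi * l$birefringence * (p[idx] - bnd[i]) / lam
    th <- l$axis_deg * pi / 180
    ch <- cos(delta / 2); sh <- sin(delta / 2)
    r11 <- ch + 1i * sh * cos(2 * th); r22 <- ch - 1i * sh * cos(2 * th)
    r12 <- 1i * sh * sin(2 * th)
    j11[idx] <- r11 * P[1, 1] + r12 * P[2, 1]
    j12[idx] <- r11 * P[1, 2] + r12 * P[2, 2]
    j21[idx] <- r12 * P[1, 1] + r22 * P[2, 1]
    j22[idx] <- r12 * P[1, 2] + r22 * P[2, 2]
  }
  # unitary inverse = conjugate transpose
  B <- list(e11 = Conj(j11), e12 = Conj(j21), e21 = Conj(j12), e22 = Conj(j22))

  # void occupancy of the tip (intensity spike at the void interface)
  void_idx <- which(vapply(phantom$layers, function(l) l$is_void, TRUE))
  void_start <- if (length(void_idx)) bnd[void_idx[1]] else NA_real_
  tip_amp <- rep(sys$tip_reflectivity, N)
  if (!is.na(void_start)) {
    inside <- p >= void_start & p <= bnd[void_idx[1] + 1]
    tip_amp[inside] <- tip_amp[inside] * tip_boost_in_void
  }

  a_ref <- mean(sc$amp)
  frH <- matrix(0, K, N)
  frV <- matrix(0, K, N)
  if (is.null(block_size)) block_size <- max(512L, as.integer(4e6 / K))

  with_seed(noise$seed, {
    glitch <- rbinom(N, 1, noise$jitter_prob) *
      sample(c(-1, 1), N, replace = TRUE) *
      noise$jitter_magnitude_rad * (1 + 0.3 * runif(N))
    psi <- noise$drift_rad_per_s * times + glitch
    s0 <- as.numeric(state == 0L)

    nb <- ceiling(N / block_size)
    for (bi in seq_len(nb)) {
      tb <- ((bi - 1) * block_size + 1):min(bi * block_size, N)
      Tb <- length(tb)
      pb <- p[tb]
      svis <- which(sc$z > min(pb) & sc$z < max(pb) + win_um)
      CH <- matrix(0 + 0i, max(1L, length(svis)), Tb)
      CV <- matrix(0 + 0i, max(1L, length(svis)), Tb)
      for (k in seq_along(svis)) {
        s <- svis[k]
        dz <- sc$z[s] - pb
        sel <- which(dz > 0 & dz < win_um)
        if (!length(sel)) next
        dzs <- dz[sel]
        g <- tb[sel]
        amp <- sc$amp[s] *
          clamp(dzs / (2 * pitch), 0, 1) *
          clamp((win_um - dzs) / (8 * pitch), 0, 1) *
          (1 / sqrt(1 + (dzs / beam_zr_um)^2)) *
          exp(-(att_z[s] - att_p[g]))
        b11 <- B$e11[g]; b12 <- B$e12[g]; b21 <- B$e21[g]; b22 <- B$e22[g]
        q <- Q[[s]]
        u11 <- q[1, 1] * b11 + q[1, 2] * b21
        u12 <- q[1, 1] * b12 + q[1, 2] * b22
        u21 <- q[2, 1] * b11 + q[2, 2] * b21
        u22 <- q[2, 1] * b12 + q[2, 2] * b22
        m11 <- b11 * u11 + b21 * u21
        m12 <- b11 * u12 + b21 * u22
        m22 <- b12 * u12 + b22 * u22
        mask0 <- s0[g]
        oH <- 0 + 0i; oV <- 0 + 0i
        for (st in 1:2) {
          v1 <- m11 * h[[st]][1] + m12 * h[[st]][2]
          v2 <- m12 * h[[st]][1] + m22 * h[[st]][2]
          w <- if (st == 1) mask0 else 1 - mask0
          oH <- oH + (G[1, 1] * v1 + G[1, 2] * v2) * w
          oV <- oV + (G[2, 1] * v1 + G[2, 2] * v2) * w
        }
        CH[k, sel] <- oH * amp
        CV[k, sel] <- oV * amp
      }
      E <- env * exp(1i * 2 * n * outer(kj, sc$z[svis]))
      if (!length(svis)) E <- matrix(0 + 0i, K, 1)
      # common-mode phase enters conjugated so that the reconstructed
      # (positive-delay) phase advances by +psi
      cm <- exp(-1i * psi[tb])
      D <- exp(1i * outer(2 * kj, -n * pb)) *
        tcrossprod(exp(1i * 2 * kj * z_off), cm)
      tipc <- tip_amp[tb] * cm *
        (tip_out[[1]][1] * s0[tb] + tip_out[[2]][1] * (1 - s0[tb]))
      tipcV <- tip_amp[tb] * cm *
        (tip_out[[1]][2] * s0[tb] + tip_out[[2]][2] * (1 - s0[tb]))
      tipvec <- env * exp(1i * 2 * kj * z_off)
      FH <- (E %*% CH) * D + tcrossprod(tipvec, tipc)
      FV <- (E %*% CV) * D + tcrossprod(tipvec, tipcV)
      frH[, tb] <- Re(FH)
      frV[, tb] <- Re(FV)
      if (noise$detector_noise_rel > 0) {
        sg <- noise$detector_noise_rel * a_ref
        frH[, tb] <- frH[, tb] + matrix(rnorm(K * Tb, 0, sg), K, Tb)
        frV[, tb] <- frV[, tb] + matrix(rnorm(K * Tb, 0, sg), K, Tb)
      }
    }
  })

  # ground truth: trajectory + ideal (surface-referenced) polarimetry
  zg <- seq(0, phantom_depth(phantom), by = pitch)
  ret_true <- vapply(zg, function(z)
    jones_rotation_angle(jones_roundtrip(phantom, z, lam)), 0)
  axis_true <- vapply(phantom$layers, function(l)
    if (l$birefringence > 0) l$axis_deg else NA_real_, 0)[layer_at(phantom, zg)]
  t_void <- if (!is.na(void_start) && any(p >= void_start))
    times[which(p >= void_start)[1]] else NA_real_
  p0 <- p[state == 0L]
  max_step <- if (length(p0) >= 2) 4 * pi * n * max(abs(diff(p0))) / lam else 0

  seq_out <- list(
    fringes = list(H = frH, V = frV),
    state = state,
    time = times,
    sys = sys,
    noise = noise,
    phantom = phantom,
    fiber = Fm,
    truth = list(
      time = times,
      tip_depth_um = p,
      depth_grid_um = zg,
      retardation = ret_true,
      axis_deg = axis_true,
      layer_boundaries_um = layer_boundaries(phantom),
      void_start_um = void_start,
      void_entry_time_s = t_void,
      gate_velocity_um_s = gate_v,
      max_true_phase_step_rad = max_step
    )
  )
  class(seq_out) <- "spectral_sequence"
  seq_out
}

#' @export
print.spectral_sequence <- function(x, ...) {
  cat(sprintf("<spectral_sequence> %d A-lines x %d k-samples, %.3g s, phantom '%s'\n",
              ncol(x$fringes$H), nrow(x$fringes$H), max(x$time),
              x$phantom$preset))
  invisible(x)
}
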