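hann_window <- function(n) {
  if (n <= 1) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Spectral bin layout: nb Hann sub-bands with 50% overlap covering the
# occupied source band (+/- 2.2 sigma of the Gaussian envelope around the
# center wavenumber). Returns a list of full-length window vectors and the
# center-wavenumber scale of each bin relative to the source center.
bin_layout <- function(sys, nb) {
  K <- sys$k_samples
  pitch_o <- sys$tissue_index_n * sys$axial_pitch_tissue_um
  dk <- pi / (K * pitch_o)
  sigma_k <- 2.355 / (2 * sys$resolution_um_air)
  hw <- min(K / 2 - 1, ceiling(2.2 * sigma_k / dk))
  j_lo <- K / 2 - hw; j_hi <- K / 2 + hw      # 0-based sample indices
  span <- j_hi - j_lo + 1
  L <- max(8L, round(2 * span / (nb + 1)))
  wins <- vector("list", nb)
  centers <- numeric(nb)
  kc <- 2 * pi / sys$center_wavelength_um
  for (b in seq_len(nb)) {
    start <- round(j_lo + (b - 1) * L / 2)
    end <- min(start + L - 1, K - 1)
    w <- numeric(K)
    w[(start:end) + 1] <- hann_window(end - start + 1)
    wins[[b]] <- w
    # bin center wavenumber (k grid is descending)
    centers[b] <- kc - ((start + end) / 2 - K / 2) * dk
  }
  list(windows = wins, k_centers = centers, k_c = kc)
}

fft_halfspace <- function(fr, w, npix, block = 16384L) {
  K <- nrow(fr); N <- ncol(fr)
  out <- matrix(0 + 0i, npix, N)
  recenter <- exp(1i * pi * (0:(npix - 1)))  # undo k-offset linear phase
  nb <- ceiling(N / block)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * block + 1):min(b * block, N)
    x <- fr[, idx, drop = FALSE]
    x <- x - rep(colMeans(x), each = K)       # remove fringe DC
    Fx <- stats::mvfft(x * w)
    out[, idx] <- Fx[seq_len(npix), , drop = FALSE] * recenter
  }
  out
}

#' Reconstruct complex tomograms from spectral fringes
#'
#' Transforms each A-line fringe from wavenumber to depth and retains the
#' positive-delay half-space. With `bins > 1`, the source band is split
#' into `bins` Hann-windowed sub-bands with 50 percent overlap (spectral
#' binning, used to limit polarization-mode-dispersion artifacts in the
#' polarimetry); the full-spectrum tomogram is always retained for
#' intensity and Doppler processing.
#'
#' @param seq a [synthesize_sequence()] output (or object read back with
#'   [read_sequence()]).
#' @param bins number of spectral bins (>= 1; 5 is the standard choice).
#' @param window full-spectrum apodization: `"none"` (the simulated source
#'   envelope already apodizes), `"hann"`, or `"hamming"`.
#' @return object of class `binned_tomogram`: `$full$H`, `$full$V`
#'   (complex `n_depth_pixels x n_alines`), `$bins` (list per bin of the
#'   same layout when `bins > 1`), plus `$state`, `$time`, `$sys`.
#' @export
reconstruct_tomogram <- function(seq, bins = 5L, window = c("none", "hann",
                                                            "hamming")) {
  window <- match.arg(window)
  if (is.null(seq$state) || length(seq$state) != ncol(seq$fringes$H))
    stop_field("seq", "malformed sequence: state labels missing or wrong length")
  if (bins < 1) stop_field("bins", "must be >= 1")
  sys <- seq$sys
  K <- sys$k_samples
  npix <- n_depth_pixels(sys)
  w_full <- switch(window,
    none = rep(1, K),
    hann = hann_window(K),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(K - 1)) / (K - 1)))
  full <- list(H = fft_halfspace(seq$fringes$H, w_full, npix),
               V = fft_halfspace(seq$fringes$V, w_full, npix))
  bins_out <- NULL
  k_centers <- NULL
  if (bins > 1) {
    lay <- bin_layout(sys, as.integer(bins))
    k_centers <- lay$k_centers
    bins_out <- lapply(lay$windows, function(w)
      list(H = fft_halfspace(seq$fringes$H, w, npix),
           V = fft_halfspace(seq$fringes$V, w, npix)))
  }
  tom <- list(full = full, bins = bins_out, nbins = as.integer(bins),
              bin_k_centers = k_centers,
              state = seq$state, time = seq$time, sys = sys,
              truth = seq$truth)
  class(tom) <- "binned_tomogram"
  tom
}

# indices of state-0 A-lines immediately followed by a state-1 A-line
pair_indices <- function(state) {
  n <- length(state)
  which(state[-n] == 0L & state[-1] == 1L)
}

#' Backscattered intensity image
#'
#' Per state pair and depth: `10 log10` of the squared magnitude summed
#' over detection channels, the two launch states of the pair, and
#' spectral bins (full spectrum when the tomogram holds a single bin),
#' floored at a configurable noise floor.
#'
#' @param tom a [reconstruct_tomogram()] output.
#' @param floor_db intensity noise floor (dB).
#' @return matrix (depth pixels x state pairs) of dB values with
#'   attributes `time` (s, at the state-0 A-line of each pair) and
#'   `floor_db`.
#' @export
compute_intensity <- function(tom, floor_db = -60) {
  i0 <- pair_indices(tom$state)
  parts <- if (!is.null(tom$bins)) tom$bins else list(tom$full)
  P <- 0
  for (b in parts)
    P <- P + Mod(b$H[, i0, drop = FALSE])^2 + Mod(b$H[, i0 + 1, drop = FALSE])^2 +
      Mod(b$V[, i0, drop = FALSE])^2 + Mod(b$V[, i0 + 1, drop = FALSE])^2
  db <- 10 * log10(pmax(P, 10^(floor_db / 10)))
  attr(db, "time") <- tom$time[i0]
  attr(db, "floor_db") <- floor_db
  db
}
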