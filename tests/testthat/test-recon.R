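test_that("a single-scatterer fringe peaks at its delay pixel in every bin", {
  sys <- quick_sys(k_samples = 256L)
  # one scatterer far from others: huge spacing leaves isolated reflectors
  ph <- uniform_phantom(2000, spacing = 150, att = 0)
  sq <- synthesize_sequence(ph, stationary_motion(0.005), sys, noise_free())
  tom <- reconstruct_tomogram(sq, bins = 5)
  sc <- psoctrack:::phantom_scatterers(ph)
  z1 <- sc$z[1]
  px_expect <- sys$tip_pixel + round(z1 / sys$axial_pitch_tissue_um)
  for (b in seq_along(tom$bins)) {
    prof <- Mod(tom$bins[[b]]$H[, 1])
    prof[seq_len(sys$tip_pixel + 6)] <- 0 # ignore the tip reflection
    expect_equal(which.max(prof) - 1, px_expect, tolerance = 2)
  }
})

test_that("zero fringes give zero profiles and floor-level intensity", {
  sys <- quick_sys()
  K <- sys$k_samples; n <- 8
  sq <- structure(list(fringes = list(H = matrix(0, K, n),
                                      V = matrix(0, K, n)),
                       state = as.integer((0:(n - 1)) %% 2),
                       time = (0:(n - 1)) * sys$state_period_T / 2,
                       sys = sys),
                  class = "spectral_sequence")
  tom <- reconstruct_tomogram(sq, bins = 1)
  expect_true(all(Mod(tom$full$H) == 0))
  idb <- compute_intensity(tom, floor_db = -60)
  expect_true(all(idb == -60))
})

test_that("malformed sequences (missing state labels) raise a format error", {
  sys <- quick_sys()
  sq <- structure(list(fringes = list(H = matrix(0, sys$k_samples, 4),
                                      V = matrix(0, sys$k_samples, 4)),
                       state = NULL, time = 1:4, sys = sys),
                  class = "spectral_sequence")
  expect_error(reconstruct_tomogram(sq), "malformed")
})

test_that("doubling the field amplitude adds 6.02 dB", {
  sys <- quick_sys()
  ph <- uniform_phantom(800)
  sq <- synthesize_sequence(ph, stationary_motion(0.002), sys, noise_free())
  sq2 <- sq
  sq2$fringes <- lapply(sq$fringes, function(m) 2 * m)
  i1 <- compute_intensity(reconstruct_tomogram(sq, bins = 1))
  i2 <- compute_intensity(reconstruct_tomogram(sq2, bins = 1))
  sel <- i1 > -40 # stay clear of the floor
  expect_equal(mean(i2[sel] - i1[sel]), 20 * log10(2), tolerance = 1e-6)
})

test_that("intensity of well-separated reflectors is additive", {
  sys <- quick_sys(k_samples = 256L)
  K <- sys$k_samples
  pitch_o <- sys$tissue_index_n * sys$axial_pitch_tissue_um
  dk <- pi / (K * pitch_o)
  kj <- 2 * pi / 1.310 - ((0:(K - 1)) - K / 2) * dk
  mk <- function(z_px) cos(2 * kj * (z_px * pitch_o))
  wrap <- function(f) structure(
    list(fringes = list(H = matrix(f, K, 2), V = matrix(0, K, 2)),
         state = 0:1, time = c(0, 2e-5), sys = sys),
    class = "spectral_sequence")
  p1 <- Mod(reconstruct_tomogram(wrap(mk(40)), bins = 1)$full$H[, 1])^2
  p2 <- Mod(reconstruct_tomogram(wrap(mk(80)), bins = 1)$full$H[, 1])^2
  p12 <- Mod(reconstruct_tomogram(wrap(mk(40) + mk(80)), bins = 1)$full$H[, 1])^2
  expect_equal(sum(p12), sum(p1) + sum(p2), tolerance = 1e-6)
  expect_equal(which.max(p1) - 1, 40)
  expect_equal(which.max(p2) - 1, 80)
})

test_that("per-bin retardation estimates agree on dispersion-free fringes", {
  sys <- quick_sys(k_samples = 512L, decimation = 5)
  ph <- uniform_phantom(1400, dn = 6.8e-4, axis = 30, att = 0.3, seed = 5)
  sq <- synthesize_sequence(ph, constant_motion(300, 0.3), sys, noise_free())
  tom <- reconstruct_tomogram(sq, bins = 5)
  pol <- compute_polarimetry(tom, keep_bins = TRUE)
  mid <- sys$tip_pixel + 1 + 120
  per_bin <- vapply(pol$per_bin$retardation, function(m)
    atan2(mean(sin(2 * m[mid, ])), mean(cos(2 * m[mid, ]))) / 2, 0)
  per_bin[per_bin < 0] <- per_bin[per_bin < 0] + pi
  # bins differ by their center wavenumber (+-5%), nothing more
  expect_lt(diff(range(per_bin)) / mean(per_bin), 0.12)
})
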