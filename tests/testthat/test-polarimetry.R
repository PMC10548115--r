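test_that("non-birefringent phantoms show near-zero retardation", {
  sys <- quick_sys(k_samples = 256L, decimation = 5)
  ph <- uniform_phantom(900, dn = 0, seed = 6)
  sq <- synthesize_sequence(ph, constant_motion(300, 0.1), sys, noise_free())
  pol <- compute_polarimetry(reconstruct_tomogram(sq, bins = 5))
  rows <- (sys$tip_pixel + 10):(nrow(pol$retardation) - 10)
  expect_lt(median(pol$retardation[rows, ]), 0.08)
})

test_that("single-layer recovery matches the Jones oracle in angle and axis", {
  sys <- quick_sys(k_samples = 512L, decimation = 5)
  dn <- 6.8e-4; th <- 30
  ph <- uniform_phantom(1400, dn = dn, axis = th, att = 0.3, seed = 5)
  sq <- synthesize_sequence(ph, constant_motion(300, 0.3), sys, noise_free())
  pol <- compute_polarimetry(reconstruct_tomogram(sq, bins = 5))
  npx <- nrow(pol$retardation)
  for (off in c(60, 120, 180)) {
    r <- sys$tip_pixel + 1 + off
    z <- off * sys$axial_pitch_tissue_um
    oracle <- jones_rotation_angle(jones_roundtrip_between(ph, 0, z))
    m <- pol$retardation[r, ]
    meas <- atan2(mean(sin(2 * m)), mean(cos(2 * m))) / 2
    if (meas < 0) meas <- meas + pi
    expect_lt(abs(meas - oracle), 0.01 * pi)
    a <- pol$axis_deg[r, pol$mask[r, ]]
    am <- wrap_axis_deg(circ_mean(2 * a * pi / 180) * 90 / pi)
    expect_lt(abs(wrap_axis_deg(am - th)), 2)
  }
  # reference pixel itself carries zero retardation
  expect_lt(max(pol$retardation[sys$tip_pixel + 1, ]), 1e-6)
})

test_that("a static fiber transformation leaves retardation invariant", {
  sys <- quick_sys(k_samples = 256L, decimation = 5)
  ph <- uniform_phantom(900, dn = 8e-4, axis = 20, seed = 8)
  mo <- constant_motion(300, 0.15)
  p1 <- compute_polarimetry(reconstruct_tomogram(
    synthesize_sequence(ph, mo, sys, noise_free()), bins = 5))
  p2 <- compute_polarimetry(reconstruct_tomogram(
    synthesize_sequence(ph, mo, sys, noise_free(), fiber = "random",
                        fiber_seed = 17), bins = 5))
  rows <- (sys$tip_pixel + 15):(nrow(p1$retardation) - 15)
  d <- abs(p1$retardation[rows, ] - p2$retardation[rows, ])
  expect_lt(median(d), 0.02)
  # axis shifts by (approximately) a constant offset across depth
  off <- wrap_axis_deg(p2$axis_deg[rows, ] - p1$axis_deg[rows, ])
  spread <- abs(wrap_axis_deg(off - median(off)))
  expect_lt(median(spread), 3)
})

test_that("outputs respect their ranges and degenerate references are masked", {
  sys <- quick_sys(k_samples = 256L, decimation = 5)
  ph <- build_phantom("shrimp", 12)
  sq <- synthesize_sequence(ph, constant_motion(400, 0.1), sys,
                            noise_spec(seed = 12))
  pol <- compute_polarimetry(reconstruct_tomogram(sq, bins = 5))
  expect_true(all(pol$retardation >= 0 & pol$retardation <= pi))
  expect_true(all(pol$axis_deg >= -90 & pol$axis_deg < 90))

  # degenerate reference: both launch states identical at the tip
  K <- 64L; n <- 4L
  H <- matrix(1 + 0i, K / 2, n)
  tom <- fake_tomogram(H, H, sys = quick_sys(k_samples = K, tip_pixel = 2L))
  pol2 <- compute_polarimetry(tom, reference_pixel = 2L)
  expect_false(any(pol2$mask))
})

test_that("bin combination is idempotent, symmetric, and variance-reducing", {
  m <- matrix(runif(20, 0, pi), 4)
  expect_identical(combine_bins(retardation = list(m))$retardation, m)
  expect_equal(combine_bins(retardation = list(m, m, m))$retardation, m,
               tolerance = 1e-12)
  th <- matrix(c(30, -60, 10, 80), 2)
  comb <- combine_bins(axis_deg = list(th, -th))$axis_deg
  expect_true(all(abs(comb) < 1e-9 | abs(abs(comb) - 90) < 1e-9))
  expect_equal(comb[1, 1], 0)

  # Monte-Carlo: 5 jittered bins combine to a tighter estimate than any one
  set.seed(42)
  truth <- 50
  err_single <- matrix(NA_real_, 200, 5)
  err_comb <- numeric(200)
  for (i in 1:200) {
    bins <- lapply(1:5, function(b) truth + matrix(rnorm(1, 0, 8), 1))
    comb <- combine_bins(axis_deg = bins)$axis_deg
    err_single[i, ] <- vapply(bins, function(b) abs(b[1] - truth), 0)
    err_comb[i] <- abs(comb[1] - truth)
  }
  expect_lt(mean(err_comb), min(colMeans(err_single)))
})
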