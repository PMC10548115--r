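test_that("phase differences reproduce injected common phases", {
  K <- 32L
  n <- 8L
  base <- matrix(complex(modulus = runif(K * n / 2, 0.5, 2),
                         argument = runif(K * n / 2, -pi, pi)), K)
  # state-0 A-lines all equal -> zero phase difference
  H <- matrix(0i, K, n)
  H[, seq(1, n, 2)] <- base[, 1]
  H[, seq(2, n, 2)] <- base[, 2]
  tom <- fake_tomogram(H, sys = quick_sys(k_samples = 2L * K))
  pd <- phase_difference(tom, 0)
  expect_true(all(abs(pd$dphi) < 1e-12))
  # multiplying successive same-state A-lines by e^{i alpha} shifts all depths
  alpha <- 0.7
  H2 <- H
  for (j in seq(3, n, 2)) H2[, j] <- H2[, j - 2] * exp(1i * alpha)
  pd2 <- phase_difference(fake_tomogram(H2, sys = quick_sys(k_samples = 2L * K)), 0)
  expect_equal(max(abs(pd2$dphi - alpha)), 0, tolerance = 1e-12)
  # fewer than two same-state A-lines is an error
  expect_error(phase_difference(fake_tomogram(H[, 1:2, drop = FALSE],
                                              sys = quick_sys(k_samples = 2L * K)), 0),
               "at least 2")
})

test_that("the jitter gate zeroes |dphi| > gate and keeps the boundary", {
  s <- fake_series(matrix(c(2.6, 2.5, -2.6, 0.4, -2.5, 3.1), 2))
  g <- jitter_gate(s, 2.5)
  expect_equal(as.vector(g$dphi), c(0, 2.5, 0, 0.4, -2.5, 0))
  # idempotence
  expect_identical(jitter_gate(g, 2.5)$dphi, g$dphi)
})

test_that("causal median matches a brute-force sort and is causal", {
  set.seed(1)
  x <- matrix(rnorm(3 * 300), 3)
  w <- 72L
  out <- temporal_median(fake_series(x), w)$dphi
  brute <- function(r, t) median(x[r, max(1, t - w + 1):t])
  for (t in c(1, 5, 71, 72, 73, 150, 300))
    expect_equal(out[2, t], brute(2, t))
  # constant series with a few gated zeroes still returns the constant
  y <- matrix(1.2, 1, 200)
  y[1, sample.int(100, 10) + 50] <- 0
  expect_equal(temporal_median(fake_series(y), w)$dphi[1, 140], 1.2)
  # causality: a future change leaves earlier outputs untouched
  x2 <- x; x2[, 200] <- 99
  out2 <- temporal_median(fake_series(x2), w)$dphi
  expect_identical(out[, 1:199], out2[, 1:199])
  # shift-equivariance
  out3 <- temporal_median(fake_series(x + 0.37), w)$dphi
  expect_equal(out3, out + 0.37, tolerance = 1e-12)
})

test_that("tip referencing removes common offsets and zeroes the tip row", {
  set.seed(2)
  x <- matrix(rnorm(8 * 40, 0, 0.3), 8)
  tip <- 2L # zero-based
  a <- tip_reference_correct(fake_series(x), tip)
  offs <- rep(runif(40, -1, 1), each = 8)
  b <- tip_reference_correct(fake_series(x + matrix(offs, 8)), tip)
  expect_equal(a$dphi[(tip + 1):8, ], b$dphi[(tip + 1):8, ], tolerance = 1e-12)
  expect_true(all(a$dphi[tip + 1, ] == 0))
  expect_error(tip_reference_correct(fake_series(x), 99L), "tip_pixel")
})

test_that("depth averaging takes the arithmetic mean below the tip", {
  tip <- 3L; span <- 46L
  npx <- tip + 1L + span
  # value at zero-based pixel j is a + b*j
  a <- 0.2; b <- 0.01
  x <- matrix(rep(a + b * (0:(npx - 1)), 5), npx)
  m <- depth_average(fake_series(x), tip, span)
  expect_equal(m, rep(a + b * mean((tip + 1):(tip + span)), 5))
  expect_equal(mean((tip + 1):(tip + span)) - tip, 23.5)
  expect_equal(depth_average(fake_series(x), tip, 1L)[1], a + b * (tip + 1))
  expect_error(depth_average(fake_series(x), tip, span + 1L), "span")
})

test_that("velocity and displacement conversions follow the Doppler relations", {
  p <- doppler_params()
  expect_equal(to_velocity(2.5, p) / 1e3, 4.7, tolerance = 0.06) # mm/s
  expect_equal(to_velocity(1.0, p), 1902.3, tolerance = 0.1)     # um/s
  expect_equal(to_velocity(0, p), 0)
  expect_equal(to_displacement(2.5, p), 0.190, tolerance = 2e-3)
  for (dphi in c(-2, -0.3, 0.7, 2.4))
    expect_equal(to_velocity(dphi, p) * p$state_period_T,
                 to_displacement(dphi, p), tolerance = 1e-15)
})

test_that("position integration telescopes", {
  expect_equal(integrate_position(rep(0, 5)), rep(0, 5))
  expect_equal(integrate_position(rep(0.2, 10))[10], 2)
  d <- c(rep(0.1, 50), rep(-0.1, 50))
  expect_equal(tail(integrate_position(d), 1), 0)
})

test_that("constant speeds are recovered within 2% on noise-free runs", {
  sys <- quick_sys(decimation = 1) # full 50 kHz rate
  ph <- uniform_phantom(2200, seed = 2)
  for (v in c(800, 2200, 4200)) {
    sq <- synthesize_sequence(ph, constant_motion(v, 0.12), sys, noise_free())
    tr <- track(reconstruct_tomogram(sq, bins = 1), doppler_params_for(sys))
    sel <- 200:length(tr$velocity_um_s)
    expect_equal(mean(tr$velocity_um_s[sel]) / v, 1, tolerance = 0.02)
  }
})

test_that("symmetric insertion/retraction closes to under 0.5% of peak", {
  # full rate: the causal median lags the apex reversal by ~window/2
  # intervals, so the closure error scales with 72 * v * T
  sys <- quick_sys(decimation = 1)
  ph <- uniform_phantom(1200, seed = 3)
  peak <- 400
  mo <- make_motion("triangle", total_time_s = 1.6, max_depth_um = peak)
  sq <- synthesize_sequence(ph, mo, sys, noise_free())
  tr <- track(reconstruct_tomogram(sq, bins = 1), doppler_params_for(sys))
  expect_lt(abs(tail(tr$tip_depth_um, 1)), 0.005 * peak)
  expect_equal(max(tr$tip_depth_um), peak, tolerance = 0.02)
})

test_that("tracking is immune to common-mode drift", {
  sys <- quick_sys(decimation = 5)
  ph <- uniform_phantom(900, seed = 4)
  ns <- noise_spec(detector_noise_rel = 0, jitter_prob = 0,
                   drift_rad_per_s = 1.0, seed = 5)
  sq <- synthesize_sequence(ph, stationary_motion(1.0), sys, ns)
  tr <- track(reconstruct_tomogram(sq, bins = 1), doppler_params_for(sys))
  expect_lt(max(abs(tr$tip_depth_um)), 0.05)
})
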