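test_that("stationary needle with zero noise gives identical same-state fringes", {
  sys <- quick_sys()
  ph <- uniform_phantom(800, spacing = 20)
  sq <- synthesize_sequence(ph, stationary_motion(0.02), sys, noise_free())
  i0 <- which(sq$state == 0)
  expect_equal(sq$fringes$H[, i0[1]], sq$fringes$H[, i0[5]], tolerance = 0)
  tom <- reconstruct_tomogram(sq, bins = 1)
  pd <- phase_difference(tom, 0)
  expect_lt(max(abs(pd$dphi)), 1e-9)
})

test_that("a reflector advancing 0.1 um per same-state interval shows ~1.314 rad", {
  sys <- system_spec(k_samples = 256, tip_pixel = 8) # full rate, T = 40 us
  ph <- uniform_phantom(3000, spacing = 60, att = 0)
  v <- 0.1 / sys$state_period_T                      # 2.5 mm/s
  sq <- synthesize_sequence(ph, constant_motion(v, 0.05), sys, noise_free())
  tom <- reconstruct_tomogram(sq, bins = 1)
  pd <- phase_difference(tom, 0)
  prof <- Mod(tom$full$H[, 1])
  pk <- which.max(prof[30:110]) + 29   # a scatterer well below the tip
  expect_equal(median(pd$dphi[pk, ]), 4 * pi * 1.37 * 0.1 / 1.310,
               tolerance = 2e-3)
})

test_that("common-mode drift advances the tip-pixel phase by rate x interval", {
  sys <- quick_sys()
  ph <- uniform_phantom(800, spacing = 20)
  rate <- 0.8 # rad/s
  ns <- noise_spec(detector_noise_rel = 0, jitter_prob = 0,
                   drift_rad_per_s = rate, seed = 3)
  sq <- synthesize_sequence(ph, stationary_motion(0.05), sys, ns)
  tom <- reconstruct_tomogram(sq, bins = 1)
  pd <- phase_difference(tom, 0)
  tipr <- sys$tip_pixel + 1
  expect_equal(median(pd$dphi[tipr, ]), rate * sys$state_period_T,
               tolerance = 1e-6)
})

test_that("fringe energy is independent of birefringence settings", {
  sys <- quick_sys()
  mo <- stationary_motion(0.01)
  pw <- function(dn) {
    ph <- uniform_phantom(800, dn = dn, axis = 40, att = 0, seed = 11)
    sq <- synthesize_sequence(ph, mo, sys, noise_free())
    sum(sq$fringes$H^2 + sq$fringes$V^2)
  }
  p0 <- pw(0); p1 <- pw(1.2e-3)
  expect_equal(p1 / p0, 1, tolerance = 0.01)
})

test_that("true motion never trips the gate and over-fast motion is rejected", {
  sys <- quick_sys(decimation = 5)
  ph <- uniform_phantom(2500)
  sq <- synthesize_sequence(ph, constant_motion(600, 0.05), sys, noise_free())
  expect_lt(sq$truth$max_true_phase_step_rad, 2.5)
  # 0.98 mm/s exceeds the gate velocity at T = 200 us
  expect_error(
    synthesize_sequence(ph, constant_motion(980, 0.05), sys, noise_free()),
    "gate")
})

test_that("synthesis is deterministic for a fixed configuration", {
  sys <- quick_sys()
  ph <- build_phantom("salmon", 5)
  ns <- noise_spec(seed = 9)
  mo <- constant_motion(400, 0.02)
  s1 <- synthesize_sequence(ph, mo, sys, ns)
  s2 <- synthesize_sequence(ph, mo, sys, ns)
  expect_identical(s1$fringes, s2$fringes)
})

test_that("phantoms shallower than insertion + window are rejected", {
  sys <- quick_sys()
  ph <- uniform_phantom(300)
  expect_error(
    synthesize_sequence(ph, constant_motion(500, 0.5), sys, noise_free()),
    "phantom")
})

test_that("ground truth bundles trajectory and ideal polarimetry profiles", {
  sys <- quick_sys()
  ph <- build_phantom("shrimp", 3)
  sq <- synthesize_sequence(ph, constant_motion(400, 0.02), sys, noise_free())
  tr <- sq$truth
  expect_equal(tr$tip_depth_um, motion_position(constant_motion(400, 0.02),
                                                tr$time))
  # oracle self-agreement: exported retardation equals the Jones rotation
  idx <- seq(1, length(tr$depth_grid_um), by = 100)
  expect_equal(tr$retardation[idx],
               vapply(tr$depth_grid_um[idx], function(z)
                 jones_rotation_angle(jones_roundtrip(ph, z)), 0),
               tolerance = 1e-12)
  expect_equal(tr$layer_boundaries_um, c(1100, 2200, 3300))
})
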