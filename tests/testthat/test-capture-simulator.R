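test_that("row integrals match a composite-quadrature oracle", {
  p <- test_pulse()
  period <- 1 / p$frequency
  for (ratio in c(0.1, 0.5, 3)) {
    em <- emitter("x", lifetime = ratio * period, brightness = 1.7)
    for (t0 in c(0, 3.21e-3, 7.777e-3)) {
      t1 <- t0 + 1.4e-5
      expect_equal(emission_window_integral(t0, t1, em, p),
                   quad_emission(t0, t1, em, p), tolerance = 1e-6)
      # window wider than a period
      expect_equal(emission_window_integral(t0, t0 + 2.3 * period, em, p),
                   quad_emission(t0, t0 + 2.3 * period, em, p, panels = 1e5),
                   tolerance = 1e-6)
    }
  }
  # fast emitter, window straddling an edge
  emf <- fast_blue()
  t0 <- 0.5 * p$duty_cycle / p$frequency
  expect_equal(emission_window_integral(t0, t0 + 1e-3, emf, p),
               quad_emission(t0, t0 + 1e-3, emf, p, panels = 1e5),
               tolerance = 1e-5)
})

test_that("integrate_row_signal handles the off-window and full-period cases", {
  p <- test_pulse(1000, 0.4)  # on [0, 0.4 ms), off [0.4, 1 ms)
  sen <- sensor_config(200, 8, line_time = 1e-5, exposure_time = 1e-5,
                       photon_scale = 100)
  scene <- uniform_scene(sen, fast_blue(), background = 50)
  # row 50: window [0.5, 0.51] ms entirely inside the OFF half
  counts <- integrate_row_signal(50, scene, sen, p)
  expect_equal(unname(counts[1, ]), 50 * rep(1e-5, 3) * c(1, 1, 1))
  # window spanning exactly one period is phase-invariant for a fast emitter
  sen2 <- sensor_config(200, 8, line_time = 1e-5, exposure_time = 1e-3,
                        photon_scale = 1)
  scene2 <- uniform_scene(sen2, emitter("f", is_fast = TRUE, brightness = 2,
                                        rgb_weights = c(0, 0, 1)))
  vals <- sapply(c(0, 1e-4, 3.7e-4), function(ph) {
    integrate_row_signal(7, scene2, sen2, excitation_pulse(1000, 0.4, ph))[1, 3]
  })
  expect_equal(vals, rep(2 * 0.4 * 1e-3, 3), tolerance = 1e-12)
})

test_that("expected_signal agrees with per-row integration and scene shape is checked", {
  p <- test_pulse()
  sen <- test_sensor(n_rows = 300, n_cols = 8, photon_scale = 500)
  scene <- lum_scene(list(fast_blue(), slow_red()),
                     list(matrix(1, 300, 8), matrix(0.5, 300, 8)),
                     reflectance_map = matrix(0.2, 300, 8),
                     background = c(10, 20, 30))
  ex <- expected_signal(scene, sen, p)
  for (r in c(0, 150, 299)) {
    expect_equal(ex[r + 1, , ], integrate_row_signal(r, scene, sen, p))
  }
  bad <- sensor_config(301, 8)
  expect_error(expected_signal(scene, bad, p), class = "shutterlum_shape_error")
})

test_that("simulation is deterministic in the seed and noise-free mode is exact", {
  p <- test_pulse()
  sen <- test_sensor(n_rows = 400, n_cols = 8, photon_scale = 3e7)
  scene <- uniform_scene(sen, slow_red(), reflect = 0.3)
  c1 <- simulate_capture(scene, sen, p, seed = 11)
  c2 <- simulate_capture(scene, sen, p, seed = 11)
  c3 <- simulate_capture(scene, sen, p, seed = 12)
  expect_identical(c1$image, c2$image)
  expect_false(identical(c1$image, c3$image))
  # noise-free: image is the quantised expected signal
  c0 <- simulate_capture(scene, sen, p, seed = 1, noise = FALSE)
  mc <- max_code(sen)
  expect_identical(
    c0$image,
    array(as.integer(round(pmin(c0$expected_signal, sen$full_well) /
                             sen$full_well * mc)), dim = dim(c0$image)))
  # simulation does not disturb the global RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_capture(scene, sen, p, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("banding geometry follows the strobe: symmetry, count, contrast", {
  sen <- sensor_config(3000, 8, line_time = 1e-5, exposure_time = 1.4e-5,
                       photon_scale = 3e7, full_well = 1e6)
  p <- test_pulse(600.08, 0.5)
  scene <- uniform_scene(sen, fast_blue())
  cap <- simulate_capture(scene, sen, p, seed = 1, noise = FALSE)
  prof <- capture_profile(cap, "B", 0, 8)
  thr <- mean(range(prof$values))
  on <- prof$values >= thr
  # 50% duty: on rows and off rows balance (symmetric banding)
  expect_equal(mean(on), 0.5, tolerance = 0.01)
  # band count tied to the pulse frequency, within 1 cycle
  transitions <- sum(diff(on) == -1)
  expect_lte(abs(transitions - 600.08 * 3000 * 1e-5), 1)
  # contrast is non-increasing in exposure_time/period up to one period,
  # and vanishes when the exposure spans a whole number of periods (each
  # window then integrates the same number of full cycles)
  period <- 1 / p$frequency
  contrasts <- sapply(c(0.1, 0.3, 0.6, 0.9, 1.0, 2.0) * period, function(ex) {
    s <- sensor_config(3000, 8, line_time = 1e-5, exposure_time = ex,
                       photon_scale = 3e7, full_well = 1e6)
    cc <- simulate_capture(uniform_scene(s, fast_blue()), s, p, 1, noise = FALSE)
    v <- capture_profile(cc, "B", 0, 8)$values
    (max(v) - min(v)) / max(max(v) + min(v), 1)
  })
  expect_true(all(diff(contrasts[1:5]) <= 1e-6))
  expect_lt(contrasts[5], 1e-3)
  expect_lt(contrasts[6], 1e-3)
})

test_that("slow-emitter off bands decay strictly and steady light gives no bands", {
  sen <- sensor_config(1200, 8, photon_scale = 3e7)
  p <- test_pulse()
  scene <- uniform_scene(sen, slow_red())
  cap <- simulate_capture(scene, sen, p, seed = 1, noise = FALSE)
  prof <- capture_profile(cap, "R", 0, 8)
  # off-band rows from the known strobe geometry (phase 0, window-centre
  # row offset exposure/2/line_time = 0.7)
  pr <- 1 / (p$frequency * sen$line_time)
  for (k in 1:5) {
    r0 <- ceiling((k + 0.5) * pr - 0.7) + 3
    r1 <- floor((k + 1) * pr - 0.7) - 3
    v <- prof$values[(r0 + 1):(r1 + 1)]
    expect_true(all(diff(v) < 0))
  }
  # steady illumination: flat profile, variance at noise level only
  cap_s <- simulate_capture(scene, sen, constant_excitation(), seed = 1)
  prof_s <- capture_profile(cap_s, "R", 0, 8)
  expect_error(segment_bands(prof_s), class = "shutterlum_flat_profile_error")
  expect_lt(stats::sd(prof_s$values) / mean(prof_s$values), 0.05)
})

test_that("saturated rows are flagged and clipping precedes quantisation", {
  sen <- sensor_config(600, 8, photon_scale = 1e8, full_well = 500)
  p <- test_pulse()
  scene <- uniform_scene(sen, fast_blue())
  cap <- simulate_capture(scene, sen, p, seed = 1, noise = FALSE)
  expect_lte(max(cap$image), max_code(sen))
  prof <- capture_profile(cap, "B", 0, 8)
  expect_gt(length(prof$saturated_rows), 0)
})
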