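test_that("channel separation is lossless", {
  img <- array(0L, dim = c(4, 3, 3))
  img[, , 1] <- matrix(7L, 4, 3)
  ch <- split_channels(img)
  expect_equal(ch$R, matrix(7L, 4, 3))
  expect_true(all(ch$G == 0) && all(ch$B == 0))
  img2 <- array(sample.int(255, 4 * 3 * 3, replace = TRUE), dim = c(4, 3, 3))
  ch2 <- split_channels(img2)
  reassembled <- array(0L, dim(img2))
  reassembled[, , 1] <- ch2$R; reassembled[, , 2] <- ch2$G
  reassembled[, , 3] <- ch2$B
  expect_identical(reassembled, img2)
  expect_error(split_channels(matrix(1, 4, 3)), class = "shutterlum_channel_error")
})

test_that("fast and slow channels show their characteristic band shapes", {
  fx <- make_fixture("two_emitter_solid",
                     params = list(n_rows = 1200, n_cols = 16, noise = FALSE))
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 1, noise = FALSE)
  blue <- capture_profile(cap, "B")
  red <- capture_profile(cap, "R")
  # blue (fast-dominated): near-square, so the middle of the on band is flat
  seg_b <- segment_bands(blue)
  on <- seg_b$intervals[seg_b$intervals$state == "on", ][2, ]
  mid <- blue$values[(on$start + 10):(on$end - 10)]
  expect_lt(diff(range(mid)) / mean(mid), 0.01)
  # red (slow): decays through the off band (sawtooth), with the off-band
  # edges taken from the unbiased fast channel
  st <- estimate_strobe(seg_b, fx$sensor)
  fall <- st$phase_row + (2 + st$duty_cycle) * st$period_rows
  rise <- st$phase_row + 3 * st$period_rows
  v <- red$values[(ceiling(fall) + 3 + 1):(floor(rise) - 3 + 1)]
  expect_true(all(diff(v) < 0))
  expect_gt(v[1] / v[length(v)], 2)
})

test_that("row profiles average the stated column range and flag saturation", {
  m <- matrix(5, 10, 8)
  prof <- extract_row_profile(m, 0, 8)
  expect_equal(prof$values, rep(5, 10))
  # a single-column range reproduces that column
  m2 <- matrix(rnorm(80), 10, 8)
  expect_equal(extract_row_profile(m2, 3, 4)$values, m2[, 4])
  expect_error(extract_row_profile(m, 4, 4), class = "shutterlum_range_error")
  expect_error(extract_row_profile(m, -1, 3), class = "shutterlum_range_error")
  m3 <- m; m3[4, 2] <- 255
  expect_equal(extract_row_profile(m3, 0, 8, max_code = 255)$saturated_rows, 3L)
  # noise-free profile equals the analytic expected signal (up to
  # quantisation of the image)
  sen <- test_sensor(n_rows = 400, n_cols = 8, photon_scale = 3e7)
  p <- test_pulse()
  scene <- uniform_scene(sen, slow_red())
  cap <- simulate_capture(scene, sen, p, 1, noise = FALSE)
  prof_img <- capture_profile(cap, "R", 0, 8)
  expected_codes <- rowMeans(cap$expected_signal[, , 1]) / sen$full_well *
    max_code(sen)
  # image codes are rounded, so the profile can differ by up to half a code
  expect_lt(max(abs(prof_img$values - expected_codes)), 0.5)
})

test_that("segmentation recovers the band ladder and rejects flat profiles", {
  # ideal square profile alternating 166/167 rows (600.08 Hz at 10 us lines)
  lens <- rep(c(166, 167), 6)
  v <- unlist(mapply(function(l, s) rep(s, l), lens, rep(c(100, 10), 6)))
  prof <- structure(list(channel = "B", values = v, n_rows = length(v),
                         saturated_rows = integer(0), col_start = 0,
                         col_end = 1), class = "row_profile")
  seg <- segment_bands(prof)
  expect_equal(seg$intervals$end - seg$intervals$start, lens)
  expect_equal(seg$intervals$state, rep(c("on", "off"), 6))
  flat <- prof; flat$values <- rep(42, 500); flat$n_rows <- 500
  expect_error(segment_bands(flat), class = "shutterlum_flat_profile_error")
  # on/off widths mirror a 50% duty cycle
  fx <- make_fixture("two_emitter_solid",
                     params = list(n_rows = 1200, n_cols = 16, noise = FALSE))
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 1, noise = FALSE)
  seg2 <- segment_bands(capture_profile(cap, "B"))
  iv <- seg2$intervals[-c(1, nrow(seg2$intervals)), ]
  w_on <- mean(iv$end[iv$state == "on"] - iv$start[iv$state == "on"])
  w_off <- mean(iv$end[iv$state == "off"] - iv$start[iv$state == "off"])
  expect_equal(w_on / (w_on + w_off), 0.5, tolerance = 0.01)
})

test_that("strobe estimation round-trips frequency and duty over the design grid", {
  for (f in c(100, 600.08, 2000)) {
    for (d in c(0.2, 0.5, 0.8)) {
      period_rows <- 1 / (f * 1e-5)
      n_rows <- max(400, ceiling(4.2 * period_rows))
      fx <- make_fixture("two_emitter_solid",
                         params = list(n_rows = n_rows, n_cols = 16,
                                       frequency = f, duty = d, noise = FALSE,
                                       phase = 0.3 / f))
      cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 1, noise = FALSE)
      st <- estimate_strobe_from_capture(cap, "B")
      expect_lt(abs(st$frequency - f) / f, 0.005)
      expect_lt(abs(st$duty_cycle - d), 0.02)
    }
  }
})

test_that("reported frequency scales as 1/line_time for the same image", {
  fx <- make_fixture("two_emitter_solid",
                     params = list(n_rows = 1200, n_cols = 16, noise = FALSE))
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 1, noise = FALSE)
  seg <- segment_bands(capture_profile(cap, "B"))
  f1 <- estimate_strobe(seg, fx$sensor)$frequency
  sen2 <- fx$sensor; sen2$line_time <- 2 * fx$sensor$line_time
  f2 <- estimate_strobe(seg, sen2)$frequency
  expect_equal(f1, 2 * f2)
})

test_that("strobe estimation needs at least two complete cycles", {
  fx <- make_fixture("two_emitter_solid",
                     params = list(n_rows = 260, n_cols = 16, noise = FALSE))
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 1, noise = FALSE)
  expect_error(estimate_strobe_from_capture(cap, "B"),
               class = "shutterlum_insufficient_cycles_error")
})

test_that("decay fits recover tau exactly on noise-free captures", {
  # generated by the closed-form emission model, not a bare exponential:
  # excluding rows whose window straddles the edge leaves a pure exponential
  fx <- make_fixture("two_emitter_solid",
                     params = list(n_rows = 1200, n_cols = 16, noise = FALSE))
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 1, noise = FALSE)
  st <- estimate_strobe_from_capture(cap, "B")
  prof <- capture_profile(cap, "R")
  fall <- st$phase_row + st$duty_cycle * st$period_rows + 2 * st$period_rows
  interval <- c(ceiling(fall), floor(fall + (1 - st$duty_cycle) * st$period_rows))
  fit <- fit_decay(prof, interval, fx$sensor, edge_row = fall)
  expect_equal(fit$tau, 5e-4, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.9999)
  # aggregated estimate across all interior bands is as accurate
  lt <- estimate_lifetime(cap, fx$sensor, st, channel = "R")
  expect_equal(lt$tau, 5e-4, tolerance = 1e-3)
})

test_that("decay fitting errors on flat or insufficient data", {
  sen <- test_sensor(n_rows = 400, n_cols = 8)
  flat <- structure(list(channel = "R", values = rep(100, 400), n_rows = 400,
                         saturated_rows = integer(0), col_start = 0,
                         col_end = 8), class = "row_profile")
  expect_error(fit_decay(flat, c(10, 90), sen),
               class = "shutterlum_unreliable_fit_error")
  expect_error(fit_decay(flat, c(10, 16), sen), class = "shutterlum_data_error")
})

test_that("noisy lifetime recovery is unbiased at SNR 20", {
  taus <- vapply(1:25, function(s) {
    fx <- make_fixture("two_emitter_solid",
                       params = list(n_rows = 1500, n_cols = 64, snr = 20))
    cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, s)
    st <- estimate_strobe_from_capture(cap, "B")
    estimate_lifetime(cap, fx$sensor, st, channel = "R")$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) / 5e-4 - 1), 0.05)
})

test_that("an 18-cycle capture yields >= 15 accepted bands with tau within 3%", {
  fx <- make_fixture("two_emitter_solid",
                     params = list(n_rows = 3000, n_cols = 96, snr = 20))
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 4)
  st <- estimate_strobe_from_capture(cap, "B")
  lt <- estimate_lifetime(cap, fx$sensor, st, channel = "R")
  expect_gte(lt$n_accepted, 15)
  expect_lt(abs(lt$tau - 5e-4) / 5e-4, 0.03)
})

test_that("lifetime estimation refuses fast-only and unresolvable scenes", {
  fx <- make_fixture("two_emitter_solid", params = list(n_rows = 1200, n_cols = 32))
  scene <- fx$scene
  scene$amplitude_maps[[2]][] <- 0  # strip the slow emitter
  cap <- simulate_capture(scene, fx$sensor, fx$pulse, 1)
  st <- estimate_strobe_from_capture(cap, "B")
  expect_error(estimate_lifetime(cap, fx$sensor, st, channel = "R"),
               class = "shutterlum_no_lifetime_error")
  # tau >> period: decay unresolvable within a band, flagged not reported
  period <- 1 / 600.08
  fx2 <- make_fixture("two_emitter_solid",
                      params = list(n_rows = 3000, n_cols = 64,
                                    tau_eu = 10 * period))
  cap2 <- simulate_capture(fx2$scene, fx2$sensor, fx2$pulse, 1)
  st2 <- estimate_strobe_from_capture(cap2, "B")
  expect_error(estimate_lifetime(cap2, fx2$sensor, st2, channel = "R"),
               class = "shutterlum_no_lifetime_error")
})

test_that("estimates are invariant to overall intensity scaling", {
  fx <- make_fixture("two_emitter_solid",
                     params = list(n_rows = 1200, n_cols = 16, noise = FALSE))
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, 1, noise = FALSE)
  scaled <- cap$image
  scaled[] <- as.integer(round(scaled * 0.31))
  st1 <- estimate_strobe_from_capture(cap, "B")
  st2 <- estimate_strobe(
    segment_bands(extract_row_profile(split_channels(scaled)$B)), fx$sensor)
  expect_equal(st1$frequency, st2$frequency, tolerance = 1e-4)
  expect_equal(st1$duty_cycle, st2$duty_cycle, tolerance = 1e-3)
  lt1 <- estimate_lifetime(cap, fx$sensor, st1, channel = "R")
  lt2 <- estimate_lifetime(scaled, fx$sensor, st2, channel = "R")
  expect_equal(lt1$tau, lt2$tau, tolerance = 1e-3)
})

test_that("species identification matches by relative lifetime tolerance", {
  lib <- species_library()
  expect_equal(identify_species(5.1e-4, lib), "Eu(tta)3phen")
  expect_equal(identify_species(5e-5, lib), "unknown")
  lib2 <- data.frame(name = c("a", "b"), tau_ref = c(5e-4, 5.5e-4),
                     tolerance = c(0.1, 0.1))
  expect_error(identify_species(5.2e-4, lib2), class = "shutterlum_ambiguity_error")
  expect_error(identify_species(5e-4, data.frame()), class = "shutterlum_input_error")
})
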