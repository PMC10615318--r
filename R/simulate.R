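# Forward capture simulation: analytic per-row integration of the emission
# kinetics, then shot noise, read noise, clipping and quantisation.

#' Luminescent scene
#'
#' Spatial description of what the camera sees: one nonnegative amplitude
#' map per emitter (local concentration/coverage), an optional map of direct
#' LED reflection (white and instantaneous — a bare strobed LED reflecting
#' off the substrate), and a constant per-channel ambient background.
#'
#' @param emitters List of [emitter()] objects.
#' @param amplitude_maps List of `n_rows x n_cols` nonnegative matrices, one
#'   per emitter.
#' @param reflectance_map Optional `n_rows x n_cols` nonnegative matrix of
#'   direct LED reflection.
#' @param background Ambient level per channel, photoelectrons per second
#'   per pixel (length 1 or 3). Constant in time, so it adds
#'   `background * exposure_time` to every pixel.
#' @param white_weights Channel weights of the reflected LED light; default
#'   neutral white.
#' @return A `lum_scene` object.
#' @export
lum_scene <- function(emitters, amplitude_maps, reflectance_map = NULL,
                      background = 0, white_weights = c(1, 1, 1) / 3) {
  if (length(emitters) != length(amplitude_maps)) {
    sl_abort("need one amplitude map per emitter", "shutterlum_shape_error")
  }
  dims <- lapply(amplitude_maps, dim)
  if (!is.null(reflectance_map)) dims <- c(dims, list(dim(reflectance_map)))
  if (length(dims) == 0) sl_abort("scene has no content", "shutterlum_shape_error")
  ref <- dims[[1]]
  ok <- vapply(dims, function(d) !is.null(d) && identical(d, ref), logical(1))
  if (!all(ok)) sl_abort("all scene maps must share one shape", "shutterlum_shape_error")
  if (any(vapply(amplitude_maps, function(m) any(m < 0), logical(1)))) {
    sl_abort("amplitude maps must be nonnegative", "shutterlum_input_error")
  }
  if (!is.null(reflectance_map) && any(reflectance_map < 0)) {
    sl_abort("reflectance map must be nonnegative", "shutterlum_input_error")
  }
  if (length(background) == 1) background <- rep(background, 3)
  if (length(background) != 3 || any(background < 0)) {
    sl_abort("`background` must be 1 or 3 nonnegative values", "shutterlum_input_error")
  }
  structure(list(shape = ref, emitters = emitters,
                 amplitude_maps = amplitude_maps,
                 reflectance_map = reflectance_map,
                 background = background,
                 white_weights = white_weights / sum(white_weights)),
            class = "lum_scene")
}

check_scene_sensor <- function(scene, sensor) {
  if (!identical(scene$shape, c(sensor$n_rows, sensor$n_cols))) {
    sl_abort(sprintf("scene shape (%d x %d) does not match sensor (%d x %d)",
                     scene$shape[1], scene$shape[2], sensor$n_rows, sensor$n_cols),
             "shutterlum_shape_error")
  }
  invisible(TRUE)
}

#' Noise-free expected photoelectron counts of a capture
#'
#' Integrates every emitter's closed-form emission (and the direct LED
#' reflection) over each row's exposure window, analytically per on/off
#' segment, and combines the per-row integrals with the scene's spatial
#' maps:
#' `counts = photon_scale * (sum_e map_e * w_e * I_e(row)
#'           + reflectance * w_white * I_x(row)) + background * exposure`.
#'
#' @param scene A [lum_scene()].
#' @param sensor A [sensor_config()].
#' @param pulse An [excitation_pulse()] or [constant_excitation()].
#' @return `n_rows x n_cols x 3` array of expected photoelectrons.
#' @export
expected_signal <- function(scene, sensor, pulse) {
  check_scene_sensor(scene, sensor)
  n_r <- sensor$n_rows; n_c <- sensor$n_cols
  win <- row_exposure_window(seq_len(n_r) - 1, sensor)
  out <- array(0, dim = c(n_r, n_c, 3))
  for (i in seq_along(scene$emitters)) {
    em <- scene$emitters[[i]]
    ie <- emission_window_integral(win$t_start, win$t_end, em, pulse)
    spatial <- scene$amplitude_maps[[i]] * ie  # recycles down rows
    for (ch in 1:3) {
      out[, , ch] <- out[, , ch] +
        sensor$photon_scale * em$rgb_weights[ch] * spatial
    }
  }
  if (!is.null(scene$reflectance_map)) {
    ix <- excitation_window_integral(win$t_start, win$t_end, pulse)
    spatial <- scene$reflectance_map * ix
    for (ch in 1:3) {
      out[, , ch] <- out[, , ch] +
        sensor$photon_scale * scene$white_weights[ch] * spatial
    }
  }
  for (ch in 1:3) {
    out[, , ch] <- out[, , ch] + scene$background[ch] * sensor$exposure_time
  }
  out
}

#' Expected counts for a single row
#'
#' @inheritParams expected_signal
#' @param row 0-based row index.
#' @return `n_cols x 3` matrix of expected photoelectrons.
#' @export
integrate_row_signal <- function(row, scene, sensor, pulse) {
  check_scene_sensor(scene, sensor)
  win <- row_exposure_window(row, sensor)
  out <- matrix(0, sensor$n_cols, 3)
  for (i in seq_along(scene$emitters)) {
    em <- scene$emitters[[i]]
    ie <- emission_window_integral(win$t_start, win$t_end, em, pulse)
    out <- out + sensor$photon_scale * ie *
      outer(scene$amplitude_maps[[i]][row + 1, ], em$rgb_weights)
  }
  if (!is.null(scene$reflectance_map)) {
    ix <- excitation_window_integral(win$t_start, win$t_end, pulse)
    out <- out + sensor$photon_scale * ix *
      outer(scene$reflectance_map[row + 1, ], scene$white_weights)
  }
  out + rep(scene$background * sensor$exposure_time, each = sensor$n_cols)
}

quantize_counts <- function(electrons, sensor) {
  clipped <- pmin(pmax(electrons, 0), sensor$full_well)
  codes <- round(clipped / sensor$full_well * max_code(sensor))
  storage.mode(codes) <- "integer"
  codes
}

#' Simulate a rolling-shutter capture
#'
#' Renders a noisy, quantised RGB image of a scene: Poisson shot noise on
#' the expected photoelectron counts, additive Gaussian read noise, clipping
#' at `full_well`, then quantisation to `bit_depth`. With `noise = FALSE`
#' the expected counts are quantised directly. The same `seed` always
#' reproduces the same image bit for bit.
#'
#' @inheritParams expected_signal
#' @param seed Integer RNG seed recorded in the result's metadata.
#' @param noise Apply the noise model? (`FALSE` = noise-free mode.)
#' @return A `capture_result`: `image` (integer array at `bit_depth`),
#'   `expected_signal` (photoelectrons), plus the configuration and seed.
#' @examples
#' sen <- sensor_config(200, 16, photon_scale = 400)
#' sc <- lum_scene(list(emitter("dye", 5e-4, brightness = 2e3,
#'                              rgb_weights = c(1, 0, 0))),
#'                 list(matrix(1, 200, 16)))
#' cap <- simulate_capture(sc, sen, excitation_pulse(600.08, 0.5), seed = 1)
#' @export
simulate_capture <- function(scene, sensor, pulse, seed = 1L, noise = TRUE) {
  exp_sig <- expected_signal(scene, sensor, pulse)
  if (noise) {
    electrons <- withr::with_seed(as.integer(seed), {
      e <- stats::rpois(length(exp_sig), lambda = exp_sig)
      if (sensor$read_noise_sigma > 0) {
        e <- e + stats::rnorm(length(exp_sig), 0, sensor$read_noise_sigma)
      }
      e
    })
    electrons <- array(electrons, dim = dim(exp_sig))
  } else {
    electrons <- exp_sig
  }
  structure(list(image = quantize_counts(electrons, sensor),
                 expected_signal = exp_sig,
                 sensor = sensor, pulse = pulse,
                 seed = as.integer(seed), noise = noise),
            class = "capture_result")
}

#' Photon scale (and ambient background) meeting a target peak SNR
#'
#' Solves for the gain at which the brightest pixel of the chosen channel
#' reaches `N / sqrt(N + B + read_noise^2) = snr`, where `N` is the peak
#' signal in photoelectrons and `B` the ambient background electrons per
#' exposure, specified as a fraction `background_frac` of the peak.
#'
#' @inheritParams expected_signal
#' @param channel Channel whose peak anchors the SNR: "R", "G" or "B".
#' @param snr Target peak signal-to-noise ratio.
#' @param background_frac Ambient background per exposure as a fraction of
#'   the peak signal.
#' @return List with `photon_scale`, `background` (electrons/s, to place in
#'   the scene) and `peak_electrons`.
#' @export
photon_scale_for_snr <- function(scene, sensor, pulse, channel = "R",
                                 snr = 20, background_frac = 0) {
  ch <- match(match.arg(channel, c("R", "G", "B")), c("R", "G", "B"))
  unit_sensor <- sensor
  unit_sensor$photon_scale <- 1
  bare_scene <- scene
  bare_scene$background <- rep(0, 3)
  s1 <- max(expected_signal(bare_scene, unit_sensor, pulse)[, , ch])
  if (s1 <= 0) sl_abort("scene has no signal in that channel", "shutterlum_input_error")
  sr2 <- sensor$read_noise_sigma^2
  f <- background_frac
  n_peak <- (snr^2 * (1 + f) + sqrt(snr^4 * (1 + f)^2 + 4 * snr^2 * sr2)) / 2
  list(photon_scale = n_peak / s1,
       background = f * n_peak / sensor$exposure_time,
       peak_electrons = n_peak)
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf("<capture_result> %d x %d x 3, %d-bit, seed %d%s\n",
              dim(x$image)[1], dim(x$image)[2], x$sensor$bit_depth, x$seed,
              if (x$noise) "" else " (noise-free)"))
  if (is_pulsed(x$pulse)) {
    cat(sprintf("  strobe %.4g Hz, duty %.3g\n",
                x$pulse$frequency, x$pulse$duty_cycle))
  } else {
    cat("  steady illumination\n")
  }
  invisible(x)
}
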