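# Sensor, excitation and emitter models, and the closed-form
# periodic-steady-state emission kinetics that the capture simulator
# integrates analytically.

#' Rolling-shutter sensor configuration
#'
#' Describes the row-to-time mapping and noise model of a rolling-shutter
#' CMOS sensor. Row `r` (0-based, top of image) starts exposing at
#' `r * line_time` and integrates for `exposure_time` seconds, so each image
#' row samples a slightly later time window than the one above it. The line
#' time is not reported by typical camera apps and must be supplied (or
#' calibrated from a strobe of known frequency, see [estimate_strobe()]).
#'
#' @param n_rows,n_cols Sensor dimensions in pixels (`n_rows >= 2`).
#' @param line_time Seconds between exposure starts of consecutive rows.
#' @param exposure_time Seconds each row integrates. May exceed `line_time`,
#'   in which case adjacent row windows overlap.
#' @param bit_depth Output bit depth, 8 or 16.
#' @param photon_scale Expected photoelectrons per unit radiant exposure
#'   (lumped gain surrogate; the paper-style "ISO" knob).
#' @param read_noise_sigma Gaussian read noise, electrons RMS.
#' @param full_well Electrons at saturation; values clip here before
#'   quantisation.
#' @param readout_reversed If `TRUE`, row `n_rows - 1` exposes first
#'   (sensors differ in scan direction).
#' @return A `sensor_config` object.
#' @examples
#' sensor_config(n_rows = 3000, n_cols = 1000)
#' @export
sensor_config <- function(n_rows, n_cols, line_time = 1e-5,
                          exposure_time = 1.4e-5, bit_depth = 16L,
                          photon_scale = 1, read_noise_sigma = 3,
                          full_well = 1e4, readout_reversed = FALSE) {
  check_scalar(n_rows, "n_rows", positive = TRUE)
  check_scalar(n_cols, "n_cols", positive = TRUE)
  if (n_rows < 2) sl_abort("`n_rows` must be >= 2", "shutterlum_input_error")
  check_scalar(line_time, "line_time", positive = TRUE)
  check_scalar(exposure_time, "exposure_time", positive = TRUE)
  if (!bit_depth %in% c(8L, 16L)) {
    sl_abort("`bit_depth` must be 8 or 16", "shutterlum_input_error")
  }
  check_scalar(photon_scale, "photon_scale", positive = TRUE)
  check_scalar(read_noise_sigma, "read_noise_sigma")
  check_scalar(full_well, "full_well", positive = TRUE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         line_time = line_time, exposure_time = exposure_time,
         bit_depth = as.integer(bit_depth), photon_scale = photon_scale,
         read_noise_sigma = read_noise_sigma, full_well = full_well,
         readout_reversed = isTRUE(readout_reversed)),
    class = "sensor_config")
}

#' Maximum digital code value of a sensor
#' @param sensor A [sensor_config()].
#' @return `2^bit_depth - 1`.
#' @export
max_code <- function(sensor) 2^sensor$bit_depth - 1

#' Square-wave (PWM) excitation strobe
#'
#' An ideal square waveform with instantaneous edges: the LED is on for
#' `duty_cycle` of each period, starting `phase` seconds after row 0 begins
#' exposing.
#'
#' @param frequency Strobe frequency in Hz (> 0).
#' @param duty_cycle On fraction of each period, strictly in (0, 1).
#' @param phase Seconds offset of the first rising edge relative to row 0
#'   exposure start.
#' @param amplitude Relative radiant intensity while on (>= 0).
#' @return An `excitation_pulse` object.
#' @examples
#' excitation_pulse(600.08, 0.5)
#' @export
excitation_pulse <- function(frequency, duty_cycle = 0.5, phase = 0,
                             amplitude = 1) {
  check_scalar(frequency, "frequency", positive = TRUE)
  check_scalar(duty_cycle, "duty_cycle")
  if (duty_cycle <= 0 || duty_cycle >= 1) {
    sl_abort("`duty_cycle` must lie strictly in (0, 1)", "shutterlum_input_error")
  }
  check_scalar(phase, "phase")
  check_scalar(amplitude, "amplitude")
  if (amplitude < 0) sl_abort("`amplitude` must be >= 0", "shutterlum_input_error")
  structure(list(frequency = frequency, duty_cycle = duty_cycle,
                 phase = phase, amplitude = amplitude),
            class = "excitation_pulse")
}

#' Constant (steady-state) illumination
#'
#' Stand-in for an un-strobed excitation source: the steady-state control
#' condition under which rolling-shutter banding — and hence any lifetime
#' information — vanishes.
#'
#' @param amplitude Relative radiant intensity (>= 0).
#' @return A `constant_excitation` object, accepted wherever an
#'   [excitation_pulse()] is.
#' @export
constant_excitation <- function(amplitude = 1) {
  check_scalar(amplitude, "amplitude")
  structure(list(amplitude = amplitude), class = "constant_excitation")
}

is_pulsed <- function(x) inherits(x, "excitation_pulse")

#' Instantaneous excitation irradiance
#'
#' @param t Time(s) in seconds (vectorised).
#' @param pulse An [excitation_pulse()] or [constant_excitation()].
#' @return `amplitude` where the strobe is on, 0 where off.
#' @examples
#' p <- excitation_pulse(600.08, 0.5)
#' excitation_state(c(0, 0.75 / 600.08), p)
#' @export
excitation_state <- function(t, pulse) {
  if (!is_pulsed(pulse)) return(rep(pulse$amplitude, length(t)))
  period <- 1 / pulse$frequency
  s <- (t - pulse$phase) %% period
  ifelse(s < pulse$duty_cycle * period, pulse$amplitude, 0)
}

#' Luminescent emitter
#'
#' A single-exponential emitter characterised by its emissive lifetime and
#' RGB emission colour. "Fast" emitters (conventional fluorophores,
#' sub-nanosecond) relax far faster than any sensor line time and are
#' modelled as instantaneous, tracking the excitation exactly. Slow emitters
#' (lanthanide complexes, TADF materials; microsecond to millisecond) follow
#' the linear kinetics `dE/dt = brightness * x(t) - E / lifetime`.
#'
#' @param name Label used in reports and species identification.
#' @param lifetime Emissive lifetime tau in seconds (required unless
#'   `is_fast`).
#' @param brightness Emission rate coefficient per unit excitation
#'   (arbitrary units).
#' @param rgb_weights Length-3 nonnegative channel fractions; normalised to
#'   sum to 1.
#' @param is_fast If `TRUE`, emission is treated as instantaneous.
#' @return An `emitter` object.
#' @examples
#' emitter("Eu(tta)3phen", lifetime = 5e-4, rgb_weights = c(0.8, 0.15, 0.05))
#' @export
emitter <- function(name, lifetime = NULL, brightness = 1,
                    rgb_weights = c(1, 1, 1) / 3, is_fast = FALSE) {
  if (!is_fast) {
    if (is.null(lifetime) || !is_scalar_number(lifetime) || lifetime <= 0) {
      sl_abort(sprintf("emitter '%s': a non-fast emitter needs lifetime > 0", name),
               "shutterlum_invalid_emitter_error")
    }
  }
  check_scalar(brightness, "brightness")
  if (brightness < 0) sl_abort("`brightness` must be >= 0", "shutterlum_input_error")
  if (length(rgb_weights) != 3 || any(rgb_weights < 0) || sum(rgb_weights) <= 0) {
    sl_abort("`rgb_weights` must be 3 nonnegative values with positive sum",
             "shutterlum_input_error")
  }
  structure(list(name = as.character(name), lifetime = lifetime,
                 brightness = brightness,
                 rgb_weights = rgb_weights / sum(rgb_weights),
                 is_fast = isTRUE(is_fast)),
            class = "emitter")
}

# Periodic-steady-state boundary levels of a slow emitter under a square
# strobe. E1 = emission at the rising edge, E2 = emission at the falling
# edge; `level` = brightness * amplitude * tau is the would-be plateau under
# continuous illumination. expm1 keeps the ratio stable for tau >> period.
cycle_levels <- function(em, pulse) {
  tau <- em$lifetime
  bA <- em$brightness * pulse$amplitude
  period <- 1 / pulse$frequency
  t_on <- pulse$duty_cycle * period
  t_off <- period - t_on
  E2 <- bA * tau * expm1(-t_on / tau) / expm1(-period / tau)
  E1 <- E2 * exp(-t_off / tau)
  list(E1 = E1, E2 = E2, level = bA * tau,
       period = period, t_on = t_on, t_off = t_off)
}

#' Emission radiance of an emitter under periodic excitation
#'
#' For fast emitters, emission tracks the strobe: `E(t) = brightness * x(t)`.
#' For slow emitters the function returns the periodic steady-state solution
#' of `dE/dt = brightness * x(t) - E / tau` (transients assumed fully
#' decayed): rising toward `brightness * amplitude * tau` while the LED is
#' on, decaying exponentially while it is off, with cycle boundary values
#' fixed by periodicity.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param em An [emitter()].
#' @param pulse An [excitation_pulse()] or [constant_excitation()].
#' @return Radiance in arbitrary units, same length as `t`.
#' @export
emission_rate <- function(t, em, pulse) {
  if (em$is_fast) return(em$brightness * excitation_state(t, pulse))
  if (is.null(em$lifetime) || em$lifetime <= 0) {
    sl_abort("slow emitter with nonpositive lifetime", "shutterlum_invalid_emitter_error")
  }
  if (!is_pulsed(pulse)) {
    return(rep(em$brightness * pulse$amplitude * em$lifetime, length(t)))
  }
  lv <- cycle_levels(em, pulse)
  tau <- em$lifetime
  s <- (t - pulse$phase) %% lv$period
  on <- s < lv$t_on
  ifelse(on,
         lv$level + (lv$E1 - lv$level) * exp(-s / tau),
         lv$E2 * exp(-(s - lv$t_on) / tau))
}

# Cumulative on-time of the strobe between `phase` and t (vectorised).
on_time_cum <- function(t, pulse) {
  period <- 1 / pulse$frequency
  t_on <- pulse$duty_cycle * period
  u <- t - pulse$phase
  k <- floor(u / period)
  s <- u - k * period
  k * t_on + pmin(s, t_on)
}

# Cumulative integral of the slow-emitter periodic steady state from `phase`
# to t. Per-period integral is level * t_on (energy balance of the linear
# kinetics); within-cycle remainder integrates the two closed-form branches.
emission_cum <- function(t, em, pulse) {
  lv <- cycle_levels(em, pulse)
  tau <- em$lifetime
  per_period <- lv$level * lv$t_on
  u <- t - pulse$phase
  k <- floor(u / lv$period)
  s <- u - k * lv$period
  g_on_full <- lv$level * lv$t_on - (lv$E1 - lv$level) * tau * expm1(-lv$t_on / tau)
  g <- ifelse(s < lv$t_on,
              lv$level * s - (lv$E1 - lv$level) * tau * expm1(-s / tau),
              g_on_full - lv$E2 * tau * expm1(-pmax(s - lv$t_on, 0) / tau))
  k * per_period + g
}

#' Integrated emission over a time window
#'
#' Exact analytic integral of [emission_rate()] over `[t0, t1]`, evaluated
#' per on/off segment of the piecewise-exponential closed form — the radiant
#' exposure a sensor row accumulates from one emitter.
#'
#' @param t0,t1 Window bounds in seconds (vectorised, `t1 >= t0`).
#' @param em An [emitter()].
#' @param pulse An [excitation_pulse()] or [constant_excitation()].
#' @return Integral values, arbitrary units times seconds.
#' @export
emission_window_integral <- function(t0, t1, em, pulse) {
  if (!is_pulsed(pulse)) {
    rate <- if (em$is_fast) em$brightness * pulse$amplitude
            else em$brightness * pulse$amplitude * em$lifetime
    return(rate * (t1 - t0))
  }
  if (em$is_fast) {
    return(em$brightness * pulse$amplitude *
             (on_time_cum(t1, pulse) - on_time_cum(t0, pulse)))
  }
  if (is.null(em$lifetime) || em$lifetime <= 0) {
    sl_abort("slow emitter with nonpositive lifetime", "shutterlum_invalid_emitter_error")
  }
  emission_cum(t1, em, pulse) - emission_cum(t0, em, pulse)
}

# Integrated excitation (for the direct LED-reflection term).
excitation_window_integral <- function(t0, t1, pulse) {
  if (!is_pulsed(pulse)) return(pulse$amplitude * (t1 - t0))
  pulse$amplitude * (on_time_cum(t1, pulse) - on_time_cum(t0, pulse))
}

#' Exposure window of a sensor row
#'
#' @param row 0-based row index/indices, `0 <= row < n_rows`.
#' @param sensor A [sensor_config()].
#' @return A list with numeric vectors `t_start` and `t_end` (seconds);
#'   `t_start = row * line_time`, `t_end = t_start + exposure_time` (with the
#'   row order flipped when `readout_reversed`).
#' @examples
#' row_exposure_window(100, sensor_config(3000, 1000))
#' @export
row_exposure_window <- function(row, sensor) {
  if (any(row < 0 | row >= sensor$n_rows | row != floor(row))) {
    sl_abort(sprintf("row index out of range [0, %d)", sensor$n_rows),
             "shutterlum_index_error")
  }
  eff <- if (sensor$readout_reversed) sensor$n_rows - 1 - row else row
  t_start <- eff * sensor$line_time
  list(t_start = t_start, t_end = t_start + sensor$exposure_time)
}

#' Map row indices to sample times
#'
#' Window-centre convention: the intensity a row records is attributed to
#' the centre of its exposure window, `row * line_time + exposure_time / 2`.
#' Under this convention a pure exponential decay sampled by overlapping box
#' windows remains exactly exponential in the row coordinate.
#'
#' @param rows 0-based (possibly fractional) row indices.
#' @param sensor A [sensor_config()].
#' @return Times in seconds.
#' @export
rows_to_time <- function(rows, sensor) {
  rows * sensor$line_time + sensor$exposure_time / 2
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf("<sensor_config> %d x %d px, line %.3g us, exposure %.3g us, %d-bit\n",
              x$n_rows, x$n_cols, x$line_time * 1e6, x$exposure_time * 1e6,
              x$bit_depth))
  cat(sprintf("  photon_scale %.4g, read noise %.3g e-, full well %.4g e-\n",
              x$photon_scale, x$read_noise_sigma, x$full_well))
  invisible(x)
}

#' @export
print.excitation_pulse <- function(x, ...) {
  cat(sprintf("<excitation_pulse> %.4g Hz, duty %.3g, phase %.3g s, amplitude %.3g\n",
              x$frequency, x$duty_cycle, x$phase, x$amplitude))
  invisible(x)
}

#' @export
print.emitter <- function(x, ...) {
  cat(sprintf("<emitter> %s: %s, rgb (%.2f, %.2f, %.2f)\n", x$name,
              if (x$is_fast) "fast (instantaneous)"
              else sprintf("tau %.4g s", x$lifetime),
              x$rgb_weights[1], x$rgb_weights[2], x$rgb_weights[3]))
  invisible(x)
}
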