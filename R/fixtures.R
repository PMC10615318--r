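# Scene generators emulating the study's experimental scenarios, each
# returning a renderable scene plus a ground-truth record for
# parameter-recovery tests.

fixture_defaults <- function() {
  list(n_rows = 3000, n_cols = 1000,
       line_time = 1e-5, exposure_time = 1.4e-5,
       bit_depth = 16L, read_noise_sigma = 3,
       frequency = 600.08, duty = 0.5, phase = 0,
       snr = 20, noise = TRUE, steady = FALSE,
       background_frac = 0,
       reflect_level = 0.3,
       # slow-emitter lifetimes (s): Eu complex, Tb complex, TADF dye
       tau_eu = 5e-4, tau_tb = 8e-4, tau_tadf = 3e-4,
       # Stern-Volmer generator settings
       K_sv = 0.01, pressures = c(0, 20, 50, 100, 200, 300),
       # thermal-quenching generator settings
       thermal = list(tau_ref = 6e-4, prefactor = 3e4, activation_scale = 3500),
       temperatures = seq(248.15, 373.15, length.out = 6),
       ambient_background_frac = 0.25)
}

fixture_scenarios <- c("pulsed_led", "two_emitter_solid",
                       "two_emitter_solution", "security_tag",
                       "pressure_series", "temperature_series")

# Build sensor + background once the scene content (at photon_scale = 1) is
# known, anchoring the requested peak SNR in `channel`.
finish_fixture <- function(scene_fun, p, channel) {
  base_sensor <- sensor_config(
    n_rows = p$n_rows, n_cols = p$n_cols, line_time = p$line_time,
    exposure_time = p$exposure_time, bit_depth = p$bit_depth,
    photon_scale = 1, read_noise_sigma = p$read_noise_sigma)
  pulse <- if (p$steady) constant_excitation(1)
           else excitation_pulse(p$frequency, p$duty, p$phase)
  scene0 <- scene_fun(0)
  budget <- photon_scale_for_snr(scene0, base_sensor, pulse, channel,
                                 snr = p$snr,
                                 background_frac = p$background_frac)
  sensor <- base_sensor
  sensor$photon_scale <- budget$photon_scale
  sensor$full_well <- 4 * budget$peak_electrons *
    (1 + p$background_frac) + 100 * p$read_noise_sigma
  list(sensor = sensor, pulse = pulse, budget = budget)
}

apply_background <- function(scene, rate) {
  scene$background <- rep(rate, 3)
  scene
}

#' Generate a named study scenario
#'
#' Builds a renderable scene (or series of scenes), a sensor configuration
#' and an excitation pulse for one of the emulated experimental scenarios,
#' plus a ground-truth record for parameter-recovery tests:
#'
#' * `pulsed_led` — a bare strobed LED reflecting off a surface
#'   (reflection-only banding).
#' * `two_emitter_solid` — a fast blue fluorophore and a slow red Eu
#'   complex co-deposited on a solid support.
#' * `two_emitter_solution` — a homogeneous fast/slow dye mixture in a
#'   vial; set `steady = TRUE` for the constant-illumination control in
#'   which the species cannot be separated.
#' * `security_tag` — three side-by-side inks (fast yellow/green, slow red
#'   Eu, slow green Tb) plus a blank region, with a matching
#'   [tag_template()] in the ground truth.
#' * `pressure_series` — an oxygen-quenchable TADF coating imaged at a
#'   series of ambient pressures, lifetimes following
#'   `tau(P) = tau0 / (1 + K_sv P)` with brightness fixed (so intensity is
#'   quenched by the same factor).
#' * `temperature_series` — a Eu complex whose lifetime follows a
#'   thermal-quenching law, imaged at a series of temperatures under dark
#'   and/or ambient lighting.
#'
#' Defaults mirror the emulated experiments: 3000 x 1000 px, line time
#' 10 us, exposure 14 us, strobe 600.08 Hz at 50% duty, peak SNR 20.
#' Generation is deterministic given `seed` (the seed feeds the simulated
#' captures; scene construction itself is deterministic).
#'
#' @param scenario One of the names above.
#' @param params Named list of overrides (see `shutterlum:::fixture_defaults()`).
#' @param seed Integer seed recorded in the fixture and used by
#'   [run_end_to_end()] simulations.
#' @return A `lum_fixture`: `scenario`, `scene` (or `scenes` + `conditions`
#'   for series), `sensor`, `pulse`, `truth`, `seed`.
#' @export
make_fixture <- function(scenario = fixture_scenarios, params = list(),
                         seed = 1L) {
  if (length(scenario) != 1 || !scenario %in% fixture_scenarios) {
    sl_abort(sprintf("unknown scenario '%s' (expected one of: %s)",
                     paste(scenario, collapse = ","),
                     paste(fixture_scenarios, collapse = ", ")),
             "shutterlum_spec_error")
  }
  p <- utils::modifyList(fixture_defaults(), params)
  fx <- switch(scenario,
    pulsed_led = fixture_pulsed_led(p),
    two_emitter_solid = fixture_two_emitter(p, solution = FALSE),
    two_emitter_solution = fixture_two_emitter(p, solution = TRUE),
    security_tag = fixture_security_tag(p),
    pressure_series = fixture_pressure_series(p),
    temperature_series = fixture_temperature_series(p))
  fx$scenario <- scenario
  fx$seed <- as.integer(seed)
  fx$params <- p
  class(fx) <- "lum_fixture"
  fx
}

fixture_pulsed_led <- function(p) {
  scene <- lum_scene(
    emitters = list(), amplitude_maps = list(),
    reflectance_map = matrix(1, p$n_rows, p$n_cols),
    background = 0)
  fin <- finish_fixture(function(i) scene, p, "G")
  scene <- apply_background(scene, fin$budget$background)
  list(scene = scene, sensor = fin$sensor, pulse = fin$pulse,
       truth = list(frequency = p$frequency, duty = p$duty,
                    strobe_channel = "G"))
}

fixture_two_emitter <- function(p, solution = FALSE) {
  fast <- if (solution) {
    emitter("perylene-bisimide", is_fast = TRUE, brightness = 1,
            rgb_weights = c(0.30, 0.55, 0.15))
  } else {
    emitter("PPE", is_fast = TRUE, brightness = 1,
            rgb_weights = c(0.10, 0.20, 0.70))
  }
  slow <- emitter("Eu(tta)3phen", lifetime = p$tau_eu,
                  brightness = 1 / p$tau_eu,
                  rgb_weights = c(0.85, 0.15, 0))
  amp <- matrix(1, p$n_rows, p$n_cols)
  if (solution) {
    # dye solution in a vial occupying the middle 60% of columns
    vial <- matrix(0, p$n_rows, p$n_cols)
    c0 <- floor(0.2 * p$n_cols) + 1
    c1 <- ceiling(0.8 * p$n_cols)
    vial[, c0:c1] <- 1
    amp <- vial
  }
  scene <- lum_scene(
    emitters = list(fast, slow),
    amplitude_maps = list(amp, amp),
    reflectance_map = p$reflect_level * matrix(1, p$n_rows, p$n_cols),
    background = 0)
  strobe_ch <- if (solution) "G" else "B"
  fin <- finish_fixture(function(i) scene, p, "R")
  scene <- apply_background(scene, fin$budget$background)
  list(scene = scene, sensor = fin$sensor, pulse = fin$pulse,
       truth = list(frequency = p$frequency, duty = p$duty,
                    tau = p$tau_eu, slow_name = "Eu(tta)3phen",
                    strobe_channel = strobe_ch, analyte_channel = "R"))
}

fixture_security_tag <- function(p) {
  n_c <- p$n_cols
  q <- function(a, b) {
    m <- matrix(0, p$n_rows, n_c)
    m[, (floor(a * n_c) + 1):ceiling(b * n_c)] <- 1
    m
  }
  fast <- emitter("PFO-BT", is_fast = TRUE, brightness = 1,
                  rgb_weights = c(0.25, 0.60, 0.15))
  eu <- emitter("Eu(tta)3phen", lifetime = p$tau_eu, brightness = 1 / p$tau_eu,
                rgb_weights = c(0.85, 0.15, 0))
  tb <- emitter("Tb(thd)3", lifetime = p$tau_tb, brightness = 1 / p$tau_tb,
                rgb_weights = c(0.10, 0.75, 0.15))
  scene <- lum_scene(
    emitters = list(fast, eu, tb),
    amplitude_maps = list(q(0, 0.25), q(0.25, 0.5), q(0.5, 0.75)),
    reflectance_map = 0.1 * matrix(1, p$n_rows, n_c),
    background = 0)
  fin <- finish_fixture(function(i) scene, p, "R")
  scene <- apply_background(scene, fin$budget$background)
  template <- tag_template(
    list(name = "ink-fast", col_start = 0L, col_end = floor(0.25 * n_c),
         channel = "G", kind = "fast"),
    list(name = "ink-Eu", col_start = floor(0.25 * n_c),
         col_end = floor(0.5 * n_c), channel = "R", kind = "slow",
         tau_ref = p$tau_eu, tolerance = 0.15),
    list(name = "ink-Tb", col_start = floor(0.5 * n_c),
         col_end = floor(0.75 * n_c), channel = "G", kind = "slow",
         tau_ref = p$tau_tb, tolerance = 0.15))
  list(scene = scene, sensor = fin$sensor, pulse = fin$pulse,
       truth = list(frequency = p$frequency, duty = p$duty,
                    taus = c(Eu = p$tau_eu, Tb = p$tau_tb),
                    template = template))
}

fixture_pressure_series <- function(p) {
  tau0 <- p$tau_tadf
  make_scene <- function(pressure) {
    tau_p <- tau0 / (1 + p$K_sv * pressure)
    tadf <- emitter("CzBP-TADF", lifetime = tau_p, brightness = 1 / tau0,
                    rgb_weights = c(0.15, 0.60, 0.25))
    lum_scene(emitters = list(tadf),
              amplitude_maps = list(matrix(1, p$n_rows, p$n_cols)),
              reflectance_map = p$reflect_level * matrix(1, p$n_rows, p$n_cols),
              background = 0)
  }
  # gain anchored on the unquenched (P = 0) scene and then held fixed
  fin <- finish_fixture(function(i) make_scene(0), p, "G")
  scenes <- lapply(p$pressures, function(pr) {
    apply_background(make_scene(pr), fin$budget$background)
  })
  list(scenes = scenes, conditions = p$pressures,
       sensor = fin$sensor, pulse = fin$pulse,
       truth = list(frequency = p$frequency, duty = p$duty,
                    K_sv = p$K_sv, tau0 = tau0,
                    strobe_channel = "B", analyte_channel = "G"))
}

fixture_temperature_series <- function(p) {
  th <- p$thermal
  tau_at <- function(tk) th$tau_ref / (1 + th$prefactor * exp(-th$activation_scale / tk))
  make_scene <- function(tk) {
    eu <- emitter("Eu(tta)3phen", lifetime = tau_at(tk),
                  brightness = 1 / th$tau_ref,
                  rgb_weights = c(0.85, 0.15, 0))
    lum_scene(emitters = list(eu),
              amplitude_maps = list(matrix(1, p$n_rows, p$n_cols)),
              reflectance_map = p$reflect_level * matrix(1, p$n_rows, p$n_cols),
              background = 0)
  }
  fin <- finish_fixture(function(i) make_scene(min(p$temperatures)), p, "R")
  ambient_rate <- p$ambient_background_frac * fin$budget$peak_electrons /
    p$exposure_time
  scenes_dark <- lapply(p$temperatures, make_scene)
  scenes_ambient <- lapply(scenes_dark, apply_background, rate = ambient_rate)
  list(scenes = scenes_dark, scenes_ambient = scenes_ambient,
       conditions = p$temperatures,
       sensor = fin$sensor, pulse = fin$pulse,
       truth = list(frequency = p$frequency, duty = p$duty,
                    thermal = th, ambient_background = ambient_rate,
                    strobe_channel = "B", analyte_channel = "R"))
}

#' @export
print.lum_fixture <- function(x, ...) {
  n <- if (!is.null(x$scene)) 1 else length(x$scenes)
  cat(sprintf("<lum_fixture> %s: %d scene(s), %d x %d px, seed %d\n",
              x$scenario, n, x$sensor$n_rows, x$sensor$n_cols, x$seed))
  invisible(x)
}
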