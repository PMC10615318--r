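# Generate -> simulate -> analyze (-> calibrate) recovery runs with a
# per-fixture tolerance suite.

default_tolerances <- function() {
  list(frequency_rel = 0.01, duty_abs = 0.03, tau_rel = 0.10,
       K_sv_rel = 0.20, tau0_rel = 0.10, thermal_tau_rel = 0.15)
}

e2e_check <- function(name, estimate, truth, tol, pass = NULL) {
  data.frame(check = name, estimate = estimate, truth = truth,
             tolerance = tol,
             pass = pass %||% (abs(estimate - truth) <= tol),
             stringsAsFactors = FALSE)
}

#' Run a full synthetic recovery experiment
#'
#' Generates a scenario with [make_fixture()], simulates the capture(s),
#' runs the inverse pipeline, and compares every recovered quantity against
#' the fixture's ground truth at the scenario's tolerance suite. Stage
#' errors propagate (they are never swallowed), except where an error *is*
#' the expected verdict (the steady-illumination control).
#'
#' @param scenario Scenario name, see [make_fixture()].
#' @param params Fixture parameter overrides.
#' @param seed Integer seed for all simulated noise.
#' @param tolerances Overrides of the tolerance suite
#'   (`shutterlum:::default_tolerances()`).
#' @return An `e2e_report`: `checks` data frame (estimate, truth,
#'   tolerance, pass) and overall `pass`.
#' @export
run_end_to_end <- function(scenario, params = list(), seed = 1L,
                           tolerances = list()) {
  tol <- utils::modifyList(default_tolerances(), tolerances)
  fx <- make_fixture(scenario, params, seed)
  checks <- switch(scenario,
    pulsed_led = e2e_pulsed_led(fx, tol),
    two_emitter_solid = e2e_two_emitter(fx, tol),
    two_emitter_solution = e2e_two_emitter(fx, tol),
    security_tag = e2e_security_tag(fx, tol),
    pressure_series = e2e_pressure(fx, tol),
    temperature_series = e2e_temperature(fx, tol))
  structure(list(scenario = scenario, seed = fx$seed, checks = checks,
                 pass = all(checks$pass)),
            class = "e2e_report")
}

e2e_strobe_checks <- function(strobe, truth, tol) {
  rbind(
    e2e_check("strobe_frequency_hz", strobe$frequency, truth$frequency,
              tol$frequency_rel * truth$frequency),
    e2e_check("duty_cycle", strobe$duty_cycle, truth$duty, tol$duty_abs))
}

e2e_pulsed_led <- function(fx, tol) {
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, fx$seed,
                          noise = fx$params$noise)
  strobe <- estimate_strobe_from_capture(cap, fx$truth$strobe_channel)
  e2e_strobe_checks(strobe, fx$truth, tol)
}

e2e_two_emitter <- function(fx, tol) {
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, fx$seed,
                          noise = fx$params$noise)
  if (fx$params$steady) {
    flat <- tryCatch({
      capture_profile(cap, fx$truth$strobe_channel)
      segment_bands(capture_profile(cap, fx$truth$strobe_channel))
      FALSE
    }, shutterlum_flat_profile_error = function(e) TRUE)
    return(e2e_check("steady_state_flat_verdict", as.numeric(flat), 1, 0,
                     pass = flat))
  }
  strobe <- estimate_strobe_from_capture(cap, fx$truth$strobe_channel)
  lt <- estimate_lifetime(cap, fx$sensor, strobe,
                          channel = fx$truth$analyte_channel)
  id <- identify_species(lt, species_library())
  rbind(
    e2e_strobe_checks(strobe, fx$truth, tol),
    e2e_check("lifetime_s", lt$tau, fx$truth$tau,
              tol$tau_rel * fx$truth$tau),
    e2e_check("species_identified", as.numeric(id == fx$truth$slow_name), 1, 0,
              pass = id == fx$truth$slow_name))
}

e2e_security_tag <- function(fx, tol) {
  cap <- simulate_capture(fx$scene, fx$sensor, fx$pulse, fx$seed,
                          noise = fx$params$noise)
  rep <- authenticate_tag(cap, fx$sensor, fx$truth$template)
  e2e_check("tag_authenticated", as.numeric(rep$pass), 1, 0, pass = rep$pass)
}

e2e_pressure <- function(fx, tol) {
  taus <- ses <- numeric(length(fx$scenes))
  for (i in seq_along(fx$scenes)) {
    cap <- simulate_capture(fx$scenes[[i]], fx$sensor, fx$pulse,
                            fx$seed + i, noise = fx$params$noise)
    strobe <- estimate_strobe_from_capture(cap, fx$truth$strobe_channel)
    lt <- estimate_lifetime(cap, fx$sensor, strobe,
                            channel = fx$truth$analyte_channel)
    taus[i] <- lt$tau
    ses[i] <- lt$tau_se
  }
  cal <- fit_stern_volmer(
    data.frame(pressure = fx$conditions, tau = taus), "lifetime")
  rbind(
    e2e_check("K_sv_per_mbar", cal$K_sv, fx$truth$K_sv,
              tol$K_sv_rel * fx$truth$K_sv),
    e2e_check("tau0_s", cal$tau0, fx$truth$tau0,
              tol$tau0_rel * fx$truth$tau0))
}

e2e_temperature <- function(fx, tol) {
  taus <- numeric(length(fx$scenes))
  for (i in seq_along(fx$scenes)) {
    cap <- simulate_capture(fx$scenes[[i]], fx$sensor, fx$pulse,
                            fx$seed + i, noise = fx$params$noise)
    strobe <- estimate_strobe_from_capture(cap, fx$truth$strobe_channel)
    lt <- estimate_lifetime(cap, fx$sensor, strobe,
                            channel = fx$truth$analyte_channel)
    taus[i] <- lt$tau
  }
  cal <- fit_thermal_response(
    data.frame(temperature = fx$conditions, tau = taus))
  th <- fx$truth$thermal
  true_tau <- function(tk) th$tau_ref / (1 + th$prefactor * exp(-th$activation_scale / tk))
  mid <- stats::median(fx$conditions)
  checks <- e2e_check("thermal_tau_at_mid_K", thermal_curve(cal, mid),
                      true_tau(mid), tol$thermal_tau_rel * true_tau(mid))
  # ambient vs dark agreement at the middle temperature
  i <- which.min(abs(fx$conditions - mid))
  cap_d <- simulate_capture(fx$scenes[[i]], fx$sensor, fx$pulse,
                            fx$seed + 101, noise = fx$params$noise)
  cap_a <- simulate_capture(fx$scenes_ambient[[i]], fx$sensor, fx$pulse,
                            fx$seed + 102, noise = fx$params$noise)
  amb <- ambient_robustness_check(cap_a, cap_d,
                                  channel = fx$truth$analyte_channel,
                                  strobe_channel = fx$truth$strobe_channel)
  rbind(checks,
        e2e_check("ambient_dark_lifetime_agreement", as.numeric(isTRUE(amb$agree)),
                  1, 0, pass = isTRUE(amb$agree)))
}

#' @export
print.e2e_report <- function(x, ...) {
  cat(sprintf("<e2e_report> %s (seed %d): %s\n", x$scenario, x$seed,
              if (x$pass) "PASS" else "FAIL"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}
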