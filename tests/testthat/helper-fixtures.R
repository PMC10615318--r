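# Shared small test objects. Test captures use reduced image sizes; the
# physics is resolution-independent and the tolerances are stated
# per-fixture.

test_pulse <- function(frequency = 600.08, duty = 0.5, phase = 0) {
  excitation_pulse(frequency, duty, phase)
}

test_sensor <- function(n_rows = 1200, n_cols = 32, ...) {
  sensor_config(n_rows = n_rows, n_cols = n_cols, ...)
}

# uniform single-emitter scene matched to a sensor
uniform_scene <- function(sensor, em, reflect = 0, background = 0) {
  lum_scene(list(em),
            list(matrix(1, sensor$n_rows, sensor$n_cols)),
            reflectance_map = if (reflect > 0) {
              reflect * matrix(1, sensor$n_rows, sensor$n_cols)
            } else NULL,
            background = background)
}

slow_red <- function(tau = 5e-4) {
  emitter("Eu(tta)3phen", lifetime = tau, brightness = 1 / tau,
          rgb_weights = c(0.85, 0.15, 0))
}

fast_blue <- function() {
  emitter("PPE", is_fast = TRUE, brightness = 1,
          rgb_weights = c(0.1, 0.2, 0.7))
}

# brute-force trapezoid integral of emission_rate (quadrature oracle)
quad_emission <- function(t0, t1, em, pulse, panels = 1e4) {
  tt <- seq(t0, t1, length.out = panels + 1)
  e <- emission_rate(tt, em, pulse)
  sum((e[-1] + e[-length(e)]) / 2) * (t1 - t0) / panels
}

# adaptive-ODE oracle for the periodic steady state: integrate dE/dt =
# b*x(t) - E/tau from E(0) = 0 through >= 20 tau of warm-up, then sample
# one period.
ode_emission_oracle <- function(em, pulse, n_samples = 41) {
  period <- 1 / pulse$frequency
  tau <- em$lifetime
  f <- function(t, y, parms) {
    list(em$brightness * excitation_state(t, pulse) - y / tau)
  }
  warm <- ceiling(max(20 * tau, 5 * period) / period) * period
  tt <- seq(warm, warm + period, length.out = n_samples)
  sol <- deSolve::ode(y = 0, times = c(0, tt), func = f, parms = NULL,
                      rtol = 1e-10, atol = 1e-12, method = "lsoda",
                      maxsteps = 1e6, hmax = period / 20)
  list(times = tt, values = sol[-1, 2])
}
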