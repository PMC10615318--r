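# Sensing calibrations: Stern-Volmer oxygen/pressure quenching and a
# single-barrier thermal-quenching temperature response, with monotone
# inversion and delta-method prediction intervals.

normalize_series <- function(series, value_cols, condition_col) {
  if (!is.data.frame(series)) {
    sl_abort("series must be a data frame", "shutterlum_input_error")
  }
  cond <- series[[condition_col]]
  if (is.null(cond)) {
    sl_abort(sprintf("series needs a `%s` column", condition_col),
             "shutterlum_input_error")
  }
  obs <- NULL
  for (nm in value_cols) {
    if (!is.null(series[[nm]])) { obs <- series[[nm]]; break }
  }
  if (is.null(obs)) {
    sl_abort(sprintf("series needs one of: %s", paste(value_cols, collapse = ", ")),
             "shutterlum_input_error")
  }
  list(condition = cond, observable = obs)
}

#' Fit a Stern-Volmer quenching calibration
#'
#' Fits `obs(P) = obs0 / (1 + K_sv * P)` by nonlinear least squares — the
#' Stern-Volmer relation `obs0 / obs = 1 + K_sv * P` for collisional
#' quenching of a long-lived excited state, with ambient pressure standing
#' in for oxygen partial pressure. The same `K_sv` governs the intensity
#' and the lifetime form (and linearity of the decay *rate* `1/tau` in `P`
#' is the identical statement, `1/tau = (1 + K_sv P)/tau0`).
#'
#' @param series Data frame with a `pressure` column (mbar) and an
#'   `intensity`, `tau` or `observable` column.
#' @param model_form `"intensity"` or `"lifetime"` — which observable is
#'   being calibrated.
#' @return A `quench_calibration`: `K_sv` (1/mbar), `I0` (unquenched
#'   observable; also exposed as `tau0` for the lifetime form), standard
#'   errors, `residual_sd`, and the calibrated ranges.
#' @examples
#' p <- c(0, 20, 50, 100, 200, 300)
#' fit_stern_volmer(data.frame(pressure = p, intensity = 100 / (1 + 0.01 * p)))
#' @export
fit_stern_volmer <- function(series, model_form = c("intensity", "lifetime")) {
  model_form <- match.arg(model_form)
  cols <- if (model_form == "intensity") c("intensity", "observable")
          else c("tau", "observable")
  s <- normalize_series(series, cols, "pressure")
  p <- s$condition; obs <- s$observable
  if (length(unique(p)) < 3) {
    sl_abort("need >= 3 distinct pressures", "shutterlum_data_error")
  }
  if (min(p) > 0.05 * max(p)) {
    sl_abort("need a near-zero pressure point to anchor the unquenched level",
             "shutterlum_data_error")
  }
  o0_init <- obs[which.min(p)]
  k_init <- stats::coef(stats::lm(I(o0_init / obs - 1) ~ 0 + p))[[1]]
  fit <- minpack.lm::nlsLM(
    obs ~ o0 / (1 + k * p),
    start = list(o0 = o0_init, k = max(k_init, 1e-9)),
    lower = c(o0 = 0, k = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  sm <- summary(fit)
  k_se <- sm$coefficients["k", "Std. Error"]
  if (co[["k"]] < -2 * k_se) {
    sl_warn(sprintf("fitted K_sv = %.3g is negative beyond 2 SE: Stern-Volmer model misfit",
                    co[["k"]]), "shutterlum_model_misfit_warning")
  }
  structure(list(K_sv = co[["k"]], I0 = co[["o0"]],
                 tau0 = if (model_form == "lifetime") co[["o0"]] else NA_real_,
                 K_se = k_se, I0_se = sm$coefficients["o0", "Std. Error"],
                 residual_sd = sm$sigma, model_form = model_form,
                 pressure_range = range(p),
                 observable_range = range(co[["o0"]] / (1 + co[["k"]] * range(p)))),
            class = "quench_calibration")
}

#' Fit a thermal-quenching temperature calibration
#'
#' Fits the single-barrier thermal-quenching form
#' `tau(T) = tau_ref / (1 + prefactor * exp(-activation_scale / T))`
#' (temperatures in kelvin) by nonlinear least squares with a small
#' multi-start over activation scales. The fitted curve must be strictly
#' decreasing over the calibrated range.
#'
#' @param series Data frame with a `temperature` column (K) and a `tau` or
#'   `observable` column.
#' @return A `thermal_calibration` with `tau_ref` (s), `prefactor`,
#'   `activation_scale` (K), standard errors, `residual_sd` and
#'   `valid_range` (K).
#' @export
fit_thermal_response <- function(series) {
  s <- normalize_series(series, c("tau", "intensity", "observable"), "temperature")
  temp <- s$condition; tau <- s$observable
  if (length(unique(temp)) < 4) {
    sl_abort("need >= 4 distinct temperatures", "shutterlum_data_error")
  }
  tr0 <- max(tau) * 1.02
  t_hi <- max(temp)
  tau_hi <- tau[which.max(temp)]
  best <- NULL
  for (a0 in c(500, 1000, 2000, 4000, 8000)) {
    c0 <- (tr0 / tau_hi - 1) / exp(-a0 / t_hi)
    if (!is.finite(c0) || c0 <= 0) next
    fit <- try(minpack.lm::nlsLM(
      tau ~ tr / (1 + cc * exp(-aa / temp)),
      start = list(tr = tr0, cc = c0, aa = a0),
      lower = c(tr = 0, cc = 1e-12, aa = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    sl_abort("thermal-quenching fit did not converge from any start",
             "shutterlum_model_misfit_error")
  }
  fit <- best$fit
  co <- stats::coef(fit)
  sm <- summary(fit)
  curve_fun <- function(tk) co[["tr"]] / (1 + co[["cc"]] * exp(-co[["aa"]] / tk))
  grid <- seq(min(temp), max(temp), length.out = 64)
  if (any(diff(curve_fun(grid)) >= 0)) {
    sl_abort("fitted thermal response is not strictly decreasing over the data range",
             "shutterlum_model_misfit_error")
  }
  structure(list(tau_ref = co[["tr"]], prefactor = co[["cc"]],
                 activation_scale = co[["aa"]],
                 se = list(tau_ref = sm$coefficients["tr", "Std. Error"],
                           prefactor = sm$coefficients["cc", "Std. Error"],
                           activation_scale = sm$coefficients["aa", "Std. Error"]),
                 residual_sd = sm$sigma,
                 valid_range = range(temp)),
            class = "thermal_calibration")
}

#' Wald confidence intervals for thermal calibration parameters
#'
#' `tau_ref` and `activation_scale` get intervals on the natural scale; the
#' `prefactor`, a positive multiplicative parameter whose sampling
#' distribution is strongly right-skewed, gets its interval on the log
#' scale (delta method) and is reported back-transformed.
#'
#' @param cal A `thermal_calibration`.
#' @param level Confidence level.
#' @return Data frame with `parameter`, `estimate`, `lower`, `upper`.
#' @export
thermal_confint <- function(cal, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lcc <- log(cal$prefactor)
  lcc_se <- cal$se$prefactor / cal$prefactor
  data.frame(
    parameter = c("tau_ref", "prefactor", "activation_scale"),
    estimate = c(cal$tau_ref, cal$prefactor, cal$activation_scale),
    lower = c(cal$tau_ref - z * cal$se$tau_ref, exp(lcc - z * lcc_se),
              cal$activation_scale - z * cal$se$activation_scale),
    upper = c(cal$tau_ref + z * cal$se$tau_ref, exp(lcc + z * lcc_se),
              cal$activation_scale + z * cal$se$activation_scale),
    stringsAsFactors = FALSE)
}

#' Evaluate a thermal calibration curve
#' @param cal A `thermal_calibration`.
#' @param temperature Kelvin (vectorised).
#' @return Predicted lifetimes in seconds.
#' @export
thermal_curve <- function(cal, temperature) {
  cal$tau_ref / (1 + cal$prefactor * exp(-cal$activation_scale / temperature))
}

#' Invert a calibration: observable to sensed condition
#'
#' Inverts the fitted monotone response and propagates the calibration's
#' residual scale by the delta method into a condition-scale interval.
#' Observables outside the calibrated response range raise an extrapolation
#' error.
#'
#' @param cal A `quench_calibration` or `thermal_calibration`.
#' @param observable Measured intensity or lifetime (same observable the
#'   calibration was fitted on).
#' @param level Confidence level of the reported interval.
#' @return List with `value` (mbar or K), `se`, `lower`, `upper`.
#' @export
predict_condition <- function(cal, observable, level = 0.95) {
  UseMethod("predict_condition")
}

#' @export
predict_condition.quench_calibration <- function(cal, observable, level = 0.95) {
  check_scalar(observable, "observable", positive = TRUE)
  slack <- 1e-9 * cal$I0
  if (observable > cal$I0 + slack) {
    sl_abort(sprintf("observable %.4g exceeds the unquenched level %.4g: outside calibrated range",
                     observable, cal$I0), "shutterlum_extrapolation_error")
  }
  p <- (cal$I0 / min(observable, cal$I0) - 1) / cal$K_sv
  if (p > cal$pressure_range[2] * (1 + 1e-6)) {
    sl_abort(sprintf("implied pressure %.4g mbar beyond calibrated maximum %.4g",
                     p, cal$pressure_range[2]), "shutterlum_extrapolation_error")
  }
  se <- cal$residual_sd * cal$I0 / (cal$K_sv * observable^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(value = p, se = se, lower = p - z * se, upper = p + z * se)
}

#' @export
predict_condition.thermal_calibration <- function(cal, observable, level = 0.95) {
  check_scalar(observable, "observable", positive = TRUE)
  lo <- thermal_curve(cal, cal$valid_range[2])
  hi <- thermal_curve(cal, cal$valid_range[1])
  slack <- 1e-9 * hi
  if (observable > hi + slack || observable < lo - slack) {
    sl_abort(sprintf("lifetime %.4g s outside calibrated response [%.4g, %.4g]",
                     observable, lo, hi), "shutterlum_extrapolation_error")
  }
  obs <- min(max(observable, lo), hi)
  ratio <- (cal$tau_ref / obs - 1) / cal$prefactor
  tk <- -cal$activation_scale / log(ratio)
  # delta method through the forward derivative d tau / d T
  e <- cal$prefactor * exp(-cal$activation_scale / tk)
  dtau_dt <- -cal$tau_ref * e * (cal$activation_scale / tk^2) / (1 + e)^2
  se <- cal$residual_sd / abs(dtau_dt)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(value = tk, se = se, lower = tk - z * se, upper = tk + z * se)
}

#' Compare lifetime estimates under ambient vs dark lighting
#'
#' Analyses two captures of the same scene that differ only in ambient
#' background, and checks that the lifetime estimates agree within their
#' joint uncertainty while the raw intensities are free to differ — the
#' robustness that makes lifetime, unlike intensity, a field-usable
#' observable. Saturated profiles are flagged and yield no silent estimate.
#'
#' @param cap_a,cap_b Two `capture_result`s (e.g. ambient and dark).
#' @param sensor A [sensor_config()] (defaults to `cap_a$sensor`).
#' @param channel Channel carrying the slow emission.
#' @param strobe_channel Channel used for strobe estimation.
#' @param labels Names of the two conditions in the report.
#' @return An `ambient_report`: per-capture `tau`, `tau_se`, mean
#'   intensity, saturation flags, the lifetime difference, its pooled SE,
#'   and `agree` (TRUE iff |diff| <= 2 pooled SE).
#' @export
ambient_robustness_check <- function(cap_a, cap_b, sensor = NULL,
                                     channel = "R", strobe_channel = "B",
                                     labels = c("ambient", "dark")) {
  sensor <- sensor %||% cap_a$sensor
  analyze_one <- function(cap) {
    prof <- capture_profile(cap, channel)
    saturated <- length(prof$saturated_rows) > 0
    if (saturated) {
      return(list(tau = NA_real_, se = NA_real_,
                  intensity = mean(prof$values), saturated = TRUE))
    }
    strobe <- estimate_strobe_from_capture(cap, strobe_channel, sensor)
    lt <- estimate_lifetime(cap, sensor, strobe, channel = channel)
    list(tau = lt$tau, se = lt$tau_se, intensity = mean(prof$values),
         saturated = FALSE)
  }
  a <- analyze_one(cap_a)
  b <- analyze_one(cap_b)
  pooled_se <- sqrt(a$se^2 + b$se^2)
  diff_tau <- a$tau - b$tau
  agree <- if (any(c(a$saturated, b$saturated))) NA else
    abs(diff_tau) <= 2 * pooled_se
  structure(list(labels = labels,
                 tau = c(a$tau, b$tau), tau_se = c(a$se, b$se),
                 intensity = c(a$intensity, b$intensity),
                 saturated = c(a$saturated, b$saturated),
                 diff = diff_tau, pooled_se = pooled_se, agree = agree),
            class = "ambient_report")
}

#' @export
print.quench_calibration <- function(x, ...) {
  cat(sprintf("<quench_calibration> (%s) K_sv %.4g /mbar (se %.3g), %s0 %.4g\n",
              x$model_form, x$K_sv, x$K_se,
              if (x$model_form == "lifetime") "tau" else "I", x$I0))
  cat(sprintf("  residual sd %.3g over %.4g-%.4g mbar\n", x$residual_sd,
              x$pressure_range[1], x$pressure_range[2]))
  invisible(x)
}

#' @export
print.thermal_calibration <- function(x, ...) {
  cat(sprintf("<thermal_calibration> tau_ref %.4g s, prefactor %.4g, activation %.4g K\n",
              x$tau_ref, x$prefactor, x$activation_scale))
  cat(sprintf("  valid %.0f-%.0f K, residual sd %.3g\n",
              x$valid_range[1], x$valid_range[2], x$residual_sd))
  invisible(x)
}

#' @export
print.ambient_report <- function(x, ...) {
  cat("<ambient_report>\n")
  for (i in 1:2) {
    cat(sprintf("  %s: tau %.4g s (se %.3g), mean intensity %.4g%s\n",
                x$labels[i], x$tau[i], x$tau_se[i], x$intensity[i],
                if (x$saturated[i]) " [SATURATED]" else ""))
  }
  cat(sprintf("  lifetime difference %.3g s vs 2 x pooled SE %.3g -> %s\n",
              x$diff, 2 * x$pooled_se,
              if (isTRUE(x$agree)) "agree" else if (isFALSE(x$agree)) "DISAGREE" else "QC flag"))
  invisible(x)
}
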