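# Band segmentation and strobe parameter estimation from a row profile.

#' Segment a row profile into on/off bands
#'
#' Thresholds the profile at the midpoint of its robust 5th/95th
#' percentiles (stable when off bands carry slow emission, unlike Otsu on a
#' bimodal-with-decay 1-D profile), merges runs shorter than `min_run` rows
#' into their neighbours, and returns alternating half-open row intervals.
#'
#' A profile whose robust contrast `(p95 - p5)/(p95 + p5)` falls below
#' `min_contrast` raises a flat-profile error — which is itself the
#' steady-state-illumination verdict: constant excitation produces no bands
#' and therefore carries no lifetime information.
#'
#' @param profile A [extract_row_profile()] result.
#' @param min_run Minimum run length in rows; shorter runs are merged.
#' @param min_contrast Robust-contrast floor below which the profile is
#'   declared flat.
#' @param probs Percentile pair defining the robust range.
#' @return A `band_segmentation`: `intervals` data frame (`start`, `end`,
#'   `state`, 0-based half-open), `threshold`, `contrast`, and the profile.
#' @export
segment_bands <- function(profile, min_run = 3, min_contrast = 0.05,
                          probs = c(0.05, 0.95)) {
  v <- profile$values
  q <- stats::quantile(v, probs, names = FALSE, type = 7)
  denom <- q[2] + q[1]
  contrast <- if (denom > 0) (q[2] - q[1]) / denom else 0
  if (!is.finite(contrast) || contrast < min_contrast) {
    sl_abort(sprintf(
      "no banding detected (robust contrast %.3g < %.3g): profile is flat, consistent with steady illumination",
      contrast, min_contrast), "shutterlum_flat_profile_error")
  }
  threshold <- (q[1] + q[2]) / 2
  on <- v >= threshold
  repeat {
    r <- rle(on)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0) break
    # flip the shortest offending run into its neighbours, then re-scan
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[i] - r$lengths[i] + 1):ends[i]
    on[idx] <- !r$values[i]
  }
  r <- rle(on)
  if (length(r$lengths) < 4) {
    sl_abort("fewer than 2 full banding cycles in profile",
             "shutterlum_insufficient_cycles_error")
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  intervals <- data.frame(start = starts, end = ends,
                          state = ifelse(r$values, "on", "off"),
                          stringsAsFactors = FALSE)
  structure(list(intervals = intervals, threshold = threshold,
                 contrast = contrast, profile = profile),
            class = "band_segmentation")
}

# Sub-row refinement of a band edge: linear interpolation of the threshold
# crossing among the rows bracketing the interval boundary `b` (0-based row
# index of the first row of the new state). Returns a fractional row index
# in window-centre coordinates.
refine_edge <- function(values, b, threshold, rising) {
  n <- length(values)
  best <- NA_real_
  best_dist <- Inf
  for (j in max(1, b - 3):min(n - 1, b + 2)) {
    v0 <- values[j]       # row j - 1 (0-based)
    v1 <- values[j + 1]   # row j
    hit <- if (rising) v0 < threshold && v1 >= threshold
           else v0 >= threshold && v1 < threshold
    if (hit) {
      frac <- (threshold - v0) / (v1 - v0)
      cand <- (j - 1) + frac
      if (abs(cand - b) < best_dist) {
        best <- cand
        best_dist <- abs(cand - b)
      }
    }
  }
  if (is.na(best)) b - 0.5 else best
}

#' Estimate strobe frequency, duty cycle and phase from a segmentation
#'
#' Band edges are refined to sub-row precision by linear interpolation of
#' the threshold crossing; the rows-per-cycle period is the mean spacing of
#' like edges (rising-to-rising and falling-to-falling pooled), the duty
#' cycle the mean on-band width over the period, and the frequency
#' `1 / (period_rows * line_time)`. First and last (possibly partial) bands
#' contribute no widths, and edge-spacing scatter feeds the standard
#' errors.
#'
#' @param seg A [segment_bands()] result.
#' @param sensor A [sensor_config()] supplying the line time.
#' @return A `strobe_estimate` with `frequency` (Hz), `duty_cycle`,
#'   `phase_row` (fractional row of the first rising edge), `period_rows`,
#'   `n_cycles` and `se` (standard errors).
#' @export
estimate_strobe <- function(seg, sensor) {
  v <- seg$profile$values
  thr <- seg$threshold
  iv <- seg$intervals
  rising <- numeric(0)
  falling <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    b <- iv$start[i]
    if (iv$state[i] == "on") rising <- c(rising, refine_edge(v, b, thr, TRUE))
    else falling <- c(falling, refine_edge(v, b, thr, FALSE))
  }
  if (length(rising) < 2 || length(falling) < 2) {
    sl_abort("fewer than 2 complete strobe cycles: cannot estimate period",
             "shutterlum_insufficient_cycles_error")
  }
  spacings <- c(diff(rising), diff(falling))
  period_rows <- mean(spacings)
  period_se <- if (length(spacings) > 1) stats::sd(spacings) / sqrt(length(spacings)) else NA_real_
  # on widths: each rising edge paired with the next falling edge
  widths <- numeric(0)
  for (r in rising) {
    f <- falling[falling > r]
    if (length(f) > 0 && (f[1] - r) < 1.5 * period_rows) {
      widths <- c(widths, f[1] - r)
    }
  }
  if (length(widths) == 0) {
    sl_abort("no complete on band between detected edges",
             "shutterlum_insufficient_cycles_error")
  }
  duty <- mean(widths) / period_rows
  duty_se <- if (length(widths) > 1) {
    stats::sd(widths / period_rows) / sqrt(length(widths))
  } else NA_real_
  frequency <- 1 / (period_rows * sensor$line_time)
  freq_se <- if (is.na(period_se)) NA_real_ else frequency * period_se / period_rows
  structure(list(frequency = frequency, duty_cycle = duty,
                 phase_row = rising[1] %% period_rows,
                 period_rows = period_rows,
                 n_cycles = length(rising),
                 se = list(frequency = freq_se, duty_cycle = duty_se,
                           period_rows = period_se)),
            class = "strobe_estimate")
}

#' Build a strobe estimate directly from a capture
#'
#' Convenience wrapper: profile, segmentation and strobe estimation in one
#' call.
#'
#' @param capture A `capture_result` (or list with `image` and `sensor`).
#' @param channel Channel to profile — pick one dominated by a fast emitter
#'   or the direct LED reflection.
#' @param sensor Sensor configuration (defaults to the capture's).
#' @inheritParams extract_row_profile
#' @return A `strobe_estimate`.
#' @export
estimate_strobe_from_capture <- function(capture, channel = "B",
                                         sensor = NULL, col_start = NULL,
                                         col_end = NULL) {
  sensor <- sensor %||% capture$sensor
  prof <- capture_profile(capture, channel, col_start, col_end)
  estimate_strobe(segment_bands(prof), sensor)
}

#' @export
print.strobe_estimate <- function(x, ...) {
  cat(sprintf("<strobe_estimate> %.4f Hz (se %.3g), duty %.4f (se %.3g)\n",
              x$frequency, x$se$frequency %||% NA, x$duty_cycle,
              x$se$duty_cycle %||% NA))
  cat(sprintf("  period %.3f rows, first rising edge at row %.2f, %d cycles\n",
              x$period_rows, x$phase_row, x$n_cycles))
  invisible(x)
}
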