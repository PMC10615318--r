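# Lifetime-based authentication of spatially patterned luminescent tags:
# each template region must show the expected channel/lifetime signature
# under pulsed excitation; constant illumination cannot reveal the pattern
# and is refused with a flat-profile error.

#' Authentication template for a patterned tag
#'
#' @param ... Region descriptors, each a list with `name`, `col_start`,
#'   `col_end` (0-based half-open columns), `channel` ("R"/"G"/"B"),
#'   `kind` ("slow" or "fast"), and for slow regions `tau_ref` (s) and
#'   `tolerance` (relative).
#' @return A `tag_template`.
#' @export
tag_template <- function(...) {
  regions <- list(...)
  if (length(regions) == 1 && is.null(regions[[1]]$name)) regions <- regions[[1]]
  for (r in regions) {
    if (is.null(r$name) || is.null(r$col_start) || is.null(r$col_end) ||
        is.null(r$channel) || is.null(r$kind)) {
      sl_abort("each region needs name, col_start, col_end, channel, kind",
               "shutterlum_input_error")
    }
    if (r$kind == "slow" && (is.null(r$tau_ref) || is.null(r$tolerance))) {
      sl_abort(sprintf("slow region '%s' needs tau_ref and tolerance", r$name),
               "shutterlum_input_error")
    }
  }
  structure(list(regions = regions), class = "tag_template")
}

#' Authenticate a luminescent security tag
#'
#' Estimates the strobe from a fast region, then checks every template
#' region: slow regions must yield an aggregated off-band lifetime within
#' tolerance of their reference, fast regions must band with the strobe
#' while yielding *no* off-band lifetime (their emission lives only in the
#' on band). The tag passes iff every region passes. A steady-illumination
#' capture has no bands and is refused with a flat-profile error — constant
#' light cannot reveal the time-resolved pattern.
#'
#' @param x A `capture_result` or integer image array.
#' @param sensor A [sensor_config()] (defaults to the capture's).
#' @param template A [tag_template()].
#' @param strobe Optional pre-computed `strobe_estimate`; otherwise
#'   estimated from the first fast region.
#' @param min_on_off_ratio Minimum on/off band intensity ratio for a fast
#'   region to count as banding.
#' @return A `tag_report`: per-region data frame and overall `pass`.
#' @export
authenticate_tag <- function(x, sensor = NULL, template, strobe = NULL,
                             min_on_off_ratio = 2) {
  sensor <- sensor %||% x$sensor
  img <- if (inherits(x, "capture_result")) x$image else x
  chans <- split_channels(img)
  n_c <- ncol(chans$R)
  for (r in template$regions) {
    if (r$col_start < 0 || r$col_end > n_c || r$col_start >= r$col_end) {
      sl_abort(sprintf("region '%s' columns [%d, %d) outside image (%d cols)",
                       r$name, r$col_start, r$col_end, n_c),
               "shutterlum_geometry_error")
    }
  }
  region_profile <- function(r) {
    extract_row_profile(chans[[r$channel]], r$col_start, r$col_end,
                        max_code = max_code(sensor), name = r$channel)
  }
  if (is.null(strobe)) {
    fast_idx <- which(vapply(template$regions, function(r) r$kind == "fast",
                             logical(1)))
    ref <- template$regions[[if (length(fast_idx) > 0) fast_idx[1] else 1]]
    strobe <- estimate_strobe(segment_bands(region_profile(ref)), sensor)
  }
  rows <- lapply(template$regions, function(r) {
    tau_hat <- NA_real_; tau_se <- NA_real_; pass <- FALSE; note <- ""
    if (r$kind == "slow") {
      est <- tryCatch(
        estimate_lifetime(img, sensor, strobe, channel = r$channel,
                          col_start = r$col_start, col_end = r$col_end),
        shutterlum_error = function(e) e)
      if (inherits(est, "condition")) {
        note <- conditionMessage(est)
      } else {
        tau_hat <- est$tau; tau_se <- est$tau_se
        pass <- abs(tau_hat - r$tau_ref) / r$tau_ref <= r$tolerance
        if (!pass) note <- sprintf("tau %.3g s outside %.0f%% of %.3g s",
                                   tau_hat, 100 * r$tolerance, r$tau_ref)
      }
    } else {
      prof <- region_profile(r)
      seg <- tryCatch(segment_bands(prof), shutterlum_error = function(e) e)
      if (inherits(seg, "condition")) {
        note <- "no banding in fast region"
      } else {
        on_rows <- unlist(mapply(function(s, e, st) if (st == "on") seq.int(s, e - 1) else NULL,
                                 seg$intervals$start, seg$intervals$end,
                                 seg$intervals$state, SIMPLIFY = FALSE))
        off_rows <- setdiff(seq_len(prof$n_rows) - 1L, on_rows)
        ratio <- mean(prof$values[on_rows + 1]) /
          max(mean(prof$values[off_rows + 1]), .Machine$double.eps)
        lt <- tryCatch(
          estimate_lifetime(img, sensor, strobe, channel = r$channel,
                            col_start = r$col_start, col_end = r$col_end),
          shutterlum_error = function(e) e)
        no_slow <- inherits(lt, "condition")
        pass <- ratio >= min_on_off_ratio && no_slow
        if (!no_slow) note <- sprintf(
          "unexpected off-band lifetime %.3g s in fast region", lt$tau)
        else if (ratio < min_on_off_ratio) note <- sprintf(
          "weak on/off contrast (ratio %.2f)", ratio)
      }
    }
    data.frame(region = r$name, kind = r$kind, channel = r$channel,
               tau_ref = r$tau_ref %||% NA_real_, tau_hat = tau_hat,
               tau_se = tau_se, pass = pass, note = note,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  structure(list(regions = report, pass = all(report$pass), strobe = strobe),
            class = "tag_report")
}

#' @export
print.tag_report <- function(x, ...) {
  cat(sprintf("<tag_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$regions, row.names = FALSE)
  invisible(x)
}
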