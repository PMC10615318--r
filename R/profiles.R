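# Channel separation and row-profile extraction: the in-code equivalent of
# splitting an RGB capture into channels and running a plot-profile over a
# column range.

#' Split an RGB image into channels
#'
#' @param image A `capture_result` or an `n_rows x n_cols x 3` array.
#' @return Named list of matrices `R`, `G`, `B`; summing them reassembles
#'   the input exactly.
#' @export
split_channels <- function(image) {
  if (inherits(image, "capture_result")) image <- image$image
  d <- dim(image)
  if (length(d) != 3 || d[3] < 3) {
    sl_abort("expected a 3-channel image array", "shutterlum_channel_error")
  }
  list(R = image[, , 1], G = image[, , 2], B = image[, , 3])
}

#' Per-row mean intensity profile of one channel
#'
#' @param channel_image A grayscale matrix (one channel).
#' @param col_start,col_end 0-based half-open column range; default the
#'   middle 50% of columns.
#' @param max_code Digital code value at saturation; rows containing any
#'   saturated pixel in the range are flagged.
#' @param name Channel label carried into reports.
#' @return A `row_profile` with `values` (length `n_rows`), `saturated_rows`
#'   (0-based) and the column range used.
#' @export
extract_row_profile <- function(channel_image, col_start = NULL,
                                col_end = NULL, max_code = NULL,
                                name = "gray") {
  n_c <- ncol(channel_image)
  col_start <- col_start %||% floor(n_c / 4)
  col_end <- col_end %||% (n_c - floor(n_c / 4))
  if (!is_scalar_number(col_start) || !is_scalar_number(col_end) ||
      col_start < 0 || col_end > n_c || col_start >= col_end) {
    sl_abort(sprintf("column range [%s, %s) invalid for %d columns",
                     format(col_start), format(col_end), n_c),
             "shutterlum_range_error")
  }
  sub <- channel_image[, (col_start + 1):col_end, drop = FALSE]
  saturated <- integer(0)
  if (!is.null(max_code)) {
    saturated <- which(rowSums(sub >= max_code) > 0) - 1L
  }
  structure(list(channel = name, values = rowMeans(sub),
                 n_rows = nrow(channel_image),
                 saturated_rows = saturated,
                 col_start = col_start, col_end = col_end),
            class = "row_profile")
}

#' Row profile straight from a capture
#'
#' @param capture A `capture_result` (or list with `image` and `sensor`).
#' @param channel "R", "G" or "B".
#' @inheritParams extract_row_profile
#' @return A `row_profile`.
#' @export
capture_profile <- function(capture, channel = c("R", "G", "B"),
                            col_start = NULL, col_end = NULL) {
  channel <- match.arg(channel)
  chans <- split_channels(capture$image)
  mc <- if (!is.null(capture$sensor)) max_code(capture$sensor) else NULL
  extract_row_profile(chans[[channel]], col_start, col_end,
                      max_code = mc, name = channel)
}

#' @export
print.row_profile <- function(x, ...) {
  cat(sprintf("<row_profile> channel %s, %d rows, cols [%d, %d), %d saturated\n",
              x$channel, x$n_rows, x$col_start, x$col_end,
              length(x$saturated_rows)))
  invisible(x)
}
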