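# Classed conditions so callers can distinguish scientific verdicts (e.g. a
# flat profile under steady illumination) from plain input mistakes.

sl_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "shutterlum_error")))
}

sl_warn <- function(message, class, ...) {
  warning(warningCondition(message, ..., class = c(class, "shutterlum_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    sl_abort(sprintf("`%s` must be a single finite number", name), "shutterlum_input_error")
  }
  if (positive && x <= 0) {
    sl_abort(sprintf("`%s` must be > 0 (got %g)", name, x), "shutterlum_input_error")
  }
  invisible(x)
}
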