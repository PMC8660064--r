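#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------
# All package errors inherit from "sedem_error" plus a specific subclass so
# callers (and the CLI) can branch on failure mode without string matching.

sedem_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "sedem_error", "error"),
                      call = call))
}

abort_invalid_measurement <- function(message) {
  sedem_abort(message, "sedem_invalid_measurement")
}

abort_insufficient_data <- function(message) {
  sedem_abort(message, "sedem_insufficient_data")
}

abort_missing_field <- function(message) {
  sedem_abort(message, "sedem_missing_field")
}

abort_validation <- function(message) {
  sedem_abort(message, "sedem_validation")
}

abort_registry <- function(message) {
  sedem_abort(message, "sedem_registry")
}

#' Round half away from zero
#'
#' Reported SeDeM radii and indices are conventionally rounded half-up
#' (2.5 -> 3), not to even as [base::round()] does.  Internal computation is
#' always full precision; this helper is applied only at reporting boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Vectorised check for a single finite numeric scalar
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_number <- function(x, what) {
  if (!is_number(x)) {
    abort_invalid_measurement(sprintf("%s must be a single finite number", what))
  }
  invisible(x)
}
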