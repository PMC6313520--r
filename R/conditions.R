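#' @keywords internal
#' Signal a parameter-validation failure, naming the offending field.
stop_invalid <- function(field, msg, call. = FALSE) {
  stop(structure(
    class = c("pharminv_invalid", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = sys.call(-1))
  ))
}

#' @keywords internal
#' Signal an infeasible instance (constraints cannot be satisfied).
stop_infeasible <- function(msg, violated = character()) {
  stop(structure(
    class = c("pharminv_infeasible", "error", "condition"),
    list(message = msg, call = sys.call(-1), violated = violated)
  ))
}

check_number <- function(x, field, lower = -Inf, strict = FALSE, upper = Inf,
                         upper_strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(field, "must be a single finite number")
  if (strict && x <= lower)
    stop_invalid(field, sprintf("must be > %g", lower))
  if (!strict && x < lower)
    stop_invalid(field, sprintf("must be >= %g", lower))
  if (upper_strict && x >= upper)
    stop_invalid(field, sprintf("must be < %g", upper))
  if (x > upper)
    stop_invalid(field, sprintf("must be <= %g", upper))
  invisible(x)
}
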