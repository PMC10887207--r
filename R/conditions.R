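# Structured error conditions. Every error raised by the package carries the
# class "pwv_error" plus one or more specific classes ("pwv_<class>"), so
# callers (and the CLI exit-code mapper) can dispatch on failure kind.

pwv_abort <- function(class, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(paste0("pwv_", class), "pwv_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

# Argument guards used across modules ---------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    pwv_abort("invalid_argument", sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    pwv_abort("invalid_argument", sprintf("`%s` must be a single non-negative finite number", name))
  }
  invisible(x)
}
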