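# Classed conditions so callers can distinguish failure modes programmatically.
# Every error raised by the package carries the superclass "mircore_error".

abort_mircore <- function(message, class, call = NULL) {
  stop(errorCondition(message, class = c(class, "mircore_error"), call = call))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort_mircore(
      sprintf("`%s` must be a single finite number in [%s, %s], got: %s",
              name, format(lower), format(upper), paste(format(x), collapse = ", ")),
      class = "mircore_parameter_error"
    )
  }
  invisible(x)
}
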