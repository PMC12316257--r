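# Structured conditions so callers (and the CLI) can distinguish bad input
# from a sampler that failed to converge.

abort_validation <- function(msg, ..., data = NULL) {
  stop(structure(
    class = c("shadecarbon_validation_error", "error", "condition"),
    list(message = paste0(msg, ...), call = sys.call(-1), data = data)
  ))
}

abort_convergence <- function(msg, diagnostics = NULL) {
  stop(structure(
    class = c("shadecarbon_convergence_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), diagnostics = diagnostics)
  ))
}

# stopifnot-style scalar checks used across constructors
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper)
    abort_validation(sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}
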