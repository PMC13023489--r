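# Internal helpers shared across modules.

# Classed error conditions so callers/tests can distinguish failure modes:
#  - dcb_domain_error     : argument outside its mathematical domain
#  - dcb_validation_error : structurally invalid input (wrong shape/label)
#  - dcb_resolution_error : mesh spacing too coarse for a region
#  - dcb_convergence_error: search/controller could not meet its contract
#  - dcb_numerical_error  : linear solve / stepping failure
dcb_abort <- function(message, class) {
  stop(structure(
    class = c(class, "dcb_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stopifnot_positive <- function(x, name, class = "dcb_validation_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    dcb_abort(sprintf("'%s' must be a single positive finite number", name), class)
  }
  invisible(x)
}

# seconds in a day / week, used throughout the retention stage
SECONDS_PER_DAY <- 86400
SECONDS_PER_WEEK <- 7 * 86400
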