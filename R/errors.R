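# Classed conditions so callers (and tests) can distinguish bad inputs from
# bad configuration from numerical failures.

abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("specswap_input_error", "specswap_error")))
}

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("specswap_config_error", "specswap_error")))
}

abort_fit <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("specswap_fit_error", "specswap_error")))
}

# Run an expression with a private RNG stream: the global .Random.seed is
# restored afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_config("seed must be a single finite number, got %s",
                 paste(seed, collapse = ","))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
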