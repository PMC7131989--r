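# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed from a base seed and integer tags
#'
#' Mixes a base seed with a sequence of small non-negative integers into a
#' new seed in [1, 2^31 - 2]. Used so that every cross-validation cell
#' (iteration, algorithm, inner fold, ...) draws from its own reproducible
#' stream while the whole benchmark remains a pure function of one seed.
#'
#' @param seed integer base seed.
#' @param ... non-negative integer tags identifying the consumer.
#' @return an integer seed.
#' @keywords internal
mix_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(seed) %% m
  for (tag in c(...)) {
    # multiplier < 2^22 keeps x * mult + tag < 2^53 (exact in doubles)
    x <- (x * 1103515 + as.numeric(tag) + 12820163) %% m
  }
  as.integer(x + 1)
}

# Evaluate code with a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Condition constructors: every classbench error carries a subclass so that
# callers (and tests) can distinguish format/integrity/schema/... failures.
cb_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "classbench_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_whole <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)
}
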