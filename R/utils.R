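`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that identical seeds give bit-identical output and no
#' global RNG state leaks.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    stopf("'seed' must be a single integer value")
  }
  withr::with_seed(as.integer(seed), code)
}

# is x a single non-missing number?
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
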