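# Internal helpers: classed conditions and reproducible RNG scoping.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clonodiv_validation_error", "clonodiv_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clonodiv_format_error",
                                "clonodiv_validation_error", "clonodiv_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clonodiv_degenerate_error",
                                "clonodiv_validation_error", "clonodiv_error")))
}

stop_estimation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clonodiv_estimation_error", "clonodiv_error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clonodiv_usage_error", "clonodiv_error")))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this; no wall-clock seeding.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("seed must be a single number, got %s", deparse(seed))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seeds (e.g. one per model/curve/restart) that stay
# within the 32-bit integer range. Arithmetic in doubles (exact below 2^53)
# so large seeds or indices cannot overflow R's 32-bit integers.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
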