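# Internal helpers: seeded evaluation and per-patient RNG stream splitting.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-patient seed derived from the global seed, so a patient's
# simulated data do not depend on cohort size or position. Multiplicative
# lagged scheme modulo the largest representable integer seed.
patient_seed <- function(seed, i) {
  (as.numeric(seed) + 48271 * as.numeric(i)) %% 2147483647
}

assert_prob_vector <- function(p, what, tol = 1e-12) {
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop(sprintf("%s must be a probability vector summing to 1", what), call. = FALSE)
  invisible(p)
}

# Modal category with ties broken toward the lower (worse) category.
modal_category <- function(probs, levels = GOSE_LEVELS) {
  levels[which.max(probs)]
}
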