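# Independent oracles: event-driven (Gillespie) simulation of many CTMC
# paths, vectorized over paths, and a brute-force metric recomputation.
# These never touch the matrix-exponential code they are used to check.

# Simulate n_paths homogeneous CTMC paths from a fixed initial state and
# return the states at the requested times (n_paths x length(times)).
gillespie_states <- function(Q, init, times, n_paths) {
  exit <- -diag(Q)
  jump_prob <- Q
  diag(jump_prob) <- 0
  jump_prob <- jump_prob / ifelse(exit > 0, exit, 1)
  t_max <- max(times)
  t_now <- numeric(n_paths)
  s_now <- rep(init, n_paths)
  out <- matrix(NA_integer_, n_paths, length(times))
  # a path is frozen permanently once its next jump would fall past t_max
  # (or its state is absorbing); each jump consumes exactly one draw
  active <- rep(exit[init] > 0, n_paths)
  while (any(active)) {
    idx <- which(active)
    nxt <- t_now[idx] + rexp(length(idx), exit[s_now[idx]])
    for (j in seq_along(times)) {
      rec <- idx[is.na(out[idx, j]) & t_now[idx] <= times[j] & nxt > times[j]]
      out[rec, j] <- s_now[rec]
    }
    done <- nxt > t_max
    active[idx[done]] <- FALSE
    adv <- idx[!done]
    if (length(adv)) {
      u <- runif(length(adv))
      cum <- jump_prob[s_now[adv], , drop = FALSE]
      for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1]
      hit <- cum >= matrix(u, nrow(cum), ncol(cum))
      s_now[adv] <- max.col(hit, ties.method = "first")
      t_now[adv] <- nxt[!done]
      active[adv[exit[s_now[adv]] == 0]] <- FALSE
    }
  }
  for (j in seq_along(times)) {
    rec <- is.na(out[, j])
    out[rec, j] <- s_now[rec]
  }
  out
}

# Brute-force metric recomputation straight from the definitions, pair by
# pair, fold by fold, without reusing any package internals.
brute_metrics <- function(observed, imputed, probs, fold) {
  folds <- sort(unique(fold))
  per_fold <- function(stat) {
    vals <- vapply(folds, function(f) stat(which(fold == f)), numeric(1))
    c(mean = mean(vals),
      se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_)
  }
  db_one <- function(i) {
    y <- observed[i]
    sum(probs[i, (3:8) > y]) - sum(probs[i, (3:8) < y])
  }
  list(
    bias = per_fold(function(ix) mean(imputed[ix] - observed[ix])),
    d_bias = per_fold(function(ix) mean(vapply(ix, db_one, numeric(1)))),
    mae = per_fold(function(ix) mean(abs(imputed[ix] - observed[ix]))),
    rmse = per_fold(function(ix) sqrt(mean((imputed[ix] - observed[ix])^2))))
}
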