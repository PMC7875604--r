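# Shared fixtures, built in code. Expensive objects are memoized so several
# test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Tiny hand-made cohort with known structure.
toy_cohort <- function() {
  obs <- data.frame(
    patient_id = c("a", "a", "a", "b", "c", "c", "d"),
    time_days = c(14, 95, 200, 200, 30, 170, 100),
    gose = c(5, 6, 7, 6, 3, 4, 8))
  gose_cohort(obs)
}

# Moderate simulated cohort reused across module tests.
small_cohort <- function() cached("small_cohort",
  simulate_cohort(synthetic_config(n_patients = 300, seed = 11)))

# The default study-scale cohort and its full cross-validated comparison
# (shared by the headline and invariant acceptance tests).
default_cohort <- function() cached("default_cohort",
  simulate_cohort(synthetic_config(n_patients = 3000, seed = 20)))

default_cv_pairs <- function() cached("default_cv_pairs",
  run_cv(default_cohort(),
         methods = c("locf", "mice", "msm", "clmm", "gp"),
         spec = cv_spec(k = 3, seed = 20)))

# An msm_fit object with prescribed intensities (bypasses fitting).
manual_msm_fit <- function(up, down, pi0 = rep(1 / 6, 6), ref_day = 14,
                           knot = NULL, log_post_scale = 0) {
  stru <- msm_structure()
  q <- numeric(nrow(stru))
  for (i in seq_len(nrow(stru))) {
    f <- stru$from[i]; t <- stru$to[i]
    q[i] <- if (t == f + 1) up[f] else down[t]
  }
  structure(list(structure = stru, logq = log(pmax(q, 1e-300)),
                 beta = rep(0, nrow(stru)), use_cov = FALSE,
                 knot = knot, log_post_scale = log_post_scale,
                 pi0 = pi0, ref_day = ref_day, report = NULL),
            class = "msm_fit")
}

# Evaluation pairs built directly from point imputations (single fold).
pairs_from_points <- function(observed, imputed, fold = 1) {
  rows <- lapply(seq_along(observed), function(i) {
    r <- goseimpute:::new_prediction(sprintf("p%03d", i), "manual",
                                     goseimpute:::point_mass(imputed[i]))
    r$fold <- fold
    r$observed <- observed[i]
    r$locf_applicable <- TRUE
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gose_eval_pairs", "data.frame")
  out
}
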