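# Cross-validation protocol, metrics, confusion matrices, subgroup tests.

test_that("metrics match a brute-force recomputation on a small pair set", {
  set.seed(6)
  observed <- sample(3:8, 18, replace = TRUE)
  imputed <- pmin(pmax(observed + sample(-2:2, 18, replace = TRUE), 3), 8)
  fold <- rep(1:3, each = 6)
  pr <- do.call(rbind, lapply(1:3, function(f)
    pairs_from_points(observed[fold == f], imputed[fold == f], fold = f)))
  class(pr) <- c("gose_eval_pairs", "data.frame")
  met <- compute_metrics(pr, "locf_subset")
  probs <- as.matrix(pr[paste0("gose", 3:8)])
  oracle <- brute_metrics(pr$observed, pr$point, probs, pr$fold)
  ov <- met[met$category == "overall", ]
  for (m in names(oracle)) {
    expect_equal(ov$fold_mean[ov$metric == m], unname(oracle[[m]]["mean"]),
                 tolerance = 1e-12)
    expect_equal(ov$se[ov$metric == m], unname(oracle[[m]]["se"]),
                 tolerance = 1e-12)
  }
})

test_that("perfect imputation zeroes every metric", {
  pr <- pairs_from_points(c(3, 5, 8, 6), c(3, 5, 8, 6))
  met <- compute_metrics(pr, "full")
  ov <- met[met$category == "overall", ]
  expect_equal(ov$fold_mean, rep(0, 4))
})

test_that("directional bias evaluates the definition directly", {
  # probs {3:.2, 4:.5, 5:.3}, observed 4 -> 0.3 - 0.2 = 0.1
  r <- goseimpute:::new_prediction("p1", "m", c(0.2, 0.5, 0.3, 0, 0, 0))
  r$fold <- 1; r$observed <- 4; r$locf_applicable <- TRUE
  expect_equal(d_bias(r), 0.1, tolerance = 1e-12)
  # point mass at the observed value -> 0
  r2 <- pairs_from_points(6, 6)
  expect_equal(d_bias(r2), 0)
  # all mass above the observed value -> +1
  r3 <- goseimpute:::new_prediction("p1", "m", c(0, 0, 0, 0, 0.4, 0.6))
  r3$fold <- 1; r3$observed <- 4; r3$locf_applicable <- TRUE
  expect_equal(d_bias(r3), 1)
})

test_that("fold assignment is stratified, deterministic, and partitions the eligible set", {
  co <- small_cohort()
  spec <- cv_spec(k = 3, seed = 77)
  f1 <- make_folds(co, spec)
  f2 <- make_folds(co, spec)
  expect_identical(f1, f2)
  expect_setequal(unique(f1$fold), 1:3)
  # stratification: per-fold category counts within 1 of proportionality
  for (cat in unique(f1$observed)) {
    counts <- table(factor(f1$fold[f1$observed == cat], levels = 1:3))
    expect_lte(max(counts) - min(counts), 1)
  }
  # three eligible patients with k = 3 -> one per fold
  el <- f1$patient_id[1:3]
  mini <- gose_cohort(co$obs[co$obs$patient_id %in% el, ])
  fm <- make_folds(mini, spec)
  expect_equal(sort(fm$fold), 1:3)
})

test_that("too few eligible patients is an error", {
  obs <- data.frame(patient_id = c("a", "b"), time_days = c(180, 181), gose = c(5, 6))
  expect_error(make_folds(gose_cohort(obs), cv_spec(k = 3)),
               "at least 3 eligible")
})

test_that("cross-validation removes only the window and keeps out-of-window rows", {
  co <- small_cohort()
  spec <- cv_spec(k = 3, seed = 77)
  folds <- make_folds(co, spec)
  test_ids <- folds$patient_id[folds$fold == 1]
  train <- goseimpute:::remove_window_obs(co, test_ids, spec)
  in_win <- train$obs$time_days >= 166 & train$obs$time_days <= 194
  expect_false(any(train$obs$patient_id[in_win] %in% test_ids))
  # out-of-window rows of test patients remain available to fitters
  out_rows_before <- sum(co$obs$patient_id %in% test_ids &
                           (co$obs$time_days < 166 | co$obs$time_days > 194))
  out_rows_after <- sum(train$obs$patient_id %in% test_ids)
  expect_equal(out_rows_after, out_rows_before)
  # other patients untouched
  expect_equal(train$obs[!train$obs$patient_id %in% test_ids, ],
               co$obs[!co$obs$patient_id %in% test_ids, ])
})

test_that("run_cv covers the eligible set exactly once per method", {
  co <- small_cohort()
  spec <- cv_spec(k = 3, seed = 77)
  pairs <- run_cv(co, methods = c("locf", "msm"), spec = spec)
  folds <- make_folds(co, spec)
  for (m in c("locf", "msm")) {
    pm <- pairs[pairs$method == m, ]
    expect_setequal(pm$patient_id, folds$patient_id)
    expect_false(anyDuplicated(pm$patient_id) > 0)
  }
  expect_error(run_cv(co, methods = "nope", spec = spec), "unknown method")
})

test_that("confusion matrices satisfy their accounting identities", {
  co <- small_cohort()
  pairs <- run_cv(co, methods = c("locf", "msm"), spec = cv_spec(k = 3, seed = 77))
  msm <- pairs[pairs$method == "msm", ]
  cm <- confusion_matrices(msm, "full")
  k <- length(unique(pairs$fold))
  fp <- goseimpute:::filter_population(msm, "full")
  expect_equal(sum(cm$counts), nrow(fp) / k, tolerance = 1e-12)
  nonzero <- colSums(cm$counts) > 0
  expect_equal(unname(colSums(cm$normalized)[nonzero]),
               rep(1, sum(nonzero)), tolerance = 1e-12)
  # perfect imputation gives the identity pattern
  perfect <- pairs_from_points(c(3, 4, 5, 6, 7, 8), c(3, 4, 5, 6, 7, 8))
  cmp <- confusion_matrices(perfect, "full")
  expect_equal(unname(diag(cmp$normalized)), rep(1, 6))
})

test_that("inverse-transform draws reproduce the distribution", {
  expect_equal(draw_multiple_imputations(c(0, 0, 0, 1, 0, 0), 20, seed = 1),
               rep(6L, 20))
  p <- c(0, 0, 0, 0.5, 0.5, 0)
  d1 <- draw_multiple_imputations(p, 10000, seed = 42)
  d2 <- draw_multiple_imputations(p, 10000, seed = 42)
  expect_identical(d1, d2)
  f6 <- mean(d1 == 6)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(f6 - 0.5), 3 * se)
  expect_true(all(d1 %in% c(6L, 7L)))
})

test_that("subgroup table skips constant covariates and is exact under equality", {
  obs <- data.frame(patient_id = sprintf("p%02d", 1:40),
                    time_days = rep(c(90, 200), 20),
                    gose = rep(5:6, 20))
  covs <- data.frame(patient_id = sprintf("p%02d", 1:40),
                     fixed = 1,
                     sex = rep(0:1, each = 20))
  co <- gose_cohort(obs, covs)
  tab <- subgroup_table(co)
  expect_match(tab$note[tab$variable == "fixed"], "single observed level")
  # identical group distributions -> chi-squared p of 1
  even <- table(rep(c(TRUE, FALSE), each = 20), rep(0:1, 20))
  expect_equal(chisq_p(even), 1)
})
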