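# Cross-validated performance assessment.
#
# Evaluation mimics a missing-completely-at-random mechanism: eligible
# patients are those with a valid GOSe within target +/- 14 days; in each
# fold ALL in-window observations of the fold's patients are removed, every
# method is fitted on everything that remains (including the test patients'
# out-of-window observations and all ineligible patients), and the removed
# window value serves as ground truth. Metrics are computed within fold and
# averaged; the standard error is over folds. Because LOCF cannot impute
# patients without a pre-target observation, comparisons including LOCF are
# restricted to the subset where it applies, for all methods alike.

#' Cross-validation specification
#'
#' @param k number of folds (default 3).
#' @param target_day imputation target (default 180).
#' @param window_halfwidth half-width of the validation window in days
#'   (default 14).
#' @param seed seed for fold assignment.
#' @param stratify_by_observed stratify fold assignment by the observed
#'   window category (default `TRUE`).
#' @return List of class `cv_spec`.
#' @export
cv_spec <- function(k = 3, target_day = DEFAULT_TARGET_DAY,
                    window_halfwidth = 14, seed = 1,
                    stratify_by_observed = TRUE) {
  stopifnot(k >= 2, window_halfwidth > 0)
  structure(list(k = k, target_day = target_day,
                 window_halfwidth = window_halfwidth, seed = seed,
                 stratify_by_observed = stratify_by_observed),
            class = "cv_spec")
}

# Observed ground-truth category per eligible patient: the in-window
# observation closest to the target day (ties to the earlier one).
# Category-1 observations are never valid ground truth.
eligible_observed <- function(cohort, spec) {
  lo <- spec$target_day - spec$window_halfwidth
  hi <- spec$target_day + spec$window_halfwidth
  res <- lapply(split_obs(cohort), function(d) {
    w <- d[d$time_days >= lo & d$time_days <= hi & d$gose != 1, , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    ord <- order(abs(w$time_days - spec$target_day), w$time_days)
    data.frame(patient_id = d$patient_id[1], observed = w$gose[ord[1]])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign eligible patients to cross-validation folds
#'
#' Eligible patients (at least one valid observation within the window,
#' alive at the target day) are partitioned into `k` folds, by default
#' stratified on the observed window category so the test sets are balanced.
#' Ineligible patients are always train-only.
#'
#' @param cohort a `gose_cohort`.
#' @param spec a `cv_spec`.
#' @return Data frame with `patient_id`, `observed`, `fold`.
#' @export
make_folds <- function(cohort, spec = cv_spec()) {
  el <- eligible_observed(cohort, spec)
  if (is.null(el) || nrow(el) < spec$k)
    stop(sprintf("need at least %d eligible patients, found %d",
                 spec$k, if (is.null(el)) 0 else nrow(el)), call. = FALSE)
  el$fold <- NA_integer_
  with_seed(spec$seed, {
    if (spec$stratify_by_observed) {
      offset <- 0L
      for (cat in sort(unique(el$observed))) {
        idx <- which(el$observed == cat)
        idx <- idx[sample.int(length(idx))]
        el$fold[idx] <- ((seq_along(idx) - 1L + offset) %% spec$k) + 1L
        offset <- offset + length(idx)
      }
    } else {
      el$fold <- ((sample.int(nrow(el)) - 1L) %% spec$k) + 1L
    }
  })
  el
}

# Remove all in-window observations of the given patients.
remove_window_obs <- function(cohort, patient_ids, spec) {
  lo <- spec$target_day - spec$window_halfwidth
  hi <- spec$target_day + spec$window_halfwidth
  drop <- cohort$obs$patient_id %in% patient_ids &
    cohort$obs$time_days >= lo & cohort$obs$time_days <= hi
  obs <- cohort$obs[!drop, , drop = FALSE]
  structure(list(obs = obs, covariates = cohort$covariates, meta = cohort$meta),
            class = "gose_cohort")
}

# Named list of per-patient observation tables (possibly 0-row) for ids.
records_for <- function(cohort, ids) {
  sp <- split(cohort$obs, factor(cohort$obs$patient_id, levels = ids))
  lapply(sp, function(d) d[order(d$time_days), c("time_days", "gose"), drop = FALSE])
}

#' Run the cross-validated method comparison
#'
#' For each fold: delete the fold patients' in-window observations, fit every
#' requested method on the remaining data, and predict each test patient's
#' category distribution at the target day from their window-removed record.
#' A method failing on a fold is marked failed with a warning; other methods
#' are unaffected.
#'
#' @param cohort a `gose_cohort`.
#' @param methods character vector of method names, see [gose_methods()].
#' @param spec a `cv_spec`.
#' @param method_args named list of per-method argument lists.
#' @return Data frame of evaluation pairs: one row per patient x method with
#'   the predictive distribution, point imputation, observed value, fold, and
#'   the per-patient LOCF-applicability flag.
#' @export
run_cv <- function(cohort, methods = c("locf", "mice", "msm", "clmm", "gp"),
                   spec = cv_spec(), method_args = list()) {
  registry <- gose_methods()
  unknown <- setdiff(methods, names(registry))
  if (length(unknown))
    stop(sprintf("unknown method name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  folds <- make_folds(cohort, spec)
  out <- list()
  for (f in seq_len(spec$k)) {
    test_ids <- folds$patient_id[folds$fold == f]
    train <- remove_window_obs(cohort, test_ids, spec)
    records <- records_for(train, test_ids)
    la <- vapply(records, function(d)
      any(d$time_days < spec$target_day & d$gose != 1), logical(1))
    for (m in methods) {
      pred <- tryCatch(
        do.call(registry[[m]],
                c(list(train = train, records = records,
                       covariates = cohort$covariates,
                       target_day = spec$target_day,
                       seed = spec$seed * 1000 + f),
                  method_args[[m]] %||% list())),
        error = function(e) {
          warning(sprintf("method %s failed on fold %d: %s", m, f,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(pred)) next
      pred <- pred[match(test_ids, pred$patient_id), , drop = FALSE]
      pred$fold <- f
      pred$observed <- folds$observed[folds$fold == f]
      pred$locf_applicable <- unname(la[test_ids])
      out[[length(out) + 1L]] <- pred
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gose_eval_pairs", "data.frame")
  res
}

filter_population <- function(pairs, population = c("locf_subset", "full")) {
  population <- match.arg(population)
  if (population == "locf_subset") pairs <- pairs[pairs$locf_applicable, , drop = FALSE]
  pairs[pairs$applicable & !is.na(pairs$point), , drop = FALSE]
}

# Per-pair directional bias: P(imputed > observed) - P(imputed < observed)
# under the pair's predictive distribution.
pair_dbias <- function(pairs) {
  P <- as.matrix(pairs[PROB_COLS])
  y <- match(pairs$observed, GOSE_LEVELS)
  vapply(seq_len(nrow(pairs)), function(i) {
    p <- P[i, ]
    sum(p[seq_len(N_STATES) > y[i]]) - sum(p[seq_len(N_STATES) < y[i]])
  }, numeric(1))
}

#' Compute the evaluation metrics
#'
#' Bias (imputed minus observed; negative means imputing lower than
#' observed), directional bias, MAE, and RMSE, overall and conditional on the
#' observed category, computed within each fold and averaged, with the
#' standard error taken over folds. The `locf_subset` population keeps only
#' pairs for which LOCF is applicable — for all methods alike.
#'
#' @param pairs output of [run_cv()].
#' @param population `"locf_subset"` (default) or `"full"`.
#' @return Tidy data frame: `method`, `population`, `category` (`"overall"`
#'   or a GOSe category), `metric`, `fold_mean`, `se`, `n`.
#' @export
compute_metrics <- function(pairs, population = c("locf_subset", "full")) {
  population <- match.arg(population)
  fp <- filter_population(pairs, population)
  if (nrow(fp) == 0) {
    out <- data.frame(method = character(), population = character(),
                      category = character(), metric = character(),
                      fold_mean = numeric(), se = numeric(), n = integer())
    attr(out, "empty") <- TRUE
    return(out)
  }
  fp$err <- fp$point - fp$observed
  fp$db <- pair_dbias(fp)
  k <- length(unique(pairs$fold))
  rows <- list()
  for (m in unique(fp$method)) {
    dm <- fp[fp$method == m, ]
    cats <- c("overall", sort(unique(dm$observed)))
    for (cat in cats) {
      dc <- if (cat == "overall") dm else dm[dm$observed == cat, ]
      per_fold <- lapply(split(dc, dc$fold), function(d)
        c(bias = mean(d$err), d_bias = mean(d$db),
          mae = mean(abs(d$err)), rmse = sqrt(mean(d$err^2))))
      M <- do.call(rbind, per_fold)
      for (metric in colnames(M)) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, population = population, category = as.character(cat),
          metric = metric, fold_mean = mean(M[, metric]),
          se = if (nrow(M) > 1) sd(M[, metric]) / sqrt(nrow(M)) else NA_real_,
          n = nrow(dc))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Directional bias of evaluation pairs
#'
#' Mean over pairs (within fold, then across folds) of the model-fitted
#' probability of exceeding the observed value minus the probability of
#' undershooting it. Ranges over `[-1, 1]`; for a point mass at the observed
#' value it is 0.
#'
#' @param pairs evaluation pairs (one method).
#' @return Scalar fold-averaged directional bias.
#' @export
d_bias <- function(pairs) {
  pairs <- pairs[pairs$applicable & !is.na(pairs$point), , drop = FALSE]
  db <- pair_dbias(pairs)
  mean(vapply(split(db, pairs$fold), mean, numeric(1)))
}

#' Fold-averaged confusion matrices
#'
#' Counts with rows = imputed and columns = observed category, averaged
#' entrywise over folds, plus the column-normalized variant (conditional on
#' the observed category). Zero-count columns are all-zero and flagged.
#'
#' @param pairs evaluation pairs for a single method (filter first).
#' @param population `"locf_subset"` or `"full"`.
#' @return List of class `gose_confusion`: `counts`, `normalized`,
#'   `empty_columns`.
#' @export
confusion_matrices <- function(pairs, population = c("locf_subset", "full")) {
  fp <- filter_population(pairs, population)
  stopifnot(length(unique(fp$method)) <= 1)
  folds <- sort(unique(pairs$fold))
  acc <- matrix(0, N_STATES, N_STATES,
                dimnames = list(imputed = GOSE_LEVELS, observed = GOSE_LEVELS))
  for (f in folds) {
    d <- fp[fp$fold == f, ]
    acc <- acc + table(factor(d$point, levels = GOSE_LEVELS),
                       factor(d$observed, levels = GOSE_LEVELS))
  }
  counts <- acc / length(folds)
  tot <- colSums(counts)
  normalized <- sweep(counts, 2, ifelse(tot > 0, tot, 1), "/")
  structure(list(counts = counts, normalized = normalized,
                 empty_columns = GOSE_LEVELS[tot == 0]),
            class = "gose_confusion")
}

#' Pearson chi-squared p-value without continuity correction
#' @param tab a contingency table (matrix).
#' @return p-value; `NA` if the test is undefined.
#' @export
chisq_p <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

#' Baseline subgroup comparison table
#'
#' Compares baseline covariates between patients for whom LOCF is applicable
#' (at least one observation before the target day) and those for whom it is
#' not. Binary and categorical covariates use the Pearson chi-squared test
#' without continuity correction; continuous covariates use the two-sided
#' Wilcoxon rank-sum test with normal approximation. Covariates with a single
#' observed level are skipped with a reason.
#'
#' @param cohort a `gose_cohort` with covariates.
#' @param target_day target day for the LOCF grouping (default 180).
#' @return Data frame: variable, type, n (non-missing), group summaries,
#'   p-value, note.
#' @export
subgroup_table <- function(cohort, target_day = DEFAULT_TARGET_DAY) {
  cv <- cohort$covariates
  if (is.null(cv)) stop("cohort has no covariates", call. = FALSE)
  grp <- locf_applicable(cohort, target_day)[cv$patient_id]
  vars <- setdiff(names(cv), "patient_id")
  rows <- lapply(vars, function(v) {
    x <- cv[[v]]
    ok <- !is.na(x)
    n <- sum(ok)
    is_cont <- v %in% CONTINUOUS_COVS ||
      (is.numeric(x) && length(unique(x[ok])) > 10)
    summ <- function(xx) {
      if (!length(xx)) return("")
      if (is_cont) sprintf("%.1f (%.1f-%.1f)", median(xx), quantile(xx, 0.25),
                           quantile(xx, 0.75))
      else paste(sprintf("%s:%d", names(table(xx)), table(xx)), collapse = " ")
    }
    if (length(unique(x[ok])) < 2)
      return(data.frame(variable = v, type = if (is_cont) "continuous" else "categorical",
                        n = n, no_locf = summ(x[ok & !grp]), locf = summ(x[ok & grp]),
                        p = NA_real_, note = "single observed level; test skipped"))
    p <- if (is_cont)
      suppressWarnings(wilcox.test(x[ok & grp], x[ok & !grp], exact = FALSE)$p.value)
    else
      chisq_p(table(factor(grp[ok]), x[ok]))
    data.frame(variable = v, type = if (is_cont) "continuous" else "categorical",
               n = n, no_locf = summ(x[ok & !grp]), locf = summ(x[ok & grp]),
               p = p, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
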