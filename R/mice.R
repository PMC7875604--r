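# Chained-equation panel imputation.
#
# Observations are first mapped to the four protocol windows (2 weeks,
# 3 months, 6 months, 12 months) by rounding to the nearest nominal day, so
# that e.g. the 6-month window contains observations up to 9 months
# post-injury. The resulting wide panel is completed by iterated conditional
# resampling: each window with missing cells is regressed on the other three
# windows (entered as numeric scores, which avoids sparse-cell separation)
# via proportional-odds ordinal regression, and its missing cells are
# resampled from the fitted category probabilities. The 6-month column of the
# completed data sets is reduced to a prediction by the most frequently
# imputed value; the draw frequencies are the probabilistic output.

WINDOW_DAYS <- c(gose_2wk = 14, gose_3mo = 91, gose_6mo = 180, gose_12mo = 365)
WINDOW_BREAKS <- c(52.5, 135.5, 272.5)   # midpoints between nominal days

#' Map a cohort's observations to the four protocol windows
#'
#' Each observation is assigned to the nearest nominal day among 14, 91, 180,
#' 365 (boundaries at the midpoints 52.5, 135.5, 272.5; everything up to the
#' 547-day horizon falls in the 12-month window). When several observations
#' land in one window, the one closest to the nominal day wins (ties go to
#' the earlier observation). Category-1 observations (deaths after the target
#' day) are excluded: the windows model the living scale.
#'
#' @param cohort a `gose_cohort`.
#' @return Data frame with `patient_id` and the four window columns
#'   (`NA` = missing); patients with no living-scale observation are omitted.
#' @export
map_to_windows <- function(cohort) {
  obs <- cohort$obs[cohort$obs$gose != 1, , drop = FALSE]
  win <- findInterval(obs$time_days, WINDOW_BREAKS) + 1L
  nominal <- WINDOW_DAYS[win]
  dist <- abs(obs$time_days - nominal)
  # closest to nominal wins; ties resolved to the earlier observation
  ord <- order(obs$patient_id, win, dist, obs$time_days)
  obs <- obs[ord, ]
  win <- win[ord]
  keep <- !duplicated(data.frame(obs$patient_id, win))
  obs <- obs[keep, ]
  win <- win[keep]
  ids <- unique(cohort$obs$patient_id[cohort$obs$gose != 1])
  out <- data.frame(patient_id = ids)
  for (w in seq_along(WINDOW_DAYS)) {
    col <- rep(NA_integer_, length(ids))
    sel <- win == w
    col[match(obs$patient_id[sel], ids)] <- obs$gose[sel]
    out[[names(WINDOW_DAYS)[w]]] <- col
  }
  out
}

# One proportional-odds conditional model: window `target` on the other
# windows as numeric scores (+ covariates); returns category probabilities
# for the rows in `rows`, or NULL on separation/non-convergence. A warm
# start from the previous sweep's fit (same window, evolving completed data)
# cuts the optimizer cost substantially without changing the MLE.
polr_probs <- function(complete, target, rows, Xc = NULL, start = NULL) {
  y <- factor(complete[[target]], levels = GOSE_LEVELS)
  others <- setdiff(names(WINDOW_DAYS), target)
  X <- as.matrix(complete[others])
  if (!is.null(Xc)) X <- cbind(X, Xc)
  yd <- droplevels(y)
  npar <- ncol(X) + nlevels(yd) - 1
  # without continuous covariates the design has few distinct rows: collapse
  # to unique (predictors, response) combinations with frequency weights —
  # the identical likelihood at a fraction of the cost
  if (is.null(Xc)) {
    key <- paste(X[, 1], X[, 2], X[, 3], as.integer(yd))
    first <- !duplicated(key)
    w <- as.vector(table(factor(key, levels = key[first])))
    Xf <- X[first, , drop = FALSE]
    yf <- yd[first]
  } else {
    Xf <- X; yf <- yd; w <- rep(1, nrow(X))
  }
  fit_try <- function(st) tryCatch(
    suppressWarnings(MASS::polr(yf ~ Xf, weights = w, Hess = FALSE,
                                start = st)),
    error = function(e) NULL)
  fit <- NULL
  if (!is.null(start) && length(start) == npar) fit <- fit_try(st = start)
  if (is.null(fit))
    fit <- tryCatch(suppressWarnings(MASS::polr(yf ~ Xf, weights = w, Hess = FALSE)),
                    error = function(e) NULL)
  if (is.null(fit)) {
    # near-deterministic data defeats polr's automatic starting values;
    # retry from zero slopes and marginal thresholds
    cum <- cumsum(prop.table(table(yd)))
    zeta0 <- stats::qlogis(pmin(pmax(cum[-length(cum)], 1e-3), 1 - 1e-3))
    fit <- fit_try(st = c(rep(0, ncol(X)), zeta0))
  }
  if (is.null(fit)) return(NULL)
  pr <- tryCatch(predict(fit, newdata = data.frame(Xf = I(X[rows, , drop = FALSE])),
                         type = "probs"),
                 error = function(e) NULL)
  if (is.null(pr)) return(NULL)
  pr <- matrix(pr, nrow = length(rows))
  full <- matrix(0, length(rows), N_STATES,
                 dimnames = list(NULL, as.character(GOSE_LEVELS)))
  full[, levels(yd)] <- pr
  attr(full, "start") <- c(coef(fit), fit$zeta)
  full
}

#' Chained-equation imputation of the wide panel
#'
#' Runs `M` independent chains. Each chain initializes missing cells by
#' sampling from the window's observed marginal, then performs `n_iter`
#' sweeps; in each sweep every window with missing cells is re-fitted and its
#' missing cells resampled from the fitted proportional-odds probabilities.
#' If a conditional model fails (separation, non-convergence) that sweep
#' falls back to the window's observed marginal, and the event is counted.
#' Observed cells are never altered.
#'
#' @param panel wide panel from [map_to_windows()].
#' @param M number of chains / completed data sets (default 50).
#' @param n_iter sweeps per chain (default 10).
#' @param seed integer seed.
#' @param use_covariates include covariates in the conditional models.
#' @param covariates per-patient covariate table (required if
#'   `use_covariates`).
#' @return List of class `imputation_draws`: `draws` (patients x M matrix of
#'   imputed 6-month values), `panel`, `n_fallback` (count of marginal
#'   fallbacks).
#' @export
chained_impute <- function(panel, M = 50, n_iter = 10, seed = 1,
                           use_covariates = FALSE, covariates = NULL) {
  stopifnot(nrow(panel) > 0, M >= 1)
  wins <- names(WINDOW_DAYS)
  marg <- lapply(wins, function(w) {
    v <- panel[[w]]
    v <- v[!is.na(v)]
    if (!length(v))
      stop(sprintf("window %s has no observed values; its conditional model is degenerate", w),
           call. = FALSE)
    v
  })
  names(marg) <- wins
  Xc <- NULL
  if (use_covariates) {
    cm <- cov_matrix(covariates, panel$patient_id)
    Xc <- cm$X
  }
  n_fallback <- 0L
  draws <- matrix(NA_integer_, nrow(panel), M,
                  dimnames = list(panel$patient_id, NULL))
  warm <- list()
  run <- function() {
    for (m in seq_len(M)) {
      complete <- panel
      for (w in wins) {
        miss <- is.na(complete[[w]])
        if (any(miss))
          complete[[w]][miss] <- sample(marg[[w]], sum(miss), replace = TRUE)
      }
      for (it in seq_len(n_iter)) {
        for (w in wins) {
          miss <- which(is.na(panel[[w]]))
          if (!length(miss)) next
          pr <- polr_probs(complete, w, miss, Xc, start = warm[[w]])
          if (!is.null(pr)) warm[[w]] <<- attr(pr, "start")
          if (is.null(pr)) {
            n_fallback <<- n_fallback + 1L
            complete[[w]][miss] <- sample(marg[[w]], length(miss), replace = TRUE)
          } else {
            complete[[w]][miss] <- vapply(seq_along(miss), function(i)
              GOSE_LEVELS[sample.int(N_STATES, 1, prob = pr[i, ])], integer(1))
          }
        }
      }
      draws[, m] <<- complete$gose_6mo
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(draws = draws, panel = panel, n_fallback = n_fallback),
            class = "imputation_draws")
}

#' Reduce imputation draws to predictive distributions
#'
#' The probability of each category is its relative frequency among the `M`
#' draws (exact rational arithmetic of counts over M); the point imputation
#' is the most frequent value, ties broken toward the lower category.
#'
#' @param draws an `imputation_draws` object, or a patients x M matrix.
#' @param method_label method name recorded in the output.
#' @return A prediction frame with one row per patient.
#' @export
reduce_to_prediction <- function(draws, method_label = "mice") {
  m <- if (inherits(draws, "imputation_draws")) draws$draws else draws
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cnt <- tabulate(match(m[i, ], GOSE_LEVELS), N_STATES)
    new_prediction(rownames(m)[i], method_label, cnt / ncol(m))
  })
  prediction_frame(rows)
}

#' Impute the 6-month GOSe by chained-equation panel imputation
#'
#' Convenience wrapper: maps the cohort to windows, runs [chained_impute()],
#' and reduces to predictions. Patients absent from the panel (no living-scale
#' observation) are returned as not applicable.
#'
#' @inheritParams chained_impute
#' @param cohort a `gose_cohort`.
#' @param target_day must be 180 (the window scheme is fixed).
#' @return A prediction frame for all cohort patients.
#' @export
impute_mice <- function(cohort, target_day = DEFAULT_TARGET_DAY, M = 50,
                        n_iter = 10, seed = 1, use_covariates = FALSE) {
  if (target_day != 180)
    stop("the chained-equation panel method is defined for target day 180", call. = FALSE)
  panel <- map_to_windows(cohort)
  dr <- chained_impute(panel, M = M, n_iter = n_iter, seed = seed,
                       use_covariates = use_covariates,
                       covariates = cohort$covariates)
  label <- if (use_covariates) "mice_cov" else "mice"
  pred <- reduce_to_prediction(dr, label)
  missing_ids <- setdiff(cohort_ids(cohort), pred$patient_id)
  if (length(missing_ids)) {
    extra <- prediction_frame(lapply(missing_ids, function(pid)
      new_prediction(pid, label, applicable = FALSE)))
    pred <- prediction_frame(list(pred, extra))
  }
  pred
}
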