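# Registry of imputation methods with a uniform interface:
# function(train, records, covariates, target_day, seed, ...) -> prediction
# frame covering every requested record. `train` is the training cohort,
# `records` a named list of per-patient observation tables describing the
# information state at prediction time.

#' Available imputation methods
#'
#' Returns the method registry. Methods: `locf`; `mice` / `mice_cov`
#' (chained-equation panel imputation without / with IMPACT covariates);
#' `msm` / `msm_cov` (multi-state model without covariates / with age);
#' `clmm` / `clmm_cov` (cumulative-link mixed model); `gp` / `gp_nocov`
#' (Gaussian-process regression, covariates on by default — the variant
#' carried forward in the comparison).
#'
#' @return Named list of method functions.
#' @export
gose_methods <- function() {
  locf_like <- function(records, target_day) {
    rows <- lapply(names(records), function(pid) {
      d <- records[[pid]]
      pre <- d[d$time_days < target_day & d$gose != 1, , drop = FALSE]
      if (nrow(pre) == 0) new_prediction(pid, "locf", applicable = FALSE)
      else new_prediction(pid, "locf", point_mass(pre$gose[nrow(pre)]))
    })
    prediction_frame(rows)
  }
  mice_like <- function(train, records, target_day, seed, use_covariates,
                        M = 50, n_iter = 10) {
    pred <- impute_mice(train, target_day, M = M, n_iter = n_iter, seed = seed,
                        use_covariates = use_covariates)
    label <- pred$method[1]
    got <- match(names(records), pred$patient_id)
    rows <- lapply(seq_along(records), function(i) {
      if (is.na(got[i])) new_prediction(names(records)[i], label, applicable = FALSE)
      else pred[got[i], ]
    })
    prediction_frame(rows)
  }
  list(
    locf = function(train, records, covariates, target_day, seed, ...)
      locf_like(records, target_day),
    mice = function(train, records, covariates, target_day, seed, ...)
      mice_like(train, records, target_day, seed, FALSE, ...),
    mice_cov = function(train, records, covariates, target_day, seed, ...)
      mice_like(train, records, target_day, seed, TRUE, ...),
    msm = function(train, records, covariates, target_day, seed, ...)
      predict(fit_msm(train, covariates = NULL, ...), records, covariates, target_day),
    msm_cov = function(train, records, covariates, target_day, seed, ...)
      predict(fit_msm(train, covariates = "age", ...), records, covariates, target_day),
    clmm = function(train, records, covariates, target_day, seed, ...)
      predict(fit_clmm(train, use_covariates = FALSE, ...), records, covariates, target_day),
    clmm_cov = function(train, records, covariates, target_day, seed, ...)
      predict(fit_clmm(train, use_covariates = TRUE, ...), records, covariates, target_day),
    gp = function(train, records, covariates, target_day, seed, ...)
      predict(fit_gp(train, use_covariates = TRUE, seed = seed, ...),
              records, covariates, target_day),
    gp_nocov = function(train, records, covariates, target_day, seed, ...)
      predict(fit_gp(train, use_covariates = FALSE, seed = seed, ...),
              records, covariates, target_day)
  )
}

#' Impute a cohort at the target day with one method
#'
#' Fits the method on the whole cohort and predicts every patient's category
#' distribution at the target day (the production use: filling the database).
#'
#' @param cohort a `gose_cohort`.
#' @param method a method name from [gose_methods()].
#' @param target_day target day (default 180).
#' @param seed integer seed for stochastic methods.
#' @param ... passed to the method (e.g. `M`, `spline_df`).
#' @return A prediction frame.
#' @export
impute_cohort <- function(cohort, method = "msm",
                          target_day = DEFAULT_TARGET_DAY, seed = 1, ...) {
  registry <- gose_methods()
  if (!method %in% names(registry))
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  records <- records_for(cohort, cohort_ids(cohort))
  registry[[method]](train = cohort, records = records,
                     covariates = cohort$covariates,
                     target_day = target_day, seed = seed, ...)
}
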