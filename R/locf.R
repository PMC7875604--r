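# Last observation carried forward: the comparator method. The imputed value
# is the category of the latest observation strictly before the target day;
# its "predictive distribution" is the corresponding point mass so that the
# metric suite applies uniformly. Patients with no pre-target observation are
# flagged not applicable rather than imputed.

#' Impute by last observation carried forward
#'
#' @param cohort a `gose_cohort` (ingested: category 2 merged, times sorted).
#' @param target_day imputation target in days post-injury (default 180);
#'   "before" is strict, so an observation exactly at the target day is an
#'   outcome, not a carry-forward source.
#' @return A prediction frame with one row per patient; rows for patients
#'   without a pre-target observation have `applicable = FALSE`.
#' @examples
#' obs <- data.frame(patient_id = "a", time_days = c(14, 95), gose = c(5, 6))
#' impute_locf(gose_cohort(obs))
#' @export
impute_locf <- function(cohort, target_day = DEFAULT_TARGET_DAY) {
  rows <- lapply(split_obs(cohort), function(d) {
    pre <- d[d$time_days < target_day & d$gose != 1, , drop = FALSE]
    if (nrow(pre) == 0)
      new_prediction(d$patient_id[1], "locf", applicable = FALSE)
    else
      new_prediction(d$patient_id[1], "locf",
                     point_mass(pre$gose[nrow(pre)]))
  })
  prediction_frame(rows)
}

#' Is LOCF applicable for each patient?
#' @param cohort a `gose_cohort`.
#' @param target_day target day (default 180).
#' @return Named logical vector over patients.
#' @export
locf_applicable <- function(cohort, target_day = DEFAULT_TARGET_DAY) {
  vapply(split_obs(cohort),
         function(d) any(d$time_days < target_day & d$gose != 1),
         logical(1))
}
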