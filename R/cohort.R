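# Data model and file I/O for longitudinal GOSe cohorts.
#
# A cohort holds a long-format observation table (patient_id, time_days, gose)
# plus an optional per-patient covariate table. Ingest applies the study rules:
# GOSe 2 (vegetative) is merged into 3, observations later than 547 days
# (18 months) post-injury are dropped, exact-tie observations collapse to the
# worse category, and patients dead at or before the target day are excluded
# (the outcome can only be missing for survivors).

INGEST_HORIZON <- 547          # days; 18 months post-injury
DEFAULT_TARGET_DAY <- 180

CONTINUOUS_COVS <- c("age", "glucose", "hemoglobin", "iss")

#' Construct a GOSe cohort from long-format observations
#'
#' Applies the ingest rules (see Details) and returns a validated cohort
#' object. Counts of each exclusion are recorded in the ingest log.
#'
#' @param obs data frame with columns `patient_id`, `time_days`, `gose`.
#' @param covariates optional data frame with one row per patient
#'   (column `patient_id` plus covariate columns such as `age`, `stratum`).
#' @param meta optional list of provenance metadata.
#' @param target_day day used for the survival condition (default 180).
#' @details Ingest rules, in order: unknown categories are an error; category 2
#'   is merged into 3; observations after day 547 are dropped; times are sorted
#'   and exact ties collapsed keeping the lower (worse) category; patients with
#'   a category-1 (dead) observation at or before `target_day` are excluded;
#'   patients left without observations are excluded.
#' @return An object of class `gose_cohort`.
#' @export
gose_cohort <- function(obs, covariates = NULL, meta = list(),
                        target_day = DEFAULT_TARGET_DAY) {
  stopifnot(is.data.frame(obs))
  need <- c("patient_id", "time_days", "gose")
  if (!all(need %in% names(obs)))
    stop("observations need columns patient_id, time_days, gose", call. = FALSE)
  obs <- obs[need]
  obs$patient_id <- as.character(obs$patient_id)
  if (!is.numeric(obs$time_days))
    stop("malformed numeric values in time_days", call. = FALSE)
  if (!is.numeric(obs$gose) || (nrow(obs) && any(obs$gose != round(obs$gose), na.rm = TRUE)))
    stop("malformed numeric values in gose", call. = FALSE)
  if (nrow(obs) && (any(is.na(obs$gose)) || any(!obs$gose %in% 1:8)))
    stop("unknown GOSe category value (must be an integer in 1..8)", call. = FALSE)
  if (nrow(obs) && any(!is.finite(obs$time_days) | obs$time_days <= 0))
    stop("time_days must be positive and finite", call. = FALSE)

  log <- c(merged_2_to_3 = 0L, dropped_late = 0L, collapsed_ties = 0L,
           dropped_dead = 0L, dropped_empty = 0L)

  if (nrow(obs)) {
    log[["merged_2_to_3"]] <- sum(obs$gose == 2)
    obs$gose[obs$gose == 2] <- 3L
    late <- obs$time_days > INGEST_HORIZON
    log[["dropped_late"]] <- sum(late)
    obs <- obs[!late, , drop = FALSE]
    obs <- obs[order(obs$patient_id, obs$time_days, obs$gose), , drop = FALSE]
    dup <- duplicated(obs[c("patient_id", "time_days")])
    log[["collapsed_ties"]] <- sum(dup)
    obs <- obs[!dup, , drop = FALSE]   # keeps the lower (worse) category
    dead <- unique(obs$patient_id[obs$gose == 1 & obs$time_days <= target_day])
    if (length(dead)) {
      log[["dropped_dead"]] <- length(dead)
      warning(sprintf("%d patient(s) dead at or before day %g excluded",
                      length(dead), target_day), call. = FALSE)
      obs <- obs[!obs$patient_id %in% dead, , drop = FALSE]
    }
  }
  obs$gose <- as.integer(obs$gose)
  rownames(obs) <- NULL

  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), "patient_id" %in% names(covariates))
    covariates$patient_id <- as.character(covariates$patient_id)
    if (anyDuplicated(covariates$patient_id))
      stop("covariate table has duplicated patient ids", call. = FALSE)
    n_before <- length(unique(covariates$patient_id))
    covariates <- covariates[covariates$patient_id %in% obs$patient_id, , drop = FALSE]
    log[["dropped_empty"]] <- n_before - nrow(covariates)
    rownames(covariates) <- NULL
  }

  structure(list(obs = obs, covariates = covariates,
                 meta = c(meta, list(ingest_log = log))),
            class = "gose_cohort")
}

#' @export
print.gose_cohort <- function(x, ...) {
  ids <- unique(x$obs$patient_id)
  cat(sprintf("GOSe cohort: %d patients, %d observations\n",
              length(ids), nrow(x$obs)))
  if (nrow(x$obs)) {
    tab <- table(factor(x$obs$gose, levels = c(1, GOSE_LEVELS)))
    cat("category counts:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
  lg <- x$meta$ingest_log
  if (!is.null(lg) && any(lg > 0))
    cat("ingest:", paste(sprintf("%s=%d", names(lg)[lg > 0], lg[lg > 0]), collapse = " "), "\n")
  invisible(x)
}

#' Patient ids of a cohort
#' @param cohort a `gose_cohort`.
#' @return character vector of unique patient ids (observation order).
#' @export
cohort_ids <- function(cohort) unique(cohort$obs$patient_id)

# Per-patient observation tables as a named list, in cohort order.
split_obs <- function(cohort) {
  split(cohort$obs, factor(cohort$obs$patient_id, levels = cohort_ids(cohort)))
}

#' Read a cohort from a long-format CSV file
#'
#' Expects columns `patient_id`, `time_days`, `gose`; any further columns are
#' treated as per-patient covariates and must be constant within a patient.
#' Applies the ingest rules of [gose_cohort()]. An empty file yields an empty
#' cohort.
#'
#' @param path CSV file path.
#' @param target_day target day for the survival condition (default 180).
#' @return A `gose_cohort`.
#' @export
read_cohort <- function(path, target_day = DEFAULT_TARGET_DAY) {
  if (file.info(path)$size == 0)
    return(gose_cohort(data.frame(patient_id = character(), time_days = numeric(),
                                  gose = integer()),
                       meta = list(source = path), target_day = target_day))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    return(gose_cohort(raw[c("patient_id", "time_days", "gose")],
                       meta = list(source = path), target_day = target_day))
  for (col in c("time_days", "gose"))
    if (!is.numeric(raw[[col]]))
      stop(sprintf("malformed numeric values in column '%s'", col), call. = FALSE)
  cov_cols <- setdiff(names(raw), c("patient_id", "time_days", "gose"))
  covariates <- NULL
  if (length(cov_cols)) {
    for (col in cov_cols) {
      nu <- tapply(raw[[col]], raw$patient_id,
                   function(v) length(unique(v[!is.na(v)])))
      if (any(nu > 1, na.rm = TRUE))
        stop(sprintf("covariate column '%s' is not constant within patient '%s'",
                     col, names(nu)[which(nu > 1)[1]]), call. = FALSE)
    }
    covariates <- raw[!duplicated(raw$patient_id), c("patient_id", cov_cols),
                      drop = FALSE]
  }
  gose_cohort(raw[c("patient_id", "time_days", "gose")], covariates,
              meta = list(source = path), target_day = target_day)
}

#' Write a cohort to a long-format CSV file
#'
#' Inverse of [read_cohort()]: covariates are repeated on each observation row
#' so that reading the file back reproduces the cohort exactly.
#'
#' @param cohort a `gose_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort$obs
  if (!is.null(cohort$covariates))
    out <- merge(out, cohort$covariates, by = "patient_id", sort = FALSE)
  out <- out[order(out$patient_id, out$time_days), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
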