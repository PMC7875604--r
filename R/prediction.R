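# Predictive-distribution container shared by all imputation methods: one row
# per patient with six probability columns (gose3..gose8), the point
# imputation (modal category, ties toward the lower category), a method label,
# and an applicability flag (LOCF cannot impute without a pre-target
# observation). Storing the full distribution lets multiple imputations be
# drawn post hoc from the saved file alone.

PROB_COLS <- paste0("gose", GOSE_LEVELS)

new_prediction <- function(patient_id, method, probs = NULL, applicable = TRUE) {
  if (!applicable || is.null(probs)) {
    p <- rep(NA_real_, N_STATES)
    point <- NA_integer_
  } else {
    if (any(probs < -1e-12)) stop("negative probability in predictive distribution")
    probs <- pmax(probs, 0)
    s <- sum(probs)
    if (abs(s - 1) > 1e-9) {
      if (s <= 0) stop("degenerate predictive distribution (all-zero)")
      probs <- probs / s
    }
    p <- probs
    point <- modal_category(probs)
  }
  row <- data.frame(patient_id = patient_id, method = method,
                    t(p), point = point, applicable = applicable)
  names(row)[3:(2 + N_STATES)] <- PROB_COLS
  row
}

prediction_frame <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gose_prediction", "data.frame")
  out
}

point_mass <- function(category) {
  p <- numeric(N_STATES)
  p[match(category, GOSE_LEVELS)] <- 1
  p
}

#' Draw multiple imputations from a predictive distribution
#'
#' Inverse-transform sampling on the cumulative probabilities over the ordered
#' categories, so stored predictive distributions suffice to generate multiple
#' imputed data sets post hoc.
#'
#' @param probs probability vector over GOSe 3..8, or one row of a prediction
#'   frame.
#' @param M number of draws.
#' @param seed integer seed.
#' @return Integer vector of `M` GOSe categories.
#' @export
draw_multiple_imputations <- function(probs, M, seed = NULL) {
  if (is.data.frame(probs)) probs <- as.numeric(probs[1, PROB_COLS])
  stopifnot(length(probs) == N_STATES)
  assert_prob_vector(probs, "predictive distribution", tol = 1e-9)
  run <- function() {
    u <- runif(M)
    GOSE_LEVELS[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
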