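# Panel-likelihood continuous-time Markov multi-state model.
#
# GOSe trajectories are observed only at scattered visit times (panel data),
# so the likelihood of a patient is the product over consecutive observation
# pairs of the transition probability P(dt)[s_i, s_{i+1}] = expm(Q dt), with
# the first observation conditioned on. The default transition structure is
# adjacent-state (birth-death): 1-4 observations per patient cannot identify
# a dense intensity matrix. Covariates (by default age only) act
# proportionally on the intensities, q_rs(x) = q_rs0 * exp(beta_rs * z) with
# z = (age - 45) / 10.

AGE_CENTER <- 45
AGE_SCALE <- 10
LOGQ_FLOOR <- -12   # exp(-12) / day ~ one transition per 450 years: effectively 0

#' Default adjacent-state transition structure
#' @param n number of states (default 6).
#' @return data frame with columns `from`, `to` (state indices 1..n).
#' @export
msm_structure <- function(n = N_STATES) {
  data.frame(from = c(1:(n - 1), 2:n), to = c(2:n, 1:(n - 1)))
}

# Build the generator from parameters for one covariate value z.
msm_build_Q <- function(structure, logq, beta, z = 0, n = N_STATES) {
  Q <- matrix(0, n, n)
  Q[cbind(structure$from, structure$to)] <- exp(logq + beta * z)
  diag(Q) <- -rowSums(Q)
  Q
}

# Consecutive observation pairs of a cohort on the living scale (category-1
# observations, i.e. deaths after the target day, are outside the 6-state
# model and excluded from fitting). Returns 0-based states for the C++ core.
msm_pairs <- function(cohort) {
  ages <- msm_age_z(cohort)
  out <- lapply(split_obs(cohort), function(d) {
    d <- d[d$gose != 1, , drop = FALSE]
    m <- nrow(d)
    if (m < 2) return(NULL)
    data.frame(patient_id = d$patient_id[1],
               from = match(d$gose[-m], GOSE_LEVELS) - 1L,
               to = match(d$gose[-1], GOSE_LEVELS) - 1L,
               t1 = d$time_days[-m],
               dt = diff(d$time_days),
               z = ages[[d$patient_id[1]]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Centered/scaled age per patient; missing age maps to the reference (z = 0).
msm_age_z <- function(cohort) {
  ids <- cohort_ids(cohort)
  z <- setNames(rep(0, length(ids)), ids)
  cv <- cohort$covariates
  if (!is.null(cv) && "age" %in% names(cv)) {
    zz <- (cv$age - AGE_CENTER) / AGE_SCALE
    zz[is.na(zz)] <- 0
    z[cv$patient_id] <- zz
  }
  as.list(z)
}

#' Panel log-likelihood of a generator matrix on a cohort
#'
#' Sum over patients of the log transition probabilities between consecutive
#' observations; single-observation patients contribute zero (their first
#' observation is conditioned on). If some observed transition has model
#' probability zero the result is `-Inf` and the attribute `bad_pair` names
#' the offending patient and pair.
#'
#' @param cohort a `gose_cohort`.
#' @param Q generator matrix on the 6 living states (GOSe 3..8).
#' @param beta optional per-transition log-linear age loadings, in the order
#'   of the non-zero off-diagonal entries of `Q` (row-wise); default zero.
#' @return Log-likelihood (scalar).
#' @export
panel_loglik <- function(cohort, Q, beta = NULL) {
  validate_generator(Q)
  off <- Q; diag(off) <- 0
  idx <- which(t(off) > 0, arr.ind = TRUE)   # row-wise order
  structure_df <- data.frame(from = idx[, 2], to = idx[, 1])
  logq <- log(off[cbind(structure_df$from, structure_df$to)])
  if (is.null(beta)) beta <- numeric(length(logq))
  stopifnot(length(beta) == length(logq))
  pr <- msm_pairs(cohort)
  if (is.null(pr) || nrow(pr) == 0) return(0)
  # transitions absent from the structure: map through full logq vector on a
  # dense parametrization so that impossible observed moves yield -Inf
  res <- cpp_panel_loglik(nrow(Q),
                          as.integer(structure_df$from - 1L),
                          as.integer(structure_df$to - 1L),
                          logq, beta,
                          as.integer(pr$from), as.integer(pr$to),
                          pr$t1, pr$dt, pr$z, -1, 0)
  ll <- res$loglik
  if (!is.finite(ll) && res$bad_pair > 0)
    attr(ll, "bad_pair") <- sprintf("patient %s, pair %d",
                                    pr$patient_id[res$bad_pair], res$bad_pair)
  ll
}

#' Fit the multi-state model by maximum panel likelihood
#'
#' Maximizes the panel log-likelihood over log-intensities (and, optionally,
#' per-transition age loadings) by box-constrained quasi-Newton (L-BFGS-B)
#' from the deterministic start log-intensity = log(0.005/day), loadings = 0.
#' Log-intensities are floored at `-12` so unidentified transitions are driven
#' to an effective zero without leaving the parameter space.
#'
#' @param cohort a `gose_cohort` with at least one patient having two or more
#'   observations.
#' @param covariates character vector of covariates entering the intensities;
#'   only `"age"` is supported (the default); use `NULL` for none.
#' @param structure transition structure data frame (`from`, `to`); default
#'   adjacent states.
#' @param knot optional day at which all intensities change by a common
#'   factor (two-epoch piecewise-homogeneous variant); `NULL` (the default)
#'   fits a time-homogeneous chain.
#' @param control list passed to [stats::optim()] control (e.g. `maxit`).
#' @return An object of class `msm_fit`: log-intensities, loadings, the
#'   initial-state distribution (empirical first observed categories) with its
#'   reference day, and a fit report (log-likelihood, convergence flag,
#'   iteration count, gradient norm).
#' @export
fit_msm <- function(cohort, covariates = "age", structure = msm_structure(),
                    knot = NULL, control = list()) {
  if (!is.null(covariates) && length(covariates) && !identical(covariates, "age"))
    stop("only 'age' is supported as an intensity covariate", call. = FALSE)
  use_cov <- identical(covariates, "age")
  pr <- msm_pairs(cohort)
  if (is.null(pr) || nrow(pr) == 0)
    stop("need at least one patient with two or more observations", call. = FALSE)
  nt <- nrow(structure)
  from0 <- as.integer(structure$from - 1L)
  to0 <- as.integer(structure$to - 1L)
  # exits observed from a state the structure declares absorbing are a data error
  absorbing <- setdiff(seq_len(N_STATES), unique(structure$from))
  if (length(absorbing) && any((pr$from + 1L) %in% absorbing & pr$to != pr$from))
    stop("observed exit from a state that the structure declares absorbing",
         call. = FALSE)
  use_knot <- !is.null(knot)
  knot_val <- if (use_knot) knot else -1
  npar <- nt * (1 + use_cov) + use_knot
  nll <- function(par) {
    logq <- par[1:nt]
    beta <- if (use_cov) par[nt + 1:nt] else numeric(nt)
    ls <- if (use_knot) par[npar] else 0
    res <- cpp_panel_loglik(N_STATES, from0, to0, logq, beta,
                            as.integer(pr$from), as.integer(pr$to),
                            pr$t1, pr$dt, pr$z, knot_val, ls)
    if (!is.finite(res$loglik)) return(1e10)
    -res$loglik
  }
  start <- c(rep(log(0.005), nt), if (use_cov) rep(0, nt), if (use_knot) 0)
  lower <- c(rep(LOGQ_FLOOR, nt), if (use_cov) rep(-3, nt), if (use_knot) -4)
  upper <- c(rep(2, nt), if (use_cov) rep(3, nt), if (use_knot) 2)
  ctrl <- modifyList(list(maxit = 400, factr = 1e8), control)
  opt <- optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper,
               control = ctrl)
  # gradient norm at the optimum (interior coordinates only)
  eps <- 1e-5
  g <- vapply(seq_len(npar), function(j) {
    pp <- opt$par; pm <- opt$par
    pp[j] <- pp[j] + eps; pm[j] <- pm[j] - eps
    (nll(pp) - nll(pm)) / (2 * eps)
  }, numeric(1))
  interior <- opt$par > lower + 1e-6 & opt$par < upper - 1e-6
  gnorm <- sqrt(sum(g[interior]^2))

  firsts <- vapply(split_obs(cohort), function(d) {
    d <- d[d$gose != 1, , drop = FALSE]
    if (nrow(d)) d$gose[1] else NA_integer_
  }, numeric(1))
  first_t <- vapply(split_obs(cohort), function(d) {
    d <- d[d$gose != 1, , drop = FALSE]
    if (nrow(d)) d$time_days[1] else NA_real_
  }, numeric(1))
  pi0 <- tabulate(match(firsts, GOSE_LEVELS), N_STATES)
  pi0 <- pi0 / sum(pi0)

  structure(list(structure = structure,
                 logq = opt$par[1:nt],
                 beta = if (use_cov) opt$par[nt + 1:nt] else rep(0, nt),
                 use_cov = use_cov,
                 knot = if (use_knot) knot else NULL,
                 log_post_scale = if (use_knot) opt$par[npar] else 0,
                 pi0 = pi0,
                 ref_day = mean(first_t, na.rm = TRUE),
                 report = list(loglik = -opt$value,
                               convergence = opt$convergence == 0,
                               iterations = opt$counts[["function"]],
                               grad_norm = gnorm)),
            class = "msm_fit")
}

#' Generator matrix of a fitted multi-state model
#' @param fit an `msm_fit`.
#' @param age patient age in years (`NA` = reference age 45).
#' @return 6x6 generator matrix.
#' @export
msm_Q <- function(fit, age = NA) {
  z <- if (is.na(age)) 0 else (age - AGE_CENTER) / AGE_SCALE
  msm_build_Q(fit$structure, fit$logq, fit$beta, z)
}

#' Transition probability matrix of a fitted model over an absolute interval
#'
#' Respects the two-epoch variant: if the fit has a knot, the interval is
#' split there and the post-knot epoch uses the scaled intensities.
#'
#' @param fit an `msm_fit`.
#' @param t_from,t_to interval endpoints in days (`t_from <= t_to`).
#' @param age patient age (`NA` = reference).
#' @return Stochastic matrix over the 6 living states.
#' @export
msm_P <- function(fit, t_from, t_to, age = NA) {
  Q <- msm_Q(fit, age)
  stopifnot(t_to >= t_from)
  kn <- fit$knot
  if (is.null(kn) || t_to <= kn)
    return(transition_matrix(Q, t_to - t_from))
  s <- exp(fit$log_post_scale)
  if (t_from >= kn)
    return(transition_matrix(Q, s * (t_to - t_from)))
  P <- transition_matrix(Q, kn - t_from) %*% transition_matrix(Q, s * (t_to - kn))
  P[P < 0] <- 0
  P
}

#' Conditional state-occupancy distribution at the target day
#'
#' Probability distribution of the state at `target_day` given a patient's
#' observation panel. With observations bracketing the target at times
#' `t_L < target < t_R` the Markov property gives
#' `probs[k] propto P(target - t_L)[s_L, k] * P(t_R - target)[k, s_R]`;
#' with only earlier observations the row of the transition matrix is used;
#' with only later observations the initial-state distribution (empirical
#' first observed categories, evolved from its reference day to the target)
#' is inverted through Bayes' rule. An observation exactly at the target day
#' yields a point mass.
#'
#' @param fit an `msm_fit`.
#' @param obs data frame with columns `time_days`, `gose` (may have 0 rows).
#' @param target_day target day.
#' @param age patient age (for the covariate-adjusted generator).
#' @return List with `probs` (vector over GOSe 3..8) or `NULL` when the panel
#'   is empty (not applicable).
#' @export
conditional_state_distribution <- function(fit, obs, target_day = DEFAULT_TARGET_DAY,
                                           age = NA) {
  obs <- obs[obs$gose != 1, , drop = FALSE]
  if (nrow(obs) == 0) return(NULL)
  at <- which(obs$time_days == target_day)
  if (length(at))
    return(list(probs = point_mass(obs$gose[at[1]])))
  left <- obs[obs$time_days < target_day, , drop = FALSE]
  right <- obs[obs$time_days > target_day, , drop = FALSE]
  probs <- rep(1, N_STATES)
  if (nrow(left)) {
    sL <- match(left$gose[nrow(left)], GOSE_LEVELS)
    tL <- left$time_days[nrow(left)]
    probs <- probs * msm_P(fit, tL, target_day, age)[sL, ]
  } else {
    # marginal state distribution at the target, from the first-observation
    # distribution evolved over (reference day -> target)
    pi_t <- as.numeric(fit$pi0 %*% msm_P(fit, min(fit$ref_day, target_day),
                                         target_day, age))
    probs <- probs * pi_t
  }
  if (nrow(right)) {
    sR <- match(right$gose[1], GOSE_LEVELS)
    probs <- probs * msm_P(fit, target_day, right$time_days[1], age)[, sR]
  }
  s <- sum(probs)
  if (s <= 0) return(list(probs = rep(1 / N_STATES, N_STATES)))
  list(probs = probs / s)
}

#' @export
predict.msm_fit <- function(object, records, covariates = NULL,
                            target_day = DEFAULT_TARGET_DAY,
                            method_label = if (object$use_cov) "msm_cov" else "msm",
                            ...) {
  ages <- record_ages(records, covariates)
  rows <- lapply(names(records), function(pid) {
    cs <- conditional_state_distribution(object, records[[pid]], target_day,
                                         age = if (object$use_cov) ages[[pid]] else NA)
    if (is.null(cs))
      new_prediction(pid, method_label, applicable = FALSE)
    else
      new_prediction(pid, method_label, cs$probs)
  })
  prediction_frame(rows)
}

# Age lookup for a named record list.
record_ages <- function(records, covariates) {
  ages <- setNames(rep(NA_real_, length(records)), names(records))
  if (!is.null(covariates) && "age" %in% names(covariates)) {
    m <- match(names(records), covariates$patient_id)
    ages[!is.na(m)] <- covariates$age[m[!is.na(m)]]
  }
  as.list(ages)
}

#' Serialize a fitted multi-state model to a plain-text file
#' @param fit an `msm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msm <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("goseimpute msm_fit v1",
               sprintf("use_cov %d", as.integer(fit$use_cov)),
               sprintf("ref_day %.17g", fit$ref_day),
               sprintf("knot %.17g %.17g",
                       if (is.null(fit$knot)) -1 else fit$knot,
                       fit$log_post_scale %||% 0),
               paste("pi0", paste(sprintf("%.17g", fit$pi0), collapse = " ")),
               "from to logq beta"), con)
  writeLines(sprintf("%d %d %.17g %.17g", fit$structure$from, fit$structure$to,
                     fit$logq, fit$beta), con)
  invisible(path)
}

#' Reload a multi-state model written by [write_msm()]
#' @param path file path.
#' @return An `msm_fit` (without the fit report).
#' @export
read_msm <- function(path) {
  ln <- readLines(path)
  stopifnot(ln[1] == "goseimpute msm_fit v1")
  use_cov <- as.integer(strsplit(ln[2], " ")[[1]][2]) == 1
  ref_day <- as.numeric(strsplit(ln[3], " ")[[1]][2])
  kn <- as.numeric(strsplit(ln[4], " ")[[1]][-1])
  pi0 <- as.numeric(strsplit(ln[5], " ")[[1]][-1])
  tab <- read.table(text = ln[-(1:6)], col.names = c("from", "to", "logq", "beta"))
  structure(list(structure = tab[c("from", "to")], logq = tab$logq,
                 beta = tab$beta, use_cov = use_cov,
                 knot = if (kn[1] < 0) NULL else kn[1], log_post_scale = kn[2],
                 pi0 = pi0, ref_day = ref_day, report = NULL),
            class = "msm_fit")
}
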