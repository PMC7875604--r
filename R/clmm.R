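# Cumulative-probit mixed model for the latent recovery trajectory.
#
# The observed category at time t arises by thresholding a latent Gaussian
# variable u = f(t) + x'beta + b0 + b1*s(t) + b2*s(t)^2 + eps, eps ~ N(0,1),
# where f is a natural cubic spline in time (population trend), s(t) a scaled
# time, and (b0, b1, b2) patient-level random effects with diagonal
# covariance. Parameters are estimated by marginal maximum likelihood with
# the random effects integrated out by a per-patient Laplace approximation
# (a deterministic stand-in for a fully Bayesian fit that preserves the
# probabilistic category output). The probit link makes the latent-Gaussian
# conditioning used in prediction exact given the Laplace posterior.

IMPACT_COVS <- c("age", "gcs_motor", "pupil_reactivity", "hypoxia", "hypotension",
                 "marshall_ct", "tsah", "edh", "glucose", "hemoglobin")

clmm_scale_time <- function(t) (t - 180) / 365

# Observation-level model frame on the living scale.
clmm_frame <- function(cohort) {
  obs <- cohort$obs[cohort$obs$gose != 1, , drop = FALSE]
  obs$y <- match(obs$gose, GOSE_LEVELS)
  obs[order(match(obs$patient_id, cohort_ids(cohort)), obs$time_days), ]
}

# Standardized covariate matrix; missing values sit at the training mean.
cov_matrix <- function(covariates, ids, scaling = NULL) {
  X <- matrix(0, length(ids), length(IMPACT_COVS),
              dimnames = list(ids, IMPACT_COVS))
  if (!is.null(covariates)) {
    m <- match(ids, covariates$patient_id)
    for (j in seq_along(IMPACT_COVS)) {
      v <- covariates[[IMPACT_COVS[j]]]
      if (!is.null(v)) X[, j] <- as.numeric(v)[m]
    }
  }
  if (is.null(scaling)) {
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- apply(X, 2, sd, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    sdv[is.na(sdv) | sdv == 0] <- 1
    scaling <- list(mu = mu, sd = sdv)
  }
  X <- sweep(X, 2, scaling$mu)
  X <- sweep(X, 2, scaling$sd, "/")
  X[is.na(X)] <- 0
  list(X = X, scaling = scaling)
}

#' Fit the cumulative-link mixed model
#'
#' Marginal maximum likelihood for the cumulative-probit model with a natural
#' cubic spline population time trend and per-patient (intercept, slope,
#' quadratic) random effects with diagonal covariance; the random effects are
#' integrated out by a Laplace approximation. Deterministic given data and
#' the documented start (thresholds from marginal category frequencies, zero
#' trend, random-effect standard deviations 1, 0.5, 0.25).
#'
#' @param cohort a `gose_cohort`; needs at least two patients with two or more
#'   observations and more than one observed category.
#' @param spline_df degrees of freedom of the natural spline over
#'   `[0, 547]` days (default 4; interior knots at quantiles of observation
#'   times).
#' @param use_covariates include the standardized IMPACT covariates as fixed
#'   effects (default `FALSE`).
#' @param control passed to [stats::optim()] control.
#' @return An object of class `clmm_fit` with thresholds `tau`, spline and
#'   covariate coefficients, random-effect log-SDs, and a report
#'   (log-likelihood, convergence and degeneracy flags).
#' @export
fit_clmm <- function(cohort, spline_df = 4, use_covariates = FALSE,
                     control = list()) {
  fr <- clmm_frame(cohort)
  if (length(unique(fr$y)) < 2)
    stop("degenerate fit: cohort has a single observed category", call. = FALSE)
  nobs_pp <- table(fr$patient_id)
  if (sum(nobs_pp >= 2) < 2)
    stop("need at least two patients with two or more observations", call. = FALSE)
  knots <- unique(quantile(fr$time_days, probs = seq_len(spline_df - 1) / spline_df))
  bknots <- c(0, INGEST_HORIZON)
  B <- splines::ns(fr$time_days, knots = knots, Boundary.knots = bknots)
  cm <- NULL
  Xc <- NULL
  if (use_covariates) {
    ids_obs <- fr$patient_id
    cm <- cov_matrix(cohort$covariates, cohort_ids(cohort))
    Xc <- cm$X[ids_obs, , drop = FALSE]
  }
  ids <- unique(fr$patient_id)
  pidx <- match(fr$patient_id, ids)
  start0 <- c(0, cumsum(tabulate(pidx)))[seq_along(ids)]
  lens <- tabulate(pidx)
  zt <- clmm_scale_time(fr$time_days)

  ncat <- N_STATES
  df <- ncol(B)
  pcov <- if (use_covariates) ncol(Xc) else 0
  freq <- tabulate(fr$y, ncat) / nrow(fr)
  cum <- pmin(pmax(cumsum(freq)[-ncat], 1e-3), 1 - 1e-3)
  tau_start <- qnorm(cum)
  par_start <- c(tau_start[1], log(pmax(diff(tau_start), 1e-2)),
                 rep(0, df + pcov), c(0, -0.7, -1.4))
  unpack <- function(par) {
    tau <- cumsum(c(par[1], exp(par[2:(ncat - 1)])))
    beta <- par[ncat - 1 + seq_len(df)]
    bcov <- if (pcov) par[ncat - 1 + df + seq_len(pcov)] else numeric(0)
    logsd <- par[ncat - 1 + df + pcov + 1:3]
    list(tau = tau, beta = beta, bcov = bcov, logsd = logsd)
  }
  nll <- function(par) {
    p <- unpack(par)
    if (any(p$logsd > 3) || any(p$logsd < -8)) return(1e10)
    eta <- as.numeric(B %*% p$beta)
    if (pcov) eta <- eta + as.numeric(Xc %*% p$bcov)
    v <- cpp_clmm_laplace(eta, zt, as.integer(fr$y), as.integer(start0),
                          as.integer(lens), p$tau, p$logsd, FALSE)$nll
    if (!is.finite(v)) 1e10 else v
  }
  ctrl <- modifyList(list(maxit = 300, reltol = 1e-9), control)
  opt <- optim(par_start, nll, method = "BFGS", control = ctrl)
  p <- unpack(opt$par)
  structure(list(tau = p$tau, beta = p$beta, bcov = p$bcov, logsd = p$logsd,
                 knots = knots, boundary_knots = bknots,
                 use_covariates = use_covariates,
                 cov_scaling = if (use_covariates) cm$scaling else NULL,
                 report = list(loglik = -opt$value,
                               convergence = opt$convergence == 0,
                               degenerate = any(diff(p$tau) < 1e-3),
                               iterations = opt$counts[["function"]])),
            class = "clmm_fit")
}

# Fixed-effect latent mean at times t for one patient's covariate row.
clmm_eta <- function(fit, t, covrow = NULL) {
  B <- splines::ns(t, knots = fit$knots, Boundary.knots = fit$boundary_knots)
  eta <- as.numeric(B %*% fit$beta)
  if (fit$use_covariates && length(fit$bcov)) {
    x <- rep(0, length(IMPACT_COVS))
    if (!is.null(covrow)) {
      for (j in seq_along(IMPACT_COVS)) {
        v <- covrow[[IMPACT_COVS[j]]]
        if (!is.null(v) && length(v) && !is.na(v)) x[j] <- as.numeric(v)
      }
      x <- (x - fit$cov_scaling$mu) / fit$cov_scaling$sd
      x[is.na(x)] <- 0
      miss <- vapply(IMPACT_COVS, function(nm) {
        v <- covrow[[nm]]; is.null(v) || !length(v) || is.na(v)
      }, logical(1))
      x[miss] <- 0
    }
    eta <- eta + sum(x * fit$bcov)
  }
  eta
}

# Category probabilities for latent mean mu and variance v (plus unit
# residual): exact Gaussian integral through the thresholds.
threshold_probs <- function(tau, mu, v) {
  sdt <- sqrt(1 + v)
  cum <- c(pnorm((tau - mu) / sdt), 1)
  diff(c(0, cum))
}

#' @export
predict.clmm_fit <- function(object, records, covariates = NULL,
                             target_day = DEFAULT_TARGET_DAY,
                             method_label = if (object$use_covariates) "clmm_cov" else "clmm",
                             ...) {
  d <- exp(2 * object$logsd)
  rows <- lapply(names(records), function(pid) {
    covrow <- if (!is.null(covariates)) covariates[match(pid, covariates$patient_id), ] else NULL
    obs <- records[[pid]]
    obs <- obs[obs$gose != 1, , drop = FALSE]
    zt_t <- clmm_scale_time(target_day)
    zrow <- c(1, zt_t, zt_t^2)
    eta_t <- clmm_eta(object, target_day, covrow)
    if (nrow(obs) == 0) {
      mu <- eta_t
      v <- sum(zrow^2 * d)
    } else {
      obs <- obs[order(obs$time_days), ]
      eta <- clmm_eta(object, obs$time_days, covrow)
      res <- cpp_clmm_laplace(eta, clmm_scale_time(obs$time_days),
                              as.integer(match(obs$gose, GOSE_LEVELS)),
                              0L, as.integer(nrow(obs)),
                              object$tau, object$logsd, TRUE)
      b <- as.numeric(res$modes[1, ])
      S <- matrix(res$covs[1, ], 3, 3)
      mu <- eta_t + sum(zrow * b)
      v <- as.numeric(zrow %*% S %*% zrow)
    }
    new_prediction(pid, method_label, threshold_probs(object$tau, mu, v))
  })
  prediction_frame(rows)
}
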