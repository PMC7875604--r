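# Latent Gaussian-process regression for GOSe trajectories.
#
# Latent variable u(t) = m(t, x) + f(t) + eps: m is a population mean
# (natural spline in time plus an optional linear term in the standardized
# IMPACT covariates) estimated by a cumulative-probit regression; f is a
# patient-level zero-mean Gaussian process with squared-exponential kernel
# (signal variance rho, length-scale ell days); eps ~ N(0, 1 - rho) is
# observation noise. The total latent variance is fixed at 1 so the
# thresholds of the stage-one probit fit remain on the correct scale; the
# free hyperparameters (rho, ell) are then estimated by maximizing the
# Laplace-approximated marginal likelihood over patients, all patients
# sharing the kernel. Observed categories arise by thresholding u.

gp_kernel <- function(t1, t2, rho, ell) {
  d <- outer(t1, t2, "-")
  rho * exp(-d^2 / (2 * ell^2))
}

# Ordinal probit cell log-probability and derivatives w.r.t. the latent f,
# with scale sigma for the residual.
gp_cell <- function(tau, y, u, sigma) {
  ncat <- length(tau) + 1
  a <- if (y < ncat) (tau[y] - u) / sigma else Inf
  c <- if (y > 1) (tau[y - 1] - u) / sigma else -Inf
  P <- pnorm(a) - pnorm(c)
  da <- if (is.finite(a)) dnorm(a) else 0
  dc <- if (is.finite(c)) dnorm(c) else 0
  if (P < 1e-300) {
    return(list(lp = -690, g = if (dc - da >= 0) 50 else -50, h = -50))
  }
  g <- (dc - da) / (P * sigma)
  h <- ((if (is.finite(c)) c * dc else 0) - (if (is.finite(a)) a * da else 0)) /
    (P * sigma^2) - g^2
  list(lp = log(P), g = g, h = min(h, -1e-12))
}

# Laplace approximation for one patient: mode of p(y | f) N(f; 0, K).
# Returns the mode, negative joint Hessian (Kinv + W), and marginal loglik.
gp_laplace <- function(K, eta, y, tau, sigma) {
  J <- length(y)
  Kc <- K + diag(1e-8, J)
  Kinv <- chol2inv(chol(Kc))
  f <- numeric(J)
  eval_joint <- function(f) {
    cells <- lapply(seq_len(J), function(j) gp_cell(tau, y[j], eta[j] + f[j], sigma))
    ll <- sum(vapply(cells, `[[`, numeric(1), "lp"))
    g <- vapply(cells, `[[`, numeric(1), "g") - as.numeric(Kinv %*% f)
    W <- diag(-vapply(cells, `[[`, numeric(1), "h"), J)
    list(obj = ll - 0.5 * sum(f * (Kinv %*% f)), g = g, H = Kinv + W, W = W, ll = ll)
  }
  st <- eval_joint(f)
  for (it in 1:50) {
    step <- solve(st$H, st$g)
    sz <- 1
    repeat {
      fn <- f + sz * step
      stn <- eval_joint(fn)
      if (stn$obj >= st$obj - 1e-12 || sz < 1e-6) break
      sz <- sz / 2
    }
    f <- fn
    st <- stn
    if (sqrt(sum(st$g^2)) < 1e-8) break
  }
  ldK <- 2 * sum(log(diag(chol(Kc))))
  ldH <- 2 * sum(log(diag(chol(st$H))))
  list(f = f, H = st$H, W = st$W, Kinv = Kinv,
       marg = st$obj - 0.5 * ldK - 0.5 * ldH)
}

#' Fit the latent Gaussian-process model
#'
#' Two stages: (1) a cumulative-probit regression of category on a natural
#' spline in time (plus standardized IMPACT covariates when
#' `use_covariates = TRUE`, the default) fixes the thresholds and the
#' population mean on the unit-variance latent scale; (2) the kernel
#' hyperparameters — signal variance `rho` (share of the unit latent variance
#' attributed to the smooth patient-level process) and length-scale `ell`
#' (days) — are estimated by maximizing the summed Laplace-approximated
#' marginal likelihood over a subsample of patients with two or more
#' observations (all patients share the kernel; single-observation patients
#' carry no information about `ell`).
#'
#' @param cohort a `gose_cohort`.
#' @param kernel_config list of starting values / bounds:
#'   `rho0` (default 0.5), `ell0` (default 90 days), `ell_range`
#'   (default `c(10, 400)`).
#' @param use_covariates include IMPACT covariates in the mean (default
#'   `TRUE`).
#' @param spline_df spline degrees of freedom for the population mean.
#' @param n_fit_patients subsample size for hyperparameter estimation
#'   (default 400).
#' @param seed seed for the subsample draw.
#' @return An object of class `gp_fit`.
#' @export
fit_gp <- function(cohort, kernel_config = list(), use_covariates = TRUE,
                   spline_df = 4, n_fit_patients = 400, seed = 1) {
  kc <- modifyList(list(rho0 = 0.5, ell0 = 90, ell_range = c(10, 400)), kernel_config)
  fr <- clmm_frame(cohort)
  if (length(unique(fr$y)) < 2)
    stop("degenerate fit: cohort has a single observed category", call. = FALSE)
  knots <- unique(quantile(fr$time_days, probs = seq_len(spline_df - 1) / spline_df))
  bknots <- c(0, INGEST_HORIZON)
  B <- splines::ns(fr$time_days, knots = knots, Boundary.knots = bknots)
  cm <- NULL
  X <- B
  if (use_covariates) {
    cm <- cov_matrix(cohort$covariates, cohort_ids(cohort))
    X <- cbind(B, cm$X[fr$patient_id, , drop = FALSE])
  }
  yf <- factor(fr$y, levels = seq_len(N_STATES))
  pfit <- MASS::polr(droplevels(yf) ~ X, method = "probit", Hess = FALSE)
  # map thresholds back onto the full 6-level scale (absent boundary levels
  # get infinite thresholds through the probability mapping)
  lev <- as.integer(levels(droplevels(yf)))
  tau <- rep(NA_real_, N_STATES - 1)
  tau[lev[-length(lev)]] <- as.numeric(pfit$zeta)
  # unobserved interior categories would leave gaps; fill by monotone spread
  tau <- fill_thresholds(tau)
  beta <- as.numeric(coef(pfit))

  eta_all <- as.numeric(X %*% beta)
  ids <- unique(fr$patient_id)
  multi <- ids[tabulate(match(fr$patient_id, ids)) >= 2]
  sub <- if (length(multi) > n_fit_patients)
    with_seed(seed, sample(multi, n_fit_patients)) else multi
  frs <- split(cbind(fr, eta = eta_all), fr$patient_id)

  obj <- function(par) {
    rho <- 1 / (1 + exp(-par[1]))
    ell <- exp(par[2])
    if (ell < kc$ell_range[1] || ell > kc$ell_range[2]) return(1e9)
    sigma <- sqrt(1 - rho)
    tot <- 0
    for (pid in sub) {
      d <- frs[[pid]]
      K <- gp_kernel(d$time_days, d$time_days, rho, ell)
      la <- gp_laplace(K, d$eta, d$y, tau, sigma)
      tot <- tot + la$marg
    }
    -tot
  }
  start <- c(log(kc$rho0 / (1 - kc$rho0)), log(kc$ell0))
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-6))
  rho <- 1 / (1 + exp(-opt$par[1]))
  ell <- exp(opt$par[2])
  structure(list(tau = tau, beta = beta, knots = knots, boundary_knots = bknots,
                 use_covariates = use_covariates,
                 cov_scaling = if (use_covariates) cm$scaling else NULL,
                 rho = rho, ell = ell, sigma = sqrt(1 - rho),
                 report = list(convergence = opt$convergence == 0,
                               marg_loglik = -opt$value,
                               n_fit_patients = length(sub),
                               ell_at_bound = ell <= kc$ell_range[1] * 1.01 ||
                                 ell >= kc$ell_range[2] * 0.99)),
            class = "gp_fit")
}

# Fill missing entries of a threshold vector keeping strict monotonicity
# (only needed when a training fold lacks a boundary category).
fill_thresholds <- function(tau) {
  n <- length(tau)
  if (!any(is.na(tau))) return(tau)
  obs <- which(!is.na(tau))
  if (length(obs) == 0) stop("no thresholds estimable", call. = FALSE)
  for (i in seq_len(n)) {
    if (is.na(tau[i])) {
      lo <- obs[obs < i]
      hi <- obs[obs > i]
      tau[i] <- if (!length(lo)) tau[min(hi)] - (min(hi) - i)
      else if (!length(hi)) tau[max(lo)] + (i - max(lo))
      else tau[max(lo)] + (tau[min(hi)] - tau[max(lo)]) * (i - max(lo)) / (min(hi) - max(lo))
    }
  }
  tau
}

gp_eta <- function(fit, t, covrow = NULL) {
  B <- splines::ns(t, knots = fit$knots, Boundary.knots = fit$boundary_knots)
  nb <- ncol(B)
  eta <- as.numeric(B %*% fit$beta[seq_len(nb)])
  if (fit$use_covariates) {
    x <- rep(0, length(IMPACT_COVS))
    if (!is.null(covrow)) {
      for (j in seq_along(IMPACT_COVS)) {
        v <- covrow[[IMPACT_COVS[j]]]
        if (!is.null(v) && length(v) && !is.na(v)) x[j] <- as.numeric(v)
      }
      x <- (x - fit$cov_scaling$mu) / fit$cov_scaling$sd
      miss <- vapply(IMPACT_COVS, function(nm) {
        v <- covrow[[nm]]; is.null(v) || !length(v) || is.na(v)
      }, logical(1))
      x[miss] <- 0
    }
    eta <- eta + sum(x * fit$bcov %||% fit$beta[nb + seq_along(IMPACT_COVS)])
  }
  eta
}

#' @export
predict.gp_fit <- function(object, records, covariates = NULL,
                           target_day = DEFAULT_TARGET_DAY,
                           method_label = if (object$use_covariates) "gp" else "gp_nocov",
                           ...) {
  rows <- lapply(names(records), function(pid) {
    covrow <- if (!is.null(covariates)) covariates[match(pid, covariates$patient_id), ] else NULL
    obs <- records[[pid]]
    obs <- obs[obs$gose != 1, , drop = FALSE]
    eta_t <- gp_eta(object, target_day, covrow)
    if (nrow(obs) == 0) {
      mu <- eta_t
      v <- object$rho + object$sigma^2   # = 1: population distribution
    } else {
      obs <- obs[order(obs$time_days), ]
      eta <- gp_eta(object, obs$time_days, covrow)
      K <- gp_kernel(obs$time_days, obs$time_days, object$rho, object$ell)
      la <- gp_laplace(K, eta, match(obs$gose, GOSE_LEVELS), object$tau, object$sigma)
      ks <- as.numeric(gp_kernel(target_day, obs$time_days, object$rho, object$ell))
      mu <- eta_t + sum(ks * (la$Kinv %*% la$f))
      # GP-Laplace predictive variance: k** - k*' (K + W^-1)^-1 k*
      Winv <- diag(1 / pmax(diag(la$W), 1e-12), nrow(obs))
      v_f <- object$rho - as.numeric(t(ks) %*% solve(K + Winv + diag(1e-8, nrow(obs)), ks))
      v <- max(v_f, 0) + object$sigma^2
    }
    # thresholds partition the unit-variance latent scale; total sd here
    cum <- c(pnorm((object$tau - mu) / sqrt(v)), 1)
    new_prediction(pid, method_label, diff(c(0, cum)))
  })
  prediction_frame(rows)
}
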