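# Latent-trajectory models: cumulative-probit mixed model and latent GP.

# A clmm_fit with prescribed parameters and a flat population trend.
manual_clmm_fit <- function(tau, logsd) {
  structure(list(tau = tau, beta = rep(0, 4), bcov = numeric(0),
                 logsd = logsd, knots = c(100, 200, 300),
                 boundary_knots = c(0, 547), use_covariates = FALSE,
                 cov_scaling = NULL, report = list()),
            class = "clmm_fit")
}

test_that("a single-category cohort is a degenerate fit error", {
  obs <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                    time_days = c(10, 100, 20, 200), gose = 6)
  expect_error(fit_clmm(gose_cohort(obs)), "single observed category")
  expect_error(fit_gp(gose_cohort(obs)), "single observed category")
})

test_that("patients without observations receive the population distribution", {
  fit <- manual_clmm_fit(tau = c(-1.5, -0.8, 0, 0.8, 1.5),
                         logsd = log(c(1, 0.5, 0.25)))
  recs <- list(p1 = data.frame(time_days = numeric(), gose = integer()),
               p2 = data.frame(time_days = numeric(), gose = integer()))
  pred <- predict(fit, recs)
  p1 <- as.numeric(pred[1, paste0("gose", 3:8)])
  p2 <- as.numeric(pred[2, paste0("gose", 3:8)])
  expect_equal(p1, p2)
  # matches the closed-form prior predictive at the target day
  zt <- (180 - 180) / 365
  v <- sum(c(1, zt, zt^2)^2 * exp(2 * fit$logsd))
  manual <- diff(c(0, pnorm((fit$tau - 0) / sqrt(1 + v)), 1))
  expect_equal(p1, manual, tolerance = 1e-9)
})

test_that("repeated top-category observations raise the top-category probability", {
  fit <- manual_clmm_fit(tau = c(-1.5, -0.8, 0, 0.8, 1.5),
                         logsd = log(c(1, 0.5, 0.25)))
  recs <- list(pop = data.frame(time_days = numeric(), gose = integer()),
               top = data.frame(time_days = c(20, 95, 160, 220), gose = rep(8L, 4)))
  pred <- predict(fit, recs)
  expect_gt(pred$gose8[2], pred$gose8[1])
  expect_equal(pred$point[2], 8L)
})

test_that("single-observation prediction agrees with a 2-D quadrature oracle", {
  tau <- c(-1.2, -0.5, 0.2, 0.9, 1.7)
  logsd <- log(c(0.9, 0.4, 0.2))
  fit <- manual_clmm_fit(tau, logsd)
  t_obs <- 95; y_obs <- 6L; target <- 180
  # latent effects enter only through v = z_obs'b and w = z_target'b,
  # jointly Gaussian under the diagonal random-effect prior
  z_o <- c(1, (t_obs - 180) / 365, ((t_obs - 180) / 365)^2)
  z_t <- c(1, 0, 0)
  D <- diag(exp(2 * logsd))
  Svv <- drop(z_o %*% D %*% z_o)
  Sww <- drop(z_t %*% D %*% z_t)
  Svw <- drop(z_o %*% D %*% z_t)
  cell <- function(tau, y, u) {
    hi <- if (y < 6) pnorm(tau[y] - u) else 1
    lo <- if (y > 1) pnorm(tau[y - 1] - u) else 0
    hi - lo
  }
  vg <- seq(-6, 6, length.out = 601) * sqrt(Svv)
  post_v <- dnorm(vg, 0, sqrt(Svv)) * vapply(vg, function(v) cell(tau, 4, v), numeric(1))
  post_v <- post_v / sum(post_v)           # y = 6 is category index 4
  probs_oracle <- numeric(6)
  for (i in seq_along(vg)) {
    mw <- Svw / Svv * vg[i]
    sw <- sqrt(Sww - Svw^2 / Svv)
    wg <- seq(-6, 6, length.out = 301) * sw + mw
    pw <- dnorm(wg, mw, sw); pw <- pw / sum(pw)
    for (k in 1:6)
      probs_oracle[k] <- probs_oracle[k] +
        post_v[i] * sum(pw * vapply(wg, function(w) cell(tau, k, w), numeric(1)))
  }
  probs_oracle <- probs_oracle / sum(probs_oracle)
  pred <- predict(fit, list(p = data.frame(time_days = t_obs, gose = y_obs)),
                  target_day = target)
  expect_lt(max(abs(as.numeric(pred[1, paste0("gose", 3:8)]) - probs_oracle)), 0.02)
})

test_that("an observation at the target day concentrates the prediction", {
  fit <- manual_clmm_fit(tau = c(-1.5, -0.8, 0, 0.8, 1.5),
                         logsd = log(c(1, 0.5, 0.25)))
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  set.seed(3)
  drop_ent <- replicate(30, {
    y <- sample(3:8, 1)
    r0 <- list(p = data.frame(time_days = numeric(), gose = integer()))
    r1 <- list(p = data.frame(time_days = 180, gose = y))
    e0 <- entropy(as.numeric(predict(fit, r0)[1, paste0("gose", 3:8)]))
    e1 <- entropy(as.numeric(predict(fit, r1)[1, paste0("gose", 3:8)]))
    e0 - e1
  })
  expect_gt(mean(drop_ent), 0)
})

test_that("clmm parameter recovery improves on richer panels (small harness)", {
  # generate directly from the model: flat trend, known thresholds
  set.seed(17)
  tau <- c(-1.5, -0.8, 0, 0.8, 1.5)
  sds <- c(1, 0.4, 0.2)
  n <- 250
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- rnorm(3, 0, sds)
    t <- c(14, 91, 180, 365)
    zt <- (t - 180) / 365
    u <- b[1] + b[2] * zt + b[3] * zt^2 + rnorm(4)
    data.frame(patient_id = sprintf("p%03d", i), time_days = t,
               gose = 3L + findInterval(u, tau))
  }))
  fit <- fit_clmm(gose_cohort(obs))
  expect_true(fit$report$convergence)
  expect_lt(max(abs(fit$tau - tau)), 0.3)
})

test_that("vanishing signal reduces the GP to the population mean model", {
  co <- small_cohort()
  fit <- fit_gp(co, use_covariates = FALSE,
                kernel_config = list(rho0 = 0.5, ell0 = 90))
  fit$rho <- 1e-10; fit$sigma <- sqrt(1 - fit$rho)
  recs <- list(a = data.frame(time_days = c(20, 95), gose = c(3L, 3L)),
               b = data.frame(time_days = c(30, 160), gose = c(8L, 8L)),
               c = data.frame(time_days = numeric(), gose = integer()))
  pred <- predict(fit, recs)
  P <- as.matrix(pred[paste0("gose", 3:8)])
  expect_lt(max(abs(P[1, ] - P[3, ])), 1e-6)   # data ignored
  expect_lt(max(abs(P[2, ] - P[3, ])), 1e-6)
})

test_that("the GP recovers a known length-scale within a factor of 1.5", {
  set.seed(29)
  tau <- c(-1.3, -0.6, 0, 0.6, 1.3)
  rho <- 0.6; ell <- 60
  n <- 250
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- sort(runif(5, 10, 450))
    K <- rho * exp(-outer(t, t, "-")^2 / (2 * ell^2)) + diag(1e-8, 5)
    f <- drop(t(chol(K)) %*% rnorm(5))
    u <- f + rnorm(5, 0, sqrt(1 - rho))
    data.frame(patient_id = sprintf("p%03d", i), time_days = t,
               gose = 3L + findInterval(u, tau))
  }))
  fit <- fit_gp(gose_cohort(obs), use_covariates = FALSE)
  expect_gt(fit$ell, ell / 1.5)
  expect_lt(fit$ell, ell * 1.5)
})

test_that("latent models show the regression-to-the-mean bias signature", {
  pairs <- default_cv_pairs()
  met_full <- compute_metrics(pairs, "full")
  for (m in c("clmm", "gp")) {
    b <- met_full[met_full$method == m & met_full$metric == "bias", ]
    low <- b$fold_mean[b$category %in% c("3", "4")]
    high <- b$fold_mean[b$category %in% c("7", "8")]
    # shrinkage toward the middle: low categories pulled up, the top category
    # pulled down, and conditional bias decreasing from low to high
    expect_gt(mean(low), 0)
    expect_lt(b$fold_mean[b$category == "8"], 0)
    expect_gt(mean(low), mean(high))
  }
})
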