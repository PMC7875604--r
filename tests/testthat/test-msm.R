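# Multi-state model: panel likelihood, fitting, conditional prediction.

test_that("single-observation patients contribute zero log-likelihood", {
  obs <- data.frame(patient_id = c("a", "b"), time_days = c(90, 100), gose = c(5, 7))
  co <- gose_cohort(obs)
  Q <- generator_matrix(rep(.01, 5), rep(.002, 5))
  expect_equal(panel_loglik(co, Q), 0)
})

test_that("a zero generator gives zero log-likelihood for unchanged patients", {
  obs <- data.frame(patient_id = c("a", "a", "b", "b"),
                    time_days = c(14, 180, 30, 200), gose = c(5, 5, 7, 7))
  co <- gose_cohort(obs)
  expect_equal(panel_loglik(co, matrix(0, 6, 6)), 0)
  # and an observed change under Q = 0 is impossible
  obs2 <- data.frame(patient_id = "a", time_days = c(14, 180), gose = c(5, 6))
  ll <- panel_loglik(gose_cohort(obs2), matrix(0, 6, 6))
  expect_true(is.infinite(ll) && ll < 0)
  expect_match(attr(ll, "bad_pair"), "patient a")
})

test_that("panel log-likelihood equals the closed-form 2-state sum on a toy cohort", {
  a <- 0.012; b <- 0.004
  Q <- generator_matrix(c(a, 0, 0, 0, 0), c(b, 0, 0, 0, 0))
  # three transition pairs on the GOSe 3/4 subchain
  obs <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
    time_days = c(10, 110, 20, 80, 5, 200),
    gose = c(3, 4, 4, 4, 3, 3))
  co <- gose_cohort(obs)
  p12 <- function(dt) a / (a + b) * (1 - exp(-(a + b) * dt))
  p22 <- function(dt) a / (a + b) + b / (a + b) * exp(-(a + b) * dt)
  p11 <- function(dt) b / (a + b) + a / (a + b) * exp(-(a + b) * dt)
  expected <- log(p12(100)) + log(p22(60)) + log(p11(195))
  expect_equal(panel_loglik(co, Q), expected, tolerance = 1e-12)
})

test_that("likelihood is invariant to shifting all observation times", {
  obs <- data.frame(
    patient_id = rep(sprintf("p%02d", 1:20), each = 3),
    time_days = rep(c(15, 95, 290), 20),
    gose = unlist(lapply(1:20, function(i) sort(3 + (c(i, i + 3, i + 5) %% 6)))))
  Q <- generator_matrix(c(.005, .02, .01, .009, .008),
                        c(.0035, .001, .0012, .0012, .001))
  co <- gose_cohort(obs)
  shifted <- obs
  shifted$time_days <- shifted$time_days + 200
  expect_equal(panel_loglik(co, Q), panel_loglik(gose_cohort(shifted), Q),
               tolerance = 1e-10)
})

test_that("refitting on the same data gives identical parameters", {
  co <- small_cohort()
  f1 <- fit_msm(co, covariates = NULL)
  f2 <- fit_msm(co, covariates = NULL)
  expect_identical(f1$logq, f2$logq)
  expect_true(f1$report$convergence)
})

test_that("unobserved transitions are driven to the intensity floor", {
  # upward-only data: all downward intensities unidentified
  set.seed(5)
  obs <- do.call(rbind, lapply(1:80, function(i) {
    data.frame(patient_id = sprintf("p%02d", i),
               time_days = c(20, 120, 300),
               gose = cummax(sample(3:8, 3, replace = TRUE)))
  }))
  co <- gose_cohort(obs)
  f <- fit_msm(co, covariates = NULL)
  down_idx <- which(f$structure$to == f$structure$from - 1)
  expect_true(any(f$logq[down_idx] <= -11.9))
  expect_true(f$report$convergence)
})

test_that("an observed exit from a declared absorbing state is a data error", {
  stru <- msm_structure()
  stru <- stru[stru$from != 6, ]   # state 6 (GOSe 8) absorbing
  obs <- data.frame(patient_id = "a", time_days = c(10, 100), gose = c(8, 7))
  expect_error(fit_msm(gose_cohort(obs), covariates = NULL, structure = stru),
               "absorbing")
})

test_that("conditional prediction collapses correctly in degenerate cases", {
  fit0 <- manual_msm_fit(up = rep(0, 5), down = rep(0, 5))
  # observation exactly at the target day -> point mass
  obs <- data.frame(time_days = c(100, 180), gose = c(5, 6))
  expect_equal(conditional_state_distribution(fit0, obs, 180)$probs,
               c(0, 0, 0, 1, 0, 0))
  # zero generator: point mass at the constant observed category
  obs2 <- data.frame(time_days = c(100, 300), gose = c(5, 5))
  pr <- conditional_state_distribution(fit0, obs2, 180)$probs
  expect_equal(pr, c(0, 0, 1, 0, 0, 0), tolerance = 1e-9)
  # empty panel -> not applicable
  expect_null(conditional_state_distribution(fit0, obs2[0, ], 180))
})

test_that("bracketed prediction uses the normalizer identity", {
  fit <- manual_msm_fit(up = c(.005, .02, .01, .009, .008),
                        down = c(.0035, .001, .0012, .0012, .001))
  Q <- msm_Q(fit)
  obs <- data.frame(time_days = c(91, 365), gose = c(4, 7))
  pr <- conditional_state_distribution(fit, obs, 180)$probs
  PL <- transition_matrix(Q, 89)
  PR <- transition_matrix(Q, 185)
  manual <- PL[2, ] * PR[, 5]
  manual <- manual / sum(manual)
  expect_equal(pr, manual, tolerance = 1e-12)
  # normalizer equals the through-probability
  expect_equal(sum(PL[2, ] * PR[, 5]), (PL %*% PR)[2, 5], tolerance = 1e-9)
})

test_that("serialized fits reload to identical predictions", {
  co <- small_cohort()
  f <- fit_msm(co, covariates = "age")
  path <- tempfile(fileext = ".txt")
  write_msm(f, path)
  f2 <- read_msm(path)
  obs <- data.frame(time_days = c(95, 370), gose = c(5, 7))
  expect_equal(conditional_state_distribution(f, obs, 180, age = 60)$probs,
               conditional_state_distribution(f2, obs, 180, age = 60)$probs,
               tolerance = 1e-12)
})
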