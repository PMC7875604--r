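# Synthetic cohort generator: exact simulation, observation process, and the
# structural properties downstream methods rely on.

test_that("a zero generator yields a constant path", {
  Q0 <- matrix(0, 6, 6)
  p <- simulate_trajectory(function(t) Q0, 547, init = 5, seed = 3)
  expect_equal(p$state, 5L)
  expect_equal(state_at(p, c(0, 180, 547)), rep(5L, 3))
})

test_that("symmetric 2-state chain spends half its time in each state", {
  a <- 0.05
  Q <- matrix(c(-a, a, a, -a), 2, byrow = TRUE)
  set.seed(42)
  occ <- replicate(300, {
    p <- simulate_trajectory(function(t) Q, 2000, init = 1)
    s <- state_at(p, seq(500, 2000, by = 10))
    mean(s == 1)
  })
  expect_lt(abs(mean(occ) - 0.5), 0.02)
})

test_that("state distribution at day 180 matches the matrix exponential", {
  Q <- generator_matrix(c(.005, .02, .01, .009, .008),
                        c(.0035, .001, .0012, .0012, .001))
  n <- 20000
  set.seed(7)
  states <- vapply(seq_len(n), function(i) {
    p <- simulate_trajectory(function(t) Q, 180, init = 2)
    state_at(p, 180)
  }, integer(1))
  emp <- tabulate(states, 6) / n
  ex <- transition_matrix(Q, 180)[2, ]
  se <- sqrt(ex * (1 - ex) / n)
  expect_true(all(abs(emp - ex) <= 3 * se + 1e-12))
})

test_that("an invalid generator is rejected with the offending row named", {
  Qbad <- matrix(0, 6, 6); Qbad[3, 4] <- -1
  expect_error(simulate_trajectory(function(t) Qbad, 10, init = 1), "row 3")
})

test_that("observe_path honours miss probability and the nominal schedule", {
  cfg <- synthetic_config(n_patients = 1, visit_jitter_sd = 0, visit_miss_prob = 0)
  p <- simulate_trajectory(function(t) matrix(0, 6, 6), 547, init = 4, seed = 1)
  ob <- observe_path(p, "ICU", cfg, seed = 2)
  expect_equal(ob$time_days, c(91, 180, 365))
  expect_equal(ob$gose, rep(6L, 3))
  cfg1 <- synthetic_config(n_patients = 1, visit_miss_prob = 1)
  expect_equal(nrow(observe_path(p, "ER", cfg1, seed = 2)), 0L)
})

test_that("fraction of patients with a valid 180-window observation matches the design", {
  cfg <- synthetic_config(n_patients = 2000, seed = 31)
  co <- simulate_cohort(cfg)
  # implied by the configuration: the day-180 visit survives with probability
  # (1 - miss) and its jitter lands within +/-14 days; other visits cannot
  # reach the window; patients losing all visits leave the cohort
  p_el <- (1 - cfg$visit_miss_prob) *
    (pnorm(14 / cfg$visit_jitter_sd) - pnorm(-14 / cfg$visit_jitter_sd))
  p_keep <- 1 - cfg$visit_miss_prob^3
  p_exp <- p_el / p_keep
  has <- vapply(split(co$obs, co$obs$patient_id),
                function(d) any(d$time_days >= 166 & d$time_days <= 194),
                logical(1))
  n <- length(has)
  ci <- p_exp + c(-1, 1) * qnorm(0.995) * sqrt(p_exp * (1 - p_exp) / n)
  expect_gt(mean(has), ci[1])
  expect_lt(mean(has), ci[2])
})

test_that("simulate_cohort is deterministic and honours the empty case", {
  c1 <- simulate_cohort(synthetic_config(n_patients = 50, seed = 9))
  c2 <- simulate_cohort(synthetic_config(n_patients = 50, seed = 9))
  expect_identical(c1$obs, c2$obs)
  expect_identical(c1$covariates, c2$covariates)
  c0 <- simulate_cohort(synthetic_config(n_patients = 0))
  expect_equal(length(cohort_ids(c0)), 0L)
})

test_that("per-patient streams do not depend on cohort size", {
  c1 <- simulate_cohort(synthetic_config(n_patients = 30, seed = 9))
  c2 <- simulate_cohort(synthetic_config(n_patients = 60, seed = 9))
  shared <- intersect(cohort_ids(c1), cohort_ids(c2))
  expect_identical(c1$obs[c1$obs$patient_id %in% shared, ],
                   c2$obs[c2$obs$patient_id %in% shared, ])
})

test_that("the default generator produces the recovery trend and category imbalance", {
  co <- default_cohort()
  tr <- co$meta$truth
  expect_gt(mean(tr$true_gose_180), mean(tr$true_gose_91))
  freq <- table(factor(tr$true_gose_180, levels = 3:8))
  expect_equal(names(which.min(freq)), "4")            # GOSe 4 rarest
  expect_gt(sum(freq[c("7", "8")]) / sum(freq), 0.35)  # skew toward 7-8
})

test_that("missingness is independent of the latent state (MAR by construction)", {
  co <- default_cohort()
  tr <- co$meta$truth
  has <- vapply(split(co$obs, co$obs$patient_id),
                function(d) any(d$time_days >= 166 & d$time_days <= 194),
                logical(1))[tr$patient_id]
  g1 <- tr$true_gose_180[has]
  g0 <- tr$true_gose_180[!has]
  se <- sqrt(var(g1) / length(g1) + var(g0) / length(g0))
  expect_lt(abs(mean(g1) - mean(g0)), 3 * se + 0.05)
})
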