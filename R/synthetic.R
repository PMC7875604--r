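# Synthetic-cohort generator.
#
# Latent truth is a continuous-time Markov chain on the merged GOSe scale 3..8
# with adjacent-state transitions and a piecewise-constant time effect: the
# intensity scale drops at a knot (default day 180), producing the population
# trend of continued recovery over the first six months that makes carrying
# observations forward biased. Patients are observed at stratum-specific
# protocol visits with Gaussian jitter; visits are missed at random with a
# probability that may depend on covariates but never on the latent state
# (missing at random by construction).

#' Configuration of the synthetic cohort generator
#'
#' Returns a validated configuration list. Defaults encode the study design
#' being emulated: three recruitment strata with visit schedules 2 weeks /
#' 3 months / 6 months (emergency room) and 3 / 6 / 12 months (ward, ICU),
#' an 18-month observation horizon, strong category imbalance with GOSe 4
#' rarest, and net upward (recovery) intensity before the day-180 knot.
#'
#' @param n_patients number of patients to simulate.
#' @param stratum_probs named 3-vector of stratum probabilities
#'   (ER, ward, ICU); must sum to 1.
#' @param visit_schedule named list of nominal visit days per stratum.
#' @param visit_jitter_sd standard deviation (days) of Gaussian visit jitter.
#' @param visit_miss_prob per-visit miss probability; a scalar, or a function
#'   of the patient's covariate row returning a scalar (must not use the
#'   latent state).
#' @param horizon_days observation horizon (default 547 days = 18 months).
#' @param intensity_params list with `up`, `down` (adjacent intensities per
#'   day, length 5 each), `knot` (day of the time-inhomogeneity), `post_scale`
#'   (intensity multiplier after the knot), `skip_frac` (optional intensity of
#'   two-state jumps as a fraction of the adjacent rate; default 0, used to
#'   test methods under mild misspecification).
#' @param covariate_effects list; `age_up` is the log-linear loading of age
#'   (per decade, centered at 45) on the upward intensities.
#' @param initial_state_probs probability vector over GOSe 3..8 at injury.
#' @param enable_death if `TRUE`, adds an absorbing death state; deaths before
#'   day 180 are excluded from the cohort, deaths after 180 appear as
#'   category-1 observations.
#' @param death_rate intensity of death from the two worst living states
#'   (only used when `enable_death = TRUE`).
#' @param seed integer seed; all randomness is split deterministically per
#'   patient so results do not depend on cohort size.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 3000,
                             stratum_probs = c(ER = 0.20, ward = 0.36, ICU = 0.44),
                             visit_schedule = list(ER = c(14, 91, 180),
                                                   ward = c(91, 180, 365),
                                                   ICU = c(91, 180, 365)),
                             visit_jitter_sd = 10,
                             visit_miss_prob = 0.3,
                             horizon_days = 547,
                             intensity_params = list(
                               up = c(0.005, 0.020, 0.010, 0.009, 0.008),
                               down = c(0.0035, 0.001, 0.0012, 0.0012, 0.0010),
                               knot = 180, post_scale = 0.3, skip_frac = 0),
                             covariate_effects = list(age_up = -0.15),
                             initial_state_probs = c(0.34, 0.13, 0.16, 0.15, 0.12, 0.10),
                             enable_death = FALSE,
                             death_rate = 0.0004,
                             seed = 1) {
  stopifnot(n_patients >= 0, visit_jitter_sd >= 0, horizon_days > 0)
  assert_prob_vector(stratum_probs, "stratum_probs")
  assert_prob_vector(initial_state_probs, "initial_state_probs")
  stopifnot(length(initial_state_probs) == N_STATES)
  for (s in names(visit_schedule)) {
    v <- visit_schedule[[s]]
    if (any(diff(v) <= 0))
      stop(sprintf("visit days for stratum '%s' must be strictly increasing", s),
           call. = FALSE)
  }
  if (is.numeric(visit_miss_prob))
    stopifnot(visit_miss_prob >= 0, visit_miss_prob <= 1)
  ip <- intensity_params
  ip$skip_frac <- ip$skip_frac %||% 0
  stopifnot(length(ip$up) == N_STATES - 1, length(ip$down) == N_STATES - 1,
            ip$post_scale >= 0, ip$knot > 0)
  structure(list(n_patients = n_patients, stratum_probs = stratum_probs,
                 visit_schedule = visit_schedule, visit_jitter_sd = visit_jitter_sd,
                 visit_miss_prob = visit_miss_prob, horizon_days = horizon_days,
                 intensity_params = ip, covariate_effects = covariate_effects,
                 initial_state_probs = initial_state_probs,
                 enable_death = enable_death, death_rate = death_rate,
                 seed = seed),
            class = "synthetic_config")
}

# Internal state coding: 1..6 = GOSe 3..8; when death is enabled state 7 is
# absorbing and maps to GOSe 1.
state_to_gose <- function(s) ifelse(s == 7L, 1L, s + 2L)

#' Time-dependent generator implied by a configuration
#'
#' Builds the `Q(t)` function for one patient: adjacent-state intensities,
#' optional two-state jumps, a log-linear age effect on upward intensities,
#' and the piecewise-constant drop in intensity scale at the knot.
#'
#' @param config a `synthetic_config`.
#' @param age patient age in years (`NA` for the reference age of 45).
#' @return Function of time `t` returning a generator matrix.
#' @export
generator_fn <- function(config, age = NA) {
  ip <- config$intensity_params
  zage <- if (is.na(age)) 0 else (age - 45) / 10
  up <- ip$up * exp((config$covariate_effects$age_up %||% 0) * zage)
  down <- ip$down
  n <- if (config$enable_death) N_STATES + 1L else N_STATES
  base <- matrix(0, n, n)
  base[cbind(1:5, 2:6)] <- up
  base[cbind(2:6, 1:5)] <- down
  if (ip$skip_frac > 0) {
    base[cbind(1:4, 3:6)] <- ip$skip_frac * up[1:4]
    base[cbind(3:6, 1:4)] <- ip$skip_frac * down[2:5]
  }
  if (config$enable_death) {
    base[1, 7] <- config$death_rate
    base[2, 7] <- config$death_rate / 2
  }
  knot <- ip$knot
  post <- ip$post_scale
  function(t) {
    Q <- if (t < knot) base else base * post
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    Q
  }
}

#' Simulate one latent state trajectory
#'
#' Exact event-driven simulation of a (possibly time-inhomogeneous)
#' continuous-time Markov chain by thinning: candidate events arrive at the
#' global rate bound and are accepted with probability equal to the current
#' total exit rate over the bound. For piecewise-constant generators such as
#' the default the bound is exact and the simulation is exact.
#'
#' @param Q_fn function of time returning a generator matrix.
#' @param t_max simulation horizon in days.
#' @param init initial state: an integer state index, or a probability vector
#'   to draw it from.
#' @param seed integer seed (the function restores the caller's RNG state).
#' @return data frame of class `state_path` with columns `time`, `state`:
#'   a right-continuous piecewise-constant path starting at time 0.
#' @export
simulate_trajectory <- function(Q_fn, t_max, init, seed = NULL) {
  check_t <- unique(c(seq(0, t_max, length.out = 33), t_max))
  rate_bound <- 0
  for (t in check_t) {
    Q <- Q_fn(t)
    validate_generator(Q)
    rate_bound <- max(rate_bound, max(-diag(Q)))
  }
  run <- function() {
    n <- nrow(Q_fn(0))
    s <- if (length(init) == 1) as.integer(init) else
      sample.int(n, 1, prob = init)
    times <- 0
    states <- s
    if (rate_bound > 0) {
      t <- 0
      repeat {
        t <- t + rexp(1, rate_bound)
        if (t > t_max) break
        rates <- Q_fn(t)[s, ]
        rates[s] <- 0
        total <- sum(rates)
        if (runif(1) < total / rate_bound) {
          s <- sample.int(n, 1, prob = rates)
          times <- c(times, t)
          states <- c(states, s)
        }
      }
    }
    structure(data.frame(time = times, state = states), class = c("state_path", "data.frame"))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' State of a trajectory at given times
#' @param path a `state_path`.
#' @param t numeric vector of times (days).
#' @return integer vector of state indices.
#' @export
state_at <- function(path, t) {
  path$state[findInterval(t, path$time)]
}

#' Observe a latent trajectory at jittered protocol visits
#'
#' Visit times are the stratum's nominal days plus Gaussian jitter, clamped to
#' `[1, horizon]`; each visit is independently missed with the configured
#' probability (a function of covariates only, never of the latent state).
#'
#' @param path a `state_path` covering `[0, horizon]`.
#' @param stratum stratum name (must appear in `config$visit_schedule`).
#' @param config a `synthetic_config`.
#' @param seed integer seed.
#' @param covariates optional covariate row passed to a functional
#'   `visit_miss_prob`.
#' @return data frame with columns `time_days`, `gose` (possibly zero rows).
#' @export
observe_path <- function(path, stratum, config, seed = NULL, covariates = NULL) {
  nominal <- config$visit_schedule[[stratum]]
  if (is.null(nominal)) stop(sprintf("unknown stratum '%s'", stratum), call. = FALSE)
  run <- function() {
    times <- nominal + rnorm(length(nominal), 0, config$visit_jitter_sd)
    times <- pmin(pmax(times, 1), config$horizon_days)
    mp <- config$visit_miss_prob
    if (is.function(mp)) mp <- mp(covariates)
    keep <- runif(length(times)) >= mp
    times <- sort(times[keep])
    data.frame(time_days = times,
               gose = state_to_gose(state_at(path, times)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Draw one patient's baseline covariates; marginals chosen to resemble a
# typical TBI cohort (median age ~48, ~66% male, mild-skewed Marshall CT),
# with realistic per-variable missingness.
draw_covariates <- function() {
  age <- round(min(max(rnorm(1, 47, 20), 0), 95), 1)
  miss <- function(x, p) if (runif(1) < p) NA else x
  data.frame(
    age = age,
    sex = miss(rbinom(1, 1, 0.66), 0.0),
    gcs_motor = miss(sample(1:6, 1, prob = c(0.05, 0.05, 0.08, 0.12, 0.25, 0.45)), 0.03),
    pupil_reactivity = miss(sample(0:2, 1, prob = c(0.08, 0.07, 0.85)), 0.04),
    hypoxia = miss(rbinom(1, 1, 0.056), 0.05),
    hypotension = miss(rbinom(1, 1, 0.057), 0.05),
    marshall_ct = miss(sample(1:6, 1, prob = c(0.41, 0.42, 0.03, 0.005, 0.005, 0.13)), 0.09),
    tsah = miss(rbinom(1, 1, 0.36), 0.03),
    edh = miss(rbinom(1, 1, 0.11), 0.03),
    glucose = miss(round(rlnorm(1, log(6.9), 0.25), 1), 0.24),
    hemoglobin = miss(round(rnorm(1, 13.5, 1.9), 1), 0.16)
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws covariates, a latent trajectory, and jittered/missed observations for
#' each patient using a deterministic per-patient seed stream. The true latent
#' state at day 180 is retained in the cohort metadata for truth-based
#' testing. When death is enabled, patients dead before day 180 are excluded
#' (the target outcome is only defined for survivors). Patients with no
#' surviving observations are excluded as at ingest.
#'
#' @param config a `synthetic_config`.
#' @return A `gose_cohort`; `meta$truth` holds the per-patient true GOSe at
#'   day 180, `meta$config` the generator configuration.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_patients == 0)
    return(gose_cohort(data.frame(patient_id = character(), time_days = numeric(),
                                  gose = integer()),
                       meta = list(config = config)))
  strata <- names(config$visit_schedule)
  obs_list <- vector("list", config$n_patients)
  cov_list <- vector("list", config$n_patients)
  truth <- numeric(config$n_patients)
  truth91 <- numeric(config$n_patients)
  keep <- logical(config$n_patients)
  for (i in seq_len(config$n_patients)) {
    with_seed(patient_seed(config$seed, i), {
      pid <- sprintf("P%05d", i)
      stratum <- sample(strata, 1, prob = config$stratum_probs)
      cov <- draw_covariates()
      Q_fn <- generator_fn(config, age = cov$age)
      path <- simulate_trajectory(Q_fn, config$horizon_days,
                                  init = config$initial_state_probs)
      s180 <- state_at(path, 180)
      if (config$enable_death && s180 == 7L) {
        keep[i] <- FALSE
      } else {
        panel <- observe_path(path, stratum, config, covariates = cov)
        keep[i] <- nrow(panel) > 0
        if (keep[i]) {
          panel$patient_id <- pid
          obs_list[[i]] <- panel
          cov_list[[i]] <- cbind(data.frame(patient_id = pid, stratum = stratum), cov)
          truth[i] <- state_to_gose(s180)
          truth91[i] <- state_to_gose(state_at(path, 91))
        }
      }
    })
  }
  obs <- do.call(rbind, obs_list[keep])
  covs <- do.call(rbind, cov_list[keep])
  truth_df <- data.frame(patient_id = covs$patient_id,
                         true_gose_180 = as.integer(truth[keep]),
                         true_gose_91 = as.integer(truth91[keep]))
  cohort <- gose_cohort(obs[c("patient_id", "time_days", "gose")], covs,
                        meta = list(config = config, seed = config$seed))
  cohort$meta$truth <- truth_df[truth_df$patient_id %in% cohort_ids(cohort), ]
  cohort
}

#' Write the companion truth table of a synthetic cohort
#' @param cohort a simulated `gose_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  if (is.null(cohort$meta$truth)) stop("cohort carries no truth table", call. = FALSE)
  write.csv(cohort$meta$truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
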