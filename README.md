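# goseimpute

Model-based single imputation of a longitudinal ordinal outcome — the extended
Glasgow Outcome Scale (GOSe) — at a fixed target day (180 days post-injury),
with a cross-validated evaluation suite and a synthetic-cohort generator for
fully reproducible benchmarking.

## The problem

Longitudinal TBI studies schedule GOSe assessments at 2 weeks, 3 months,
6 months and 12 months post-injury, but visits are jittered across wide
protocol windows and many are missed. The 6-month GOSe is the primary
endpoint, so missing or mistimed values are routinely filled by *last
observation carried forward* (LOCF) — which is biased downward whenever
patients are still recovering, ignores information collected after day 180,
and gives no uncertainty statement.

This package implements five imputation strategies that each return a full
predictive distribution `P(GOSe_180 = k), k ∈ {3,…,8}` per patient (GOSe 2 is
merged into 3; category 1 is excluded by conditioning on 6-month survival):

| method | idea |
|---|---|
| `locf` | last pre-target observation, as a degenerate point mass |
| `mice` | chained proportional-odds imputation of the four protocol windows |
| `clmm` | cumulative-probit mixed model: spline population trend + per-patient quadratic random effects |
| `gp` | latent Gaussian-process deviations from a population mean (IMPACT covariates by default) |
| `msm` | continuous-time Markov multi-state model fitted from panel data by maximum likelihood, `P(Δt) = expm(QΔt)` |

The point imputation is the modal category (ties toward the worse category),
and multiple imputations can be drawn post hoc from the stored distribution by
inverse-transform sampling.

Evaluation follows a 3-fold cross-validation on patients with a valid
observation in 180 ± 14 days: the fold's in-window observations are removed,
all methods are refitted on everything else, and bias (imputed − observed),
directional bias, MAE, RMSE and fold-averaged confusion matrices are computed
overall and conditional on the observed category — on the subset where LOCF
applies, and on the full eligible set.

## Worked example

```r
library(goseimpute)

# a synthetic cohort emulating the study design: three recruitment strata,
# jittered protocol visits, 30% missed assessments, recovery before day 180
cohort <- simulate_cohort(synthetic_config(n_patients = 500, seed = 42))
cohort
#> GOSe cohort: 486 patients, 1037 observations
#> category counts: 1:0 3:221 4:68 5:154 6:155 7:183 8:256

# impute everyone's day-180 GOSe with the multi-state model
pred <- impute_cohort(cohort, method = "msm", seed = 1)
head(pred[, c("patient_id", "gose3", "gose6", "gose8", "point")], 3)
#>   patient_id      gose3        gose6        gose8 point
#> 1     P00001 0.99735853 1.656858e-09 7.311101e-18     3
#> 2     P00002 0.15091002 1.030377e-01 1.426184e-03     4
#> 3     P00003 0.00694492 3.713517e-01 2.190341e-02     5

# cross-validated comparison against LOCF
pairs <- run_cv(cohort, methods = c("locf", "msm"), spec = cv_spec(seed = 1))
met <- compute_metrics(pairs, population = "locf_subset")
subset(met, category == "overall" & metric == "bias")
#>    method  population category metric  fold_mean         se   n
#> 1    locf locf_subset  overall   bias -0.4814514 0.01987661 214
#> 29    msm locf_subset  overall   bias -0.3738500 0.01028441 214
```

LOCF imputes about half a category too low on average — the signature of
carrying stale observations forward through a recovering population — while
the multi-state model, which interpolates between the observations bracketing
day 180, cuts that bias substantially. On the full default cohort
(`n_patients = 3000`) the same comparison also shows the MSM's advantage in
MAE/RMSE and the characteristic difficulty of the rarest category (GOSe 4)
for every method.

A command-line wrapper covering `simulate`, `impute`, `evaluate` and `table1`
is installed at `inst/cli/goseimpute`:

```sh
Rscript inst/cli/goseimpute simulate --n 3000 --seed 1 --out cohort.csv
Rscript inst/cli/goseimpute evaluate --cohort cohort.csv \
    --methods locf,msm,mice --k 3 --seed 1 --out-dir results/
```

## Package layout

* `R/synthetic.R` — continuous-time Markov trajectory simulator and the
  cohort generator (visit jitter, MAR missed visits, IMPACT covariates).
* `R/ctmc.R`, `R/msm.R`, `src/` — generator matrices, matrix exponentials,
  panel likelihood (RcppArmadillo), fitting and conditional prediction.
* `R/mice.R`, `R/clmm.R`, `R/gp.R`, `R/locf.R` — the other four methods.
* `R/evaluation.R` — folds, metrics, confusion matrices, subgroup table.
* `R/cohort.R`, `R/cli.R` — data model, CSV I/O, command-line entry points.
* `vignettes/methods.Rmd` — models, assumptions, numerical choices, and what
  the synthetic benchmark does and does not demonstrate.
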