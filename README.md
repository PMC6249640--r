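# coxianjm

Two-stage joint modelling of longitudinal biomarker and survival data with
a Coxian phase-type regression model.

## The problem

In degenerative diseases such as chronic kidney disease (CKD), a routinely
measured biomarker — haemoglobin, say — co-evolves with the underlying
disease process, and how an *individual* deviates from the population-average
biomarker trajectory carries prognostic information. Standard joint models
link such deviations to survival through a Cox proportional hazards model,
which says nothing about *how* a patient progresses before the event.
`coxianjm` instead represents survival with a **Coxian phase-type
distribution**: the time to absorption of a continuous-time Markov chain
whose ordered transient phases can be read as latent disease stages. This
yields, beyond covariate effects, the probability of dying from each stage,
a partition of the observed death times into stage cohorts, and
population-average *and* patient-specific survivor and hazard curves.

The package is aimed at biostatisticians analysing registry-style data:
repeated biomarker measurements per subject plus an event/censoring time.

## The model

**Stage 1.** A linear mixed effects model for the longitudinal response
(ML estimation, delegated to `lme4`):

    y_ij = x_ij' beta + b_i0 + b_i1 t_ij + e_ij,
    (b_i0, b_i1) ~ N(0, D),   e_ij ~ N(0, sigma^2),

with empirical BLUPs b̂_i = D Z_i' V_i^{-1} (y_i − X_i β̂) as each subject's
intercept and slope deviation.

**Stage 2.** An n-phase Coxian phase-type distribution with sequential
transition rates λ_k (phase k → k+1) and absorption rates μ_k (phase k →
death), density f(t) = **p** exp(**Q** t) **q**, in which every rate of
subject *i* is scaled by the multiplicative rate-of-flow factor

    exp(− b_i0 α1 − b_i1 t_i α2).

Rates and α are estimated jointly by multi-start Nelder–Mead maximum
likelihood; the number of phases is chosen by sequential likelihood-ratio
tests with AIC/BIC; standard errors of the factors e^{−α} come from a
subject-level nonparametric bootstrap. Absorption probabilities
π_k = (μ_k / (μ_k + λ_k)) Π_{j<k} λ_j / (μ_j + λ_j) classify the ordered
event times into phase cohorts.

## Worked example

The fitted three-phase model of a haemodialysis cohort has rates
λ = (0.060, 0.467, 0), μ = (9.02e−11, 0.435, 0.060) per month and
coefficients α = (0.246, 0.156):

```r
library(coxianjm)

baseline <- coxian_params(lambda = c(0.060, 0.467, 0),
                          mu     = c(9.02e-11, 0.435, 0.060))
absorption_probabilities(baseline)
#> # A tibble: 3 × 2
#>   phase          prob
#>   <int>         <dbl>
#> 1     1 0.00000000150
#> 2     2 0.482
#> 3     3 0.518
```

Essentially no one dies from the first (stable) phase; 48.2% of deaths come
from the fast second phase and 51.8% from the slow third. A subject whose
haemoglobin starts 3.85 g/dL below the population average (intercept
deviation −3.850, slope deviation +0.081, seen at 6.72 months) flows

```r
f <- rate_scaling_factor(list(b0 = -3.850, b1 = 0.081), t = 6.72,
                         alpha = c(0.246, 0.156))
round(f, 3)
#> [1] 2.368
round(scaled_parameters(baseline, f)$mu[3], 3)
#> [1] 0.142
```

2.368 times faster than average, and their limiting hazard is 0.142 rather
than 0.060 per month — a candidate for earlier intervention.

The full two-stage pipeline on a synthetic cohort emulating the registry
(577 subjects, ~18 monthly haemoglobin measurements each):

```r
cohort  <- generate_cohort(ckd_preset(seed = 42))
lme     <- fit_lme_stage(cohort$longitudinal, fixed = c("x1", "x2"))
glance(lme)
#> # A tibble: 1 × 8
#>    loglik    df sigma2 var_b0 var_b1 cor_b0_b1 n_subjects reml
#> 1 -11940.     8  0.976   1.47 0.0412    -0.744        577 FALSE

effects <- predict_random_effects(lme)
fit  <- fit_coxian_regression(cohort$survival, effects, n_phases = 3,
                              n_restarts = 10, seed = 1)
tidy(fit, coefficients = TRUE)
#> # A tibble: 2 × 3
#>   term   estimate rate_factor
#> 1 alpha1   0.411        0.663
#> 2 alpha2   0.0917       0.912

boot <- bootstrap_coxian(fit, B = 200, seed = 2)
tidy(boot)[, 1:6]
#> # A tibble: 2 × 6
#>   term           estimate      se conf_low conf_high perc_low
#> 1 exp_neg_alpha1    0.663 0.0334     0.598     0.729    0.599
#> 2 exp_neg_alpha2    0.912 0.00682    0.899     0.926    0.898
```

Both intervals exclude 1: lower initial haemoglobin and a steeper
haemoglobin trend both significantly accelerate progression. `autoplot()`
methods draw the fitted curves, and `plot_individual_curves()` overlays
patient-specific survivor or hazard curves on the population average.
A thin CLI (`exec/coxianjm`) exposes `simulate`, `run` and `curves`
subcommands over the same functions; `run_two_stage()` writes a JSON
results bundle, curve CSVs and a text report.

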