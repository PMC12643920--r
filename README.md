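# ecodisc

Hierarchical Bayesian analysis of effort- and time-discounting tasks with
self-benefitting vs pro-environmental rewards.

## The problem

In pro-environmental decision tasks, participants repeatedly choose
between a no-cost option (1 credit, guaranteed) and a costly option
(2–10 credits) that requires either physical effort (grip force at
40–80% of individual maximum, 5 levels) or waiting time (5 calibrated
durations, 3–27 s). Rewards are paid to the participant ("self") or
donated to a CO2-reduction program ("environment"). The analysis
question: how steeply does each cost devalue the reward, and is the
devaluation steeper when the environment benefits?

`ecodisc` is for researchers running or reanalysing such paradigms. It
covers the full pipeline: generative encoding of the experimental
design, a synthetic cohort simulator, the 12-model discounting space,
hierarchical Bayesian estimation, PSIS-LOO model comparison, validation
(posterior predictive checks, parameter recovery), and the descriptive
and nonparametric statistics used to summarise the data.

## The model

The costly option's subjective value is a discounted reward, with cost
entering as its level C ∈ {1..5}:

    linear:      SV = R − k·C
    parabolic:   SV = R − k·C²
    hyperbolic:  SV = R / (1 + k·C)

and choices follow a softmax in the value difference against the
1-credit baseline:

    P(costly) = 1 / (1 + exp(−β·(SV_costly − SV_baseline)))

The discount rate k and inverse temperature β can each be joint or
separate across recipients, giving 12 models (e.g. `parabolic-2k2b` =
parabolic with recipient-specific k and β). Subject parameters are
log-normally distributed around group-level means; estimation is by
MCMC (JAGS) with split-R̂ convergence checks, and models are compared by
LOOIC = −2·elpd computed with Pareto-smoothed importance sampling. The
headline individual-difference quantity is the asymmetry
`k_self − k_env`, which the package relates to policy-support scores
with Kendall's tau and tests across recipients with the Wilcoxon
signed-rank test.

## Worked example

```r
library(ecodisc)

# simulate a small cohort under the default study conditions
coh <- simulate_cohort(cohort_config(n_subjects = 8, seed = 42))

# descriptive summary: costly-choice proportions by recipient (effort task)
round(100 * c(
  self = choice_proportions(coh$trials, task = "effort", recipient = "self")$participant_mean,
  env  = choice_proportions(coh$trials, task = "effort", recipient = "environment")$participant_mean), 1)

# fit the recipient-specific parabolic model to the effort task
eff <- subset(coh$trials, task == "effort")
fit <- fit_model(eff, model_spec("parabolic"),
                 config = mcmc_config(chains = 2, iterations = 900,
                                      warmup = 400, seed = 1))
fit
compute_loo(fit)
head(k_difference(fit), 3)
```

```
#> self  env
#> 74.0 66.1
#> posterior_fit: parabolic-2k2b, task effort, 8 subjects, 1000 draws, max Rhat 1.012
#> PSIS-LOO: elpd -204.8 (SE 14.9), LOOIC 409.7, 0 high khat
#>   participant     k_self      k_env      k_diff
#> 1        S001 0.13759673 0.07115605  0.06644068
#> 2        S002 0.31488631 0.90865262 -0.59376631
#> 3        S003 0.05420091 0.33746433 -0.28326342
```

Simulated participants chose the costly option less often when the
reward went to the environment (66.1% vs 74.0% of trials); the fitted
recipient-specific discount rates recover that asymmetry per subject
(negative `k_diff` = steeper environmental discounting), and the LOOIC
is the model-comparison score (lower is better) used to select among
the 12 candidate models with `compare_models()`.

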