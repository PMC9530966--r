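# ttesim

Target trial emulation and longitudinal g-methods for simulated hospital
cohorts.

## The problem

Observational studies of in-hospital treatments — corticosteroids for
severe COVID-19 pneumonia being the canonical recent example — face a
tangle of longitudinal complications: treatment is started when patients
deteriorate (confounding by indication), illness severity both responds to
treatment and drives future treatment, death, and discharge
(treatment-confounder feedback), and discharge removes the healthiest
patients from view (informative loss to follow-up). "Model-first" analyses
that drop such data into a Cox regression inherit immortal-time bias,
collider bias from severity-based inclusion criteria, and time-dependent
confounding that no covariate adjustment can repair.

The question-first alternative is to emulate a hypothetical target trial: a
dynamic regime that starts a 6-day corticosteroid course if and when a
patient meets severe-hypoxia criteria, contrasted with never treating, with
loss to follow-up abolished. The estimand is the 28-day counterfactual
mortality risk difference

θ = P(Y^(dynamic) = 1) − P(Y^(never) = 1),

identified by the longitudinal g-formula under sequential conditional
randomization of treatment and censoring given baseline and time-varying
confounders.

`ttesim` provides all the pieces needed to study this design question with
a known answer:

- **Synthetic cohorts** (`dgp_config()`, `simulate_cohort()`): a
  daily-resolution hospitalized-cohort process with a latent severity state
  driving hypoxia, treatment, death, and discharge, itself relieved by
  recent treatment. Counterfactual truth comes from forced-regime Monte
  Carlo (`counterfactual_risk_mc()`) or, for a finite-state configuration,
  exact trajectory enumeration (`enumerate_truth()`).
- **Trial emulation primitives**: methylprednisolone-equivalent dosing
  (`mpred_equivalent()`), rolling 24-hour 0.5 mg/kg exposure windows
  (`derive_daily_exposure()`), severe-hypoxia derivation from
  respiratory-support records (`derive_daily_hypoxia()`), eligibility
  filtering, and the two regimes (`regime()`, `assign_regime()`).
- **Estimators** (`estimate_regime()`, `emulate_trial()`): iterated
  conditional expectation g-computation, inverse probability of treatment
  and censoring weighting, and the primary sequentially doubly robust (SDR)
  estimator with cross-fitting and a super-learner ensemble
  (`fit_superlearner()`), with influence-function standard errors and
  normal 95% confidence intervals.
- **Model-first designs** (`run_all_designs()`): the ten Cox study designs
  (A–J) common in the observational corticosteroid literature — anytime /
  1-day / 5-day exposure windows, death and pre-treatment exclusions,
  censoring at late treatment, and a time-varying Cox model — so the
  design biases can be demonstrated against the known truth.

## Worked example

```r
library(ttesim)

cfg <- dgp_config(n_patients = 5000, seed = 7)   # 28-day cohort process
coh <- simulate_cohort(cfg)
coh
#> <long_cohort> 5000 patients, 41381 person-days, horizon 28
#>   deaths 956, lost to follow-up 3838, ever treated 775, ever hypoxic 2562

em <- emulate_trial(coh, method = "sdr", v_folds = 5, seed = 7)
em
#> Target trial emulation
#> risk_dynamic [sdr]: 0.2664 (se 0.0415, 95% CI 0.1851 to 0.3478), n = 5000
#> risk_never [sdr]: 0.3419 (se 0.0205, 95% CI 0.3018 to 0.3821), n = 5000
#> risk_difference [sdr]: -0.0755 (se 0.0465, 95% CI -0.1665 to 0.0155), n = 5000

contrast(em$risk_dynamic, em$risk_never, "odds_ratio")
#> odds_ratio [sdr]: 0.6990 (se 0.2318, 95% CI 0.4438 to 1.1010), n = 5000

run_all_designs(coh, designs = c("A", "B", "F", "J"))
#> Model-first Cox designs (exposure hazard ratios)
#>   design    hr ci_low ci_high     n events excluded status
#> 1      A 0.542  0.462   0.636  2562    871     2438     ok
#> 2      B 0.704  0.582   0.851  2562    871     2438     ok
#> 3      F 0.683  0.576   0.809  2562    871     2438     ok
#> 4      J 0.779  0.645   0.939 41381    956      0       ok

counterfactual_risk_mc(cfg, regime("dynamic"), n_mc = 200000, seed = 1)
#> counterfactual risk 0.2949 (MC se 0.0010, n = 200000)
```

Reading: the SDR emulation estimates a 7.6-point mortality reduction for
the dynamic corticosteroid regime (truth for this process: −6.6 points,
risks 29.5% vs 36.1%). Design A — exposure defined as treatment *anytime*
during hospitalization — returns a hazard ratio of 0.54: the immortal time
between hypoxia and treatment manufactures spurious protection far beyond
the real effect, while the 1-day-window design (B) sits closer to the
truth and the time-varying Cox model (J) remains confounded by
treatment-severity feedback.

A thin command-line wrapper is installed at `inst/cli/emulate.R` with
subcommands `simulate | estimate | model-first | describe | experiment`;
cohorts travel as delimited text (`write_cohort()` / `read_cohort()`),
configurations as YAML, and replicated experiments produce a `results/` +
`logs/` bundle via `run_experiment()`.

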