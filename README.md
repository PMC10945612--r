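# pursuitrisk

Pre-season risk modelling for significantly symptomatic sports concussion,
built around attention-dependent smooth-pursuit eye movement.

Athletic pre-season (baseline) batteries collect demographics, injury
history, cognitive scores, symptom questionnaires and — in the paradigm this
package models — circular-pursuit eye tracking: the athlete follows a dot
moving on a circle of 10° radius at 0.4 Hz, recorded at 500 Hz. The
question is whether any of these baseline measures predict which athletes
will still carry a *significant symptom burden* (BISQ attention-memory
factor score ≥ 0.53) when tested within two weeks of a subsequent
concussion. Because such cohorts are rare-outcome (a few percent concussed,
~1% symptomatic) and the raw data are not public, the package ships a
first-class synthetic-data module that generates gaze traces and athlete
cohorts with the study's stated structure, so the entire pipeline is
testable end to end.

The package is for biostatisticians and concussion researchers who want a
transparent, fully tested reference implementation of the dual modelling
workflow:

1. **Oculometrics** — automated record screening (>10% missing data,
   calibration artifacts, head instability) and six pursuit performance
   metrics: SDs of radial and tangential gaze positional error, mean signed
   radial error, mean phase lead/lag, and horizontal/vertical pursuit gains
   (slope of desaccaded eye velocity on target velocity).
2. **Traditional arm** — five construct-domain multiple logistic
   regressions (demographics/history, pursuit, cognitive, concussion
   symptoms, psychological/mood) with Wald *p* < 0.10 retention, feeding a
   summary model over the retained union after adult/youth scale
   harmonization.
3. **Penalized arm** — elastic-net logistic regression
   (mixing weight α, default 0.5) on a 70/30 train/test split with tenfold
   cross-validation and BIC/deviance-ratio lambda selection, refit by plain
   maximum likelihood.
4. **Comparison** — McFadden pseudo R², ROC AUC (rank-based with midrank
   ties), misclassification, deviance ratio.

Both statistical engines are implemented from first principles and verified
against independent references in the test suite:

* logistic ML fitting by IRLS with Wald inference
  (`B`, `SE`, `OR = exp(B)`, 95% CI `exp(B ± 1.96·SE)`, LR χ², McFadden
  pseudo R² `1 − ℓ/ℓ₀`), and
* elastic-net coordinate descent minimizing
  `deviance/(2n) + λ·(α‖β‖₁ + (1−α)/2·‖β‖₂²)`
  on an internally standardized design with an unpenalized intercept,
  warm-started along a descending log-spaced λ path, with per-λ BIC
  `deviance + k·ln(n)` and deviance ratio `1 − deviance/null deviance`.

## Worked example

```r
library(pursuitrisk)

# simulate an imperfect tracker: gains < 1, 6 degrees of phase lag, noise,
# saccades, blinks -- then recover the metrics
trace <- simulate_gaze_trace(
  target_trajectory(radius = 10, frequency = 0.4, duration = 30),
  gaze_sim_params(gain_h = 0.92, gain_v = 0.88, phase_offset = -6,
                  radial_noise_sd = 0.4, tangential_noise_sd = 0.5,
                  saccade_rate = 0.8, missing_fraction = 0.05, seed = 7))
compute_pursuit_metrics(trace)
#> Pursuit metrics: SD radial 0.427, SD tangential 0.528 deg
#>   mean radial error -1.042 deg, mean phase -5.99 deg (lag)
#>   gain H 0.905, gain V 0.872

# an enriched cohort (higher concussion rate than the 2.9% default, for a
# compact example), assembled and pushed through the traditional arm
cohort <- simulate_cohort(cohort_config(n_athletes = 6000,
                                        concussion_rate = 0.15, seed = 42))
sample <- assemble_analysis_sample(cohort)
sample
#> Analysis sample: 6000 baseline-tested, 897 concussed
#>   5 excluded (late testing), 892 evaluated in window
#>   367 significantly symptomatic, 525 resolved (dropped)
#>   final sample: 5470 (367 cases, 5103 controls)

run_selection(sample)
#> Domain demographics_history   n =  5470, retained: age, prior_head_injury
#> Domain pursuit                n =  3995, retained: (none)
#> Domain cognitive              n =  5342, retained: srt_rt_sd, trails_a_errors
#> Domain concussion_symptoms    n =  5352, retained: rpq_noise, rpq_sleep, rpq_concentration
#> Domain psych_mood             n =  5363, retained: caars_inattention, caars_impulsivity, conners3_inattention
#>
#> Summary model over 9 retained variables:
#> Logistic model: 2931 obs (163 events), chi2[9] = 49.90, p = 1.13e-07, pseudo R2 = 0.040
#>   ...                 B      SE  p_value odds_ratio ...
#>   prior_head_injury  0.64000 0.16600 0.000116      1.900
#>   adhd_inattention_t 0.02240 0.00804 0.005360      1.020
#>   ...
```

The trace metrics read back the simulation knobs (gain ~0.9, ~6° lag, a
mean radial error of about `10·0.9 − 10 = −1°` from under-scaled tracking),
and the selection recovers the planted cohort effects (prior head injury,
age, inattention, noise/sleep symptoms) alongside the occasional
false-positive retention that the *p* < 0.10 rule is expected to admit.

The elastic-net arm runs analogously — see `?enet_path_select` and
`?refit_selected`; `compare_models()` produces the side-by-side report.

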