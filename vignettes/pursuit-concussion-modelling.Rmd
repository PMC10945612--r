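---
title: "Modelling pre-season risk of symptomatic sports concussion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pre-season risk of symptomatic sports concussion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitrisk)
```

This vignette is the package's account of its science: what is being
modelled, the assumptions behind each stage, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open.

## The problem

A significant acute symptom burden after a sports concussion is defined
here by the BISQ attention-memory factor — a mean frequency score (0–3)
over 28 common post-concussion symptoms — at or above a cutoff of 0.53.
The modelling question is prognostic: which *pre-season baseline*
measures distinguish athletes who, once concussed, will still carry such a
burden when tested within 14 days of injury, from athletes who were never
concussed. Resolved concussed athletes (evaluated in the window but below
the cutoff) are excluded from the modelling sample rather than pooled with
controls, since they are neither cases nor clean never-concussed controls.

Two modelling arms are run in parallel on the same analysis sample:

* a **sequential** arm — five construct-domain multiple logistic
  regressions whose candidates are retained at Wald $p < 0.10$, feeding a
  single summary model; and
* a **penalized** arm — an elastic-net logistic regression over the full
  candidate set, with the selected support refit by plain maximum
  likelihood.

## Circular-pursuit oculometrics

### Stimulus and frames

The stimulus is a dot on a circle (default radius $r = 10^\circ$ of visual
angle, frequency $f = 0.4$ Hz, sampling 500 Hz). For a gaze sample $g$ and
target position $T(\theta)$, the error $e = g - T$ is decomposed onto the
unit radial vector at the target's polar angle (positive = outside the
circle) and the unit tangential vector along the direction of motion
(positive = ahead of the target). The phase error is the wrapped
difference of the polar angles of gaze and target, signed so that positive
means a lead; a pure tracking delay $\tau$ at frequency $f$ appears as a
lag of $360 f \tau$ degrees (50 ms at 0.4 Hz = 7.2°). All signed
quantities are anchored to the motion, so mirroring the scene (which flips
the nominal rotation direction) leaves every metric unchanged — a property
the test suite checks explicitly.

### Screening

Records pass an automated screen before metrics are computed:

* missing data: invalid-sample fraction strictly greater than 0.10 fails
  the record. The boundary is strict, so exactly 10.0% passes.
* calibration artifact: the magnitude of the mean gaze-minus-target vector
  exceeds 3°. This is a package default standing in for an unquantified
  rule; it is configurable and documented as such, not a reference value.
* head instability: the 200-ms running median of gaze-minus-target
  position jumps by more than 5° across one window width — again a
  configurable proxy for an unquantified criterion.

### Velocity, saccades and gains

Gaze velocity is a Savitzky–Golay local-polynomial derivative (window 21
samples = 42 ms, order 2), applied per run of consecutive valid samples;
missing runs are never interpolated. The window was chosen for low phase
distortion at 500 Hz; its only visible cost is a sub-0.1% attenuation of
the 0.4 Hz component, which is why the identity-tracking gain reads
0.9997 rather than 1.0000.

Saccades are runs where smoothed gaze speed strictly exceeds 50°/s
(perfect pursuit of the default target runs at $2\pi r f \approx
25.1$°/s), padded by ±10 ms and merged when overlapping. A relative guard
of $10^{-9}$ on the comparison keeps a plateau exactly at the threshold
from being flagged through floating-point jitter. Because the derivative
filter spreads saccadic velocity half a window beyond the detected
interval, the gain fit excludes a further half-window margin around
saccadic samples.

The six metrics are computed over valid, non-saccadic samples: SDs of
radial and tangential error; the mean *signed* radial error (an absolute
variant is available by option, since either reading of "average radial
error" is defensible); the circular mean of the phase error; and per-axis
gains as the least-squares slope through the origin of eye velocity on
target velocity — a velocity-ratio definition, not a position-amplitude
ratio. SDs are computed after desaccading by default (also toggleable).
Records with under 1 s of usable samples after desaccading raise an error
rather than returning unstable statistics.

## The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
ground truth; its defaults are the study conditions, not tuning knobs.

**Gaze traces.** The smooth component is the target rotated along its
circle by a phase offset and scaled per axis by the gains; Gaussian noise
is added in the radial/tangential frame; saccades are out-and-back
ballistic excursions (default 2° amplitude at 150–300°/s, i.e. ~20 ms);
missingness is injected as contiguous blink-like runs of 100–300 ms
totalling the requested fraction. Everything is a pure function of the
seed.

**Cohorts.** One row per athlete with marginals matching the reference
sample: age 18.6 (SD 3.0) years on 12–30 — drawn from a truncated normal
whose *truncated* mean equals the configured mean, undoing the asymmetric
truncation bias — 62% male, 53% Caucasian, 27.5% prior head injury, and a
2.9% concussion incidence. Concussion assignment is independent of the
covariates; among concussed athletes a latent symptomatic state is drawn
from a logistic model whose default log-odds are the summary-model effect
sizes (prior head injury OR 3.15, SD radial OR 2.55 per degree, inattention
OR 1.035 per T point, age OR 0.875 per year, plus the smaller RPQ item and
anxiety effects), with the intercept solved so the marginal symptomatic
rate among concussed is 0.39. The BISQ score is then generated on the side
of the 0.53 cutoff dictated by the latent state (shifted beta variates;
a `bisq_fidelity` below 1 allows misclassification). Days to testing are
truncated normal with mean 5.8 and SD 3.5 on [0, 16] — the upper bound is a
package choice that lets a small fraction of assessments fall outside the
14-day window, as happens in practice; the true delay distribution is not
known beyond its moments and range. Block-wise missingness is missing
completely at random; the pursuit block defaults to a 26.6% technical
failure rate, mirroring how often eye records fail screening in practice.

Two things follow from this construction and matter for interpretation.
First, case status in the analysis sample (symptomatic-concussed vs
never-concussed) is a *composition* of the concussion draw and the latent
logistic, so refitting case status on the covariates recovers attenuated
versions of the latent coefficients — the generator's fidelity is
therefore tested on the latent model itself (symptomatic vs resolved among
concussed), where the coefficients are recovered within sampling error.
Second, the generator emulates marginals and one planted outcome
mechanism, not real data: covariates are mutually independent, instruments
have no item structure, and missingness is MCAR. Passing tests show the
*pipeline* is correct and calibrated, not that real cohorts behave this
way.

**Participant-flow fixture.** A deterministic cohort reproducing the
reference flow exactly: 3091 baseline-tested, 90 concussed, exactly one
assessed after day 14, and a 35/54 symptomatic/resolved split among the 89
evaluated, for a final sample of 3036. Group-wise marginals (age means,
prior head injury 27.5% vs 51.4%, and the other categorical rows) are
baked in by deterministic rounding. Testing delays of the evaluated
athletes form a fixed multiset on [0, 14] with mean exactly 5.8; since
$89 \times 5.8 = 516.2$ is not an integer, the multiset is 88 integers
plus a single tenth-precision value — an all-integer multiset with that
mean does not exist. Ages and delays are assigned through a fixed stride
permutation so that row order (and hence group membership) carries no
spurious age or delay trend. A `scale` argument shrinks all counts
proportionally (rounding half up) for fast tests. No random number is
drawn anywhere in the fixture.

## The logistic core

`fit_logistic()` is a from-scratch IRLS implementation: weighted
least-squares updates until the deviance changes by less than $10^{-8}$
(or 100 iterations), standard errors from the inverse Fisher information
at the optimum, Wald $z$ tests, odds ratios with 95% CIs at $z = 1.96$.
The score equations $X^\top(y - \hat p) = 0$ hold at convergence to
machine-level tolerance, which also forces the mean fitted probability to
equal the event rate. Coefficients exceeding 15 in absolute value raise a
separation error: IRLS on separated data inflates coefficients by roughly
one unit per iteration while the deviance change shrinks like
$e^{-|B|}$, so a plain deviance criterion would otherwise "converge" to a
meaningless optimum near $|B| \approx 22$.

The pseudo R² is McFadden's $1 - \ell/\ell_0$ by default; Nagelkerke's
variant is available by option because reported pseudo R² values in the
applied literature are rarely attributable to a specific definition
(different major packages default differently). No small-sample or
rare-event (Firth) correction is applied, matching plain ML practice.

## Sequential selection

Each domain model is a *multiple* logistic regression over its candidate
list, fitted on domain-wise complete cases — athletes lacking eye records
are dropped from the pursuit domain only, not from the other domains.
Candidates with Wald $p$ strictly below 0.10 are retained; the threshold
is deliberately liberal (type II error is the expensive mistake at the
selection stage) and strict at the boundary. Retention is monotone in the
threshold, and under the null the rule retains close to 10% of candidates
— both properties are under test.

The psychological/mood domain is special: adult (BAI, CES-D, CAARS) and
youth (BAI-Y, BDI-Y, Conners 3) instruments are mutually exclusive per
athlete, so a single complete-case fit over all fourteen candidates would
be empty by construction. The domain is therefore fitted per instrument
stratum and the retained lists pooled. For the summary model, retained
anxiety measures map to `anxiety_z` (within-stratum standardization —
instrument norm tables are proprietary, so within-sample Z is used) and
retained inattention subscales map to `adhd_inattention_t` (both
instruments' inattention scales are T-scored). Other stratum-bound
retentions cannot be pooled; if they arrive from one stratum only, the
summary model is fitted on that stratum's complete cases, and if they
arrive from both (making the complete-case intersection empty) they are
dropped from the summary model with an explicit note. Retained variables
stay in the summary model regardless of their summary-model $p$ values.

## Elastic net

The objective is
$\frac{1}{2n}\,\mathrm{deviance}(\beta_0, \beta) + \lambda\big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\big)$
with the intercept unpenalized and covariates standardized internally to
unit (1/n) SD; reported coefficients are back-transformed to the original
scale. The solver is cyclic coordinate descent on the IRLS quadratic
approximation (compiled inner loop with an active-set strategy),
converged when the largest standardized-coefficient change falls below
$10^{-7}$; standardized coefficients below $10^{-10}$ are snapped to
exact zero so that support sizes are well defined at the top of the path.
The path starts at $\lambda_{\max} = \max_j |x_j^\top(y - \bar y)|/(n\alpha)$
— the exact threshold at which the null model is stationary — and descends
over 100 log-spaced values to $10^{-4}\lambda_{\max}$, warm-started. KKT
stationarity residuals are computed for every fit and exposed, and the
suite verifies them against $10^{-6}$ alongside agreement with an
independent penalized-regression reference and the unpenalized MLE in the
vanishing-penalty limit.

**Lambda selection.** Three criteria are in play — tenfold CV, BIC and
the in-sample deviance ratio — and they do not combine on their own:
maximizing the deviance ratio alone always drives $\lambda \to 0$. The
rule implemented is: restrict to the subpath whose CV deviance is within
one standard error of the CV minimum, pick the BIC minimizer there, and
break ties toward the larger $\lambda$. BIC is
$\mathrm{deviance} + k\ln(n_\text{train})$ with $k$ counting nonzero
coefficients *including* the intercept — stated explicitly because
penalized-model BIC conventions vary — and the whole per-$\lambda$ table
(deviance, deviance ratio, BIC, CV deviance and SE, support size) is
always emitted so alternative rules can be applied downstream. The
deviance ratio is reported, never optimized. A consequence worth stating
plainly: at a rare-outcome scale (tens of events in the training split)
the $k\ln n$ penalty is close to the deviance reduction even of genuine
effects, and the rule can honestly select the intercept-only model; the
path object flags this instead of manufacturing a support.

The 70/30 split is simple random by default, matching standard practice;
a stratified option is provided (and used where a handful of events could
otherwise land entirely in one part). Complete-case filtering happens
before splitting. The selected support is refit by plain ML on the full
analysis sample via the logistic core.

## Evaluation

AUC is the Mann–Whitney statistic with midrank ties, computed in-sample on
the full analysis sample for both arms — the comparison is of fitted
models' logits, not of cross-validated predictions. Misclassification is
reported at the 0.5 probability threshold (under a ~1% event rate this
equals the base rate, with everything predicted negative — which is why
the prevalence-threshold variant is reported alongside) and the deviance
ratio and McFadden R² complete the report. The auxiliary checks use the
standard implementations: a pooled-variance two-sample $t$ (degrees of
freedom $n_1 + n_2 - 2$, matching the reported style) for days-to-testing
between symptomatic and resolved athletes and for SD radial by prior head
injury, OLS for the BISQ-on-delay slope, and Pearson correlation for SD
radial against baseline sleep complaints.

## Problem sizes and numerical conventions

The test and acceptance workloads use sizes chosen to give tight Monte
Carlo error at desk scale: coverage of 95% Wald intervals over 600
simulated cohorts of $n = 500$ with ~150 events each; null retention over
1000 domain fits of $n = 300$; sparse-support recovery over 100 replicates
of $n = 600$, 25 candidates, 5 planted signals and ≥150 events; pursuit
metric recovery on 30 s traces at 500 Hz. The demonstration pipeline in
`scripts/acceptance.R` runs at the study's own conditions (3091 athletes,
2.9% concussion incidence).

Numerical conventions collected in one place: strict inequalities at the
0.10 missingness and 50°/s saccade boundaries (the latter with a
$10^{-9}$ relative guard); the inclusive boundary at the 0.53 BISQ cutoff;
IRLS deviance tolerance $10^{-8}$; coordinate-descent coefficient
tolerance $10^{-7}$ with $10^{-10}$ zero-snapping; separation guard at
$|B| > 15$; CI multiplier 1.96; λ-selection ties toward the larger λ.

## Limitations

* The generator's covariates are independent; real baseline batteries are
  strongly intercorrelated, which is precisely the regime where elastic
  net should outperform sequential selection most clearly. The comparison
  here validates correctness and calibration, not that advantage.
* Screening proxies for calibration quality and head stability are
  package defaults, not validated against tracker hardware.
* Binocular recordings are modelled as a single cyclopean stream; no
  disparity, pupil or latency metrics are computed.
* Harmonization uses within-sample standardization, so harmonized scores
  are sample-relative rather than norm-referenced.
* No inference-after-selection correction is applied in either arm; the
  summary-model $p$ values inherit the usual post-selection optimism.
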