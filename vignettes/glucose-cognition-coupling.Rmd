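---
title: "Modeling dynamic glucose-cognition coupling in type 1 diabetes"
author: "glucocog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dynamic glucose-cognition coupling in type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucocog)
```

## The scientific problem

People with type 1 diabetes (T1D) experience large, frequent glucose
fluctuations. Laboratory work shows cognition degrades in both hypoglycemia
and hyperglycemia, but how moment-to-moment glucose variation couples with
moment-to-moment cognitive variation in daily life is much harder to
measure. Two technologies make it tractable: continuous glucose monitoring
(CGM), which samples interstitial glucose about every 5 minutes, and
cognitive ecological momentary assessment (EMA), in which participants
complete ultra-brief smartphone tasks several times a day — here a
digit-symbol matching task (DSM; processing speed, scored as number correct
in 30 s and median correct-response reaction time) and a gradual-onset
go/no-go task (GCPT; sustained attention, scored as d-prime and median
correct-response RT).

`glucocog` implements the full analysis pipeline for such a study —
preprocessing and quality control, a hierarchical Bayesian model of
within-person glucose-cognition coupling, practical-equivalence testing of
individual differences, localization of glucose levels associated with
optimal performance, and data-driven screening of person-level
characteristics that predict individual vulnerability — together with a
synthetic-study generator with known ground truth, so that every stage is
testable without access to any participant data.

## The model

Let $Y_{ij}$ be the cognitive score of person $j$ at EMA session $i$, and
$g_{ij}$ the person's glucose just before the session, centered at the
person's mean and scaled by the person's SD. The model is a random
quadratic-slope hierarchical regression:

$$
Y_{ij} = (\gamma_{00} + u_{0j}) + (\gamma_{10} + u_{1j})\, g_{ij}
       + (\gamma_{20} + u_{2j})\, g_{ij}^2 + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim \mathcal N(0, \sigma_\varepsilon^2),
$$

with $(u_{0j}, u_{1j}, u_{2j})$ multivariate normal with a full $3\times 3$
covariance. The quadratic terms are the quantity of interest: for RT
outcomes a positive $\gamma_{20}$ means slowing at both low and high
glucose (a U-shape), and the person-specific deviation $u_{2j}$ — "cognitive
vulnerability to glucose fluctuations" — quantifies how much more or less
curved person $j$'s response is than the group's.

In practice the two glucose terms are near-collinear, so fitting uses
orthogonal quadratic polynomials: an intercept plus two zero-mean,
unit-norm, mutually orthogonal columns built by QR over the included rows
(`build_model_frame()`). Coefficients on this basis are not in
per-glucose-SD units; the frame retains the affine map between bases, and
every summary can be reported on either (`basis = "orthogonal"` or
`"raw"`). Before basis construction, rows whose squared scaled glucose lies
more than 3 SDs from the pooled mean of squared scaled glucose are excluded
— extreme-leverage sessions that otherwise destabilize sampling.

### Priors and sampling

The sampler is JAGS (Gibbs sampling with hierarchical centering:
person-level coefficient vectors are drawn around the group coefficients).
Priors are weakly informative at the outcome's own scale, with
$SD_y$ the outcome SD over included rows:

* group coefficients: $\mathcal N(0,\, (2.5\, SD_y)^2)$, intercept centered
  at the outcome mean;
* residual SD: half-exponential with rate $1/SD_y$;
* random-effect covariance: inverse-Wishart with 4 degrees of freedom and
  scale $SD_y^2 I_3$, a conventional conjugate default that keeps all three
  SDs and their correlations jointly flexible at the outcome scale.

Chains are initialized at the pooled least-squares solution, which
stabilizes burn-in and keeps the degenerate zero-residual case (used in
noiseless validation fits) pinned to the deterministic solution. A fit is
flagged `converged` only when the potential scale reduction factor
$\widehat R \le 1.01$ for every monitored parameter; downstream summaries
refuse unconverged fits unless `force = TRUE`. Defaults
(`sampler_control()`: 4 chains, 1000 adaptation, 4000 burn-in, 20000
iterations thinned by 10) reach that gate on cohorts of tens of persons
with tens of sessions each in about a minute; the unit tests use shorter,
smaller-data settings.

### What the model can and cannot identify

On the unit-norm basis, each person's quadratic column carries total
leverage of about $1/J$ ($J$ persons), so the per-person uncertainty of
$u_{2j}$ scales as $\sigma_\varepsilon \sqrt J$. With realistic residual
noise this is large: individual vulnerability estimates are heavily shrunk,
and the random-effect SDs are informed mostly through the dispersion of the
person-level estimates. This is a property of the design, not the software;
it is why individual estimates are reported with 95/90/66% credible
intervals and a certainty class rather than as point values, and why the
equivalence test below is the appropriate population-level summary.

## Equivalence testing and optimal performance

Individual differences are assessed with a region of practical equivalence
(ROPE) on each random-effect SD: the region is $[0,\, 0.2\, SD_y]$, and the
decision is `negligible` when the 95% equal-tailed interval of the SD's
posterior lies inside the region, `meaningful` when entirely outside, and
`undecided` otherwise. Equal-tailed quantile intervals are used throughout
(the highest-density alternative differs negligibly for these unimodal
posteriors and the quantile convention keeps interval nesting exact).

Optimal performance is located by evaluating the expected outcome over a
grid of scaled glucose ($[-4, 4]$ in steps of 0.05) for 1000 posterior
draws, averaging across draws, and taking the minimum (RT) or maximum
(accuracy) of the mean curve — for the group and for each person. The
optimum is reported in person-SD units, converted to mg/dL via the person's
(or the average) glucose SD, and as percent deviation from typical
performance, defined as the expected outcome at the person's glucose mean
($g = 0$). An optimum on the grid boundary is flagged: it means the fitted
parabola opens the wrong way or has its vertex outside the plausible range.
Group optima can be combined across analysis samples as sample-size-weighted
averages (`combine_optima()`).

## Preprocessing and quality control

* **CGM cleaning** (`clean_glucose()`): the first 24 h of each sensor is
  dropped (reduced accuracy during warm-up) and a person is eligible only
  with more than 72 h of remaining coverage.
* **Glycemic metrics** (`glycemic_profile()`): mean, SD, CV
  ($100 \cdot SD/\text{mean}$), and percent of readings in the consensus
  bands — in-range 70–180 mg/dL inclusive, below 70, below 54, above 180,
  above 250 (strict inequalities for the outer bands, so in-range / below-70
  / above-180 partition the readings). Fractions of readings equal
  time-weighted fractions at the fixed 5-minute cadence.
* **Alignment** (`align_glucose_to_ema()`): each session uses the most
  recent reading in the half-open window $[t - 5\text{min}, t)$ before its
  start; a reading exactly at the start is excluded, and sessions with no
  reading in the window contribute no observation.
* **Centering** (`center_scale_within_person()`): person means and SDs are
  computed from the aligned values entering the model, not the full CGM
  stream — the model's "average glucose" is then the average of the modeled
  exposures. A centering-only variant (`scale = FALSE`) supports the
  robustness analysis; on synthetic data the two variants rank persons'
  vulnerability nearly identically.
* **Session QC** (`apply_session_qc()`): sessions are excluded when DSM
  accuracy < 50%, DSM number correct < 6, GCPT omission rate > 50% (strict),
  responses were not registered by touchscreen, or the task did not
  complete; reason codes are exhaustive, and a session is excluded exactly
  when its reason list is non-empty. The accuracy rule uses correct /
  attempted trials.
* **Participant filters** (`apply_participant_filters()`): persons recording
  more than the 45 scheduled sessions (protocol anomaly) or failing QC in at
  least half of possible sessions are excluded outright; analysis samples
  are then defined by kept-session completion at the ≥50%, ≥66% and ≥80%
  cutoffs, and membership is monotone across cutoffs by construction.
  Effects are interpreted only when significant in every completion sample.

Reliability (`estimate_reliability()`) reports between-person reliability
from a random-intercept variance decomposition,
$\sigma^2_p / (\sigma^2_p + \sigma^2_e/\bar T)$, and a split-half
within-person reliability: sessions are scored separately on odd and even
trials, both halves are centered within person, pooled deviations are
correlated and Spearman-Brown adjusted. The split-half estimator is this
package's concrete choice for within-person consistency; other multilevel
generalizability formulations exist and can give somewhat different values.

## Predictor screening

Person-level vulnerability estimates (posterior means of $u_{2j}$) are
regressed on a standardized person-level feature table (58 features by
default: CGM summary metrics, clinical history, demographics) with lasso
regression. In each of 1000 repetitions, 10-fold cross-validation folds are
reassigned at random, the penalty is tuned, the tuned model is refit to the
full data, and nonzero coefficients are recorded; a feature is *robust*
when retained in more than 50% of repetitions in **every** completion
sample. Missing feature entries are imputed once with the column median
(with an audit of imputed counts), and zero-variance columns are dropped.

The penalty is tuned with the one-SE rule rather than the minimum-error
rule. With the data fixed and only folds re-randomized, the minimum-error
penalty can collapse to near zero on datasets where chance correlations
flatten the cross-validation curve; most features are then retained in
nearly every repetition and retention frequency stops discriminating signal
from noise. The one-SE penalty keeps the retained set sparse and makes the
retention-frequency robustness rule meaningful; `rule = "min"` is available
for comparison.

## The synthetic-study generator

Because studies of this kind cannot deposit raw participant data, the
generator (`simulate_population()`, `simulate_glucose_series()`,
`simulate_ema_sessions()`, `simulate_study()`) emulates the full study with
a recorded ground truth (`truth_record`):

* **Cohort**: 200 persons; person glucose means drawn from a truncated
  normal at 182.3 (44.3) mg/dL on [115, 380] and SDs at 65.6 (18.8) on
  [24, 117] — the descriptive scale of a contemporary adult T1D cohort;
  per-person EMA compliance Beta(8, 1.4) (mean ≈ 0.85, a realistic
  completion rate with a small tail below the 50% exclusion cutoff).
* **Glucose**: stationary AR(1) at 5-minute resolution with the person's
  mean and SD and lag-1 autocorrelation 0.95 per step — no published
  generative model exists for CGM traces, and AR(1) at this phi reproduces
  realistic short-horizon smoothness; readings clamp to the 40–400 mg/dL
  sensor range, and the device id switches at day 10 to emulate the
  two-sensor wear protocol.
* **EMA schedule**: 3 prompts/day for 15 days, uniform within the morning
  (9:00–12:59), afternoon (13:00–16:59) and evening (17:00–21:00) windows,
  sessions starting within 30 minutes of the prompt. Timestamps are naive
  local time (the protocol excluded cross-timezone travel).
* **Outcomes**: latent session scores follow the quadratic model at the
  within-person scaled glucose at session start. Defaults place the DSM RT
  vertex 0.72 person-SDs above the glucose mean with a ~0.57% (≈5.4 ms)
  gain over typical performance, at the published descriptive scale of each
  task.
* **Trials**: DSM trial RTs are log-normal around the latent median
  (σ-log 0.25) with 93% trial accuracy; GCPT sessions have 75 trials (60
  city / 15 mountain), with hit and false-alarm probabilities placed
  symmetrically around a response bias of 0.5 on the z-scale so the
  quantile link recovers the latent d-prime. The log-normal RT choice is a
  stand-in — the marginal distribution of real momentary RTs is not
  characterized — so tests against the generator validate the scoring and
  modeling machinery, not distributional realism.
* **Planted predictors**: seven named features (age, time below 70 mg/dL,
  lifetime severe hypoglycemic events, microvascular disease, glucose CV,
  fatigue, neck circumference — the glycemic ones derived from the person's
  true stationary distribution, hence realistically intercorrelated)
  contribute linearly to the DSM RT quadratic deviation $u_{2j}$, giving
  stability selection a recoverable ground truth among 51 null features.

What the generator does **not** emulate: meal/insulin dynamics and
circadian glucose structure, device error models, practice effects, and
any systematic missingness linked to glycemic state. Passing tests
therefore demonstrate the statistical machinery is correct under the
declared data-generating process, not that real data meet its assumptions.

## Validation experiments and problem sizes

The package's end-to-end checks (in `tests/testthat/test-acceptance.R`,
recomputed by `scripts/acceptance.R`) use problem sizes chosen to be
informative yet quick:

* *Parameter recovery*: 60 persons × 30 sessions simulated at a published
  coefficient scale for a momentary RT outcome (group coefficients ≈ (955,
  −373, 261) on the model basis, random-effect SDs ≈ (224, 312, 238),
  residual ≈ 125 ms); group coefficients must be recovered within 15%
  relative error or 2 posterior SDs, with $\widehat R \le 1.01$. At these
  study conditions the per-observation quadratic signal is only a few ms
  against a 125 ms residual, so the posterior-SD branch is the binding one
  — a faithful reflection of how subtle these effects are.
* *Vertex localization*: a noiseless cohort with raw-basis vertex at +0.72
  scaled glucose; the grid optimum must land within one grid step.
* *Equivalence discrimination*: 50 persons × 30 sessions with small
  residual SD (5 outcome units) so the curvature SD is identified (the
  $\sigma_\varepsilon\sqrt J$ floor sits well inside the ROPE); with zero
  generating curvature SD the decision must not be "meaningful", with
  curvature SD at half the outcome SD it must be.
* *Selection recovery*: 190 persons, 58 features, 7 planted coefficients of
  1.5 (each ≈9% of outcome variance, base curvature SD 2), 200 repetitions
  per completion sample: all 7 must exceed 50% retention everywhere while
  median null retention stays below 50%.

## Known limitations

* The inverse-Wishart prior ties the scale of all three random-effect SDs
  together and bounds the posterior away from zero more strongly than a
  half-t/LKJ formulation would; with weakly identified SDs the ROPE
  decision therefore tends to "undecided" rather than "negligible".
* Per-person vulnerability estimates are strongly shrunk at realistic noise
  levels; rank orderings are informative, absolute values less so.
* The completion-cutoff samples are nested, so cross-cutoff consistency is
  a robustness device rather than independent replication.
* A single median imputation pass is used for missing features; repetition-
  level re-imputation would propagate imputation uncertainty into retention
  frequencies.

## A minimal run

```{r, eval = FALSE}
cfg <- study_config(n_persons = 40,
                    sampler = sampler_control(chains = 2, adapt = 500,
                                              burnin = 1000, iter = 8000,
                                              thin = 4),
                    selection = list(repetitions = 100, folds = 10))
report <- run_pipeline(cfg, seed = 1, outcomes = "dsm_rt",
                       out_dir = "glucocog-out")
report$consistency
report$optima_combined
report$robust
```
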