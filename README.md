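# glucocog

Dynamic within-person coupling of glucose and cognition in type 1 diabetes
(T1D), as a tested, reusable R pipeline.

People with T1D experience frequent swings into hypo- and hyperglycemia,
and laboratory studies show cognition suffers at both extremes. Combining
continuous glucose monitoring (CGM, a reading every ~5 minutes) with
cognitive ecological momentary assessment (EMA, ultra-brief smartphone
tasks 3×/day) makes it possible to ask *when* and *for whom* naturally
occurring glucose fluctuations impair cognition. `glucocog` implements the
full analysis for such a study, for biostatisticians and digital-health
researchers working with intensive longitudinal data:

* **CGM preprocessing** — sensor warm-up exclusion, coverage eligibility,
  glycemic summary metrics (mean, SD, CV, time in range / below 70 / below
  54 / above 180 / above 250 mg/dL), and time-alignment of readings to EMA
  sessions (most recent reading 0–5 minutes before session start).
* **EMA scoring and QC** — digit-symbol matching (number correct in 30 s,
  median correct-response RT) and go/no-go scoring (d′ via the
  standard-normal quantile link with log-linear correction, omission rate,
  median RT), session-level effort rules, participant-level completion
  filters at the ≥50/≥66/≥80% cutoffs, and multilevel reliability.
* **The hierarchical model** — cognition on within-person centered and
  scaled glucose with orthogonal quadratic polynomials and correlated
  person random effects:

  $$Y_{ij} = (\gamma_{00}+u_{0j}) + (\gamma_{10}+u_{1j})g_{ij} +
    (\gamma_{20}+u_{2j})g_{ij}^2 + \varepsilon_{ij}$$

  The person-specific curvature $\gamma_{20}+u_{2j}$ is "cognitive
  vulnerability to glucose fluctuations". Fitting uses MCMC (JAGS) with an
  $\widehat R \le 1.01$ convergence gate; summaries include credible-
  interval significance, ROPE practical-equivalence tests of the
  random-effect SDs ($[0,\ 0.2\,SD_y]$), and grid-based localization of the
  glucose level associated with optimal performance.
* **Predictor screening** — repeated cross-validated lasso over a
  standardized 58-feature person-level table, with features called robust
  when retained in >50% of repetitions at every completion cutoff.
* **A synthetic-study generator** — AR(1) glucose streams, EMA schedules
  with partial compliance, trial-level task records generated from latent
  scores, and a feature table with planted effects, all recorded in a
  ground-truth object so every stage is testable end to end.

## Worked example

A small synthetic cohort through the whole pipeline (simulate → clean →
score → QC → align → fit → optima):

```r
library(glucocog)
cfg <- study_config(n_persons = 30,
                    sampler = sampler_control(chains = 2, adapt = 500,
                                              burnin = 1000, iter = 8000,
                                              thin = 4),
                    selection = list(repetitions = 50, folds = 5))
report <- run_pipeline(cfg, seed = 1, outcomes = "dsm_rt", force = TRUE)
report
```

```
Pipeline report
  aligned observations: 1059 
  analysis sample sizes: cutoff_0.5=30, cutoff_0.66=28, cutoff_0.8=22 
 outcome      term significant_all_cutoffs
  dsm_rt   glucose                    TRUE
  dsm_rt glucose^2                    TRUE
```

The quadratic glucose term is significant in every completion sample:
reaction time rises at both low and high within-person glucose. The
coefficient rows for the ≥66% sample (orthogonal fitting basis; `basis =
"raw"` in `summarize_group_effects()` converts to per-glucose-SD units):

```
 outcome cutoff        term estimate     se    cil    ciu significant
  dsm_rt   0.66 (Intercept)    943.6  37.77  869.9 1017.5        TRUE
  dsm_rt   0.66     glucose   -443.0 143.85 -722.3 -153.5        TRUE
  dsm_rt   0.66   glucose^2    433.2 142.94  155.5  722.0        TRUE
```

and the sample-size-weighted optimum across cutoffs:

```r
report$optima_combined
```

```
 outcome glucose_star_scaled glucose_star_mgdl performance_at_star
  dsm_rt               0.564              36.6                 918
 typical_performance pct_deviation_from_typical
                 922                     -0.453
```

Optimal (fastest) responding occurs about 0.56 person-SDs (~37 mg/dL)
above the person's average glucose, about 0.45% (~4 ms) faster than
typical performance — the generator plants the vertex at +0.72 SD with a
0.57% gain, and a 30-person cohort recovers it to within sampling error.

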