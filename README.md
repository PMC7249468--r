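# bbbclear

Blood–brain barrier integrity and brain biomarker clearance in
longitudinal CSF/blood monitoring data.

## The problem

After severe traumatic brain injury (TBI), brain-enriched proteins such as
**S100B** (astrocytic, ~9–14 kDa) and **NSE** (neuron-specific enolase,
~39 kDa) leak from injured tissue into cerebrospinal fluid and, with some
delay, into blood. *How* they get to blood is unresolved: passage across a
disrupted blood–brain barrier (BBB) is one route; barrier-independent
routes (e.g. glymphatic/lymphatic drainage) are another. The distinction
matters for anyone interpreting a blood biomarker level at the bedside.

Barrier integrity is measured by the albumin quotient

```
Q_A = albumin_CSF / albumin_blood        (CSF in mg/L, blood in g/L)
```

since albumin has no intracranial source, an elevated Q_A means a leaky
barrier. In a neurocritical-care unit with an external ventricular drain,
CSF and blood can be sampled every 6–12 h for a week, giving
multi-compartment time series per patient: biomarker in CSF, biomarker in
blood, and Q_A.

`bbbclear` implements the full longitudinal analysis for such data, plus a
mechanistic synthetic-cohort generator so every stage can be verified at
desk scale:

* **Data model** — long-format ingestion with unit normalisation, Q_A
  computation, age-banded reference flagging, cohort summaries
  (median/IQR, count/%), and the Fisher-z power calculation for detecting
  a target correlation.
* **Alignment** — linear interpolation of multi-rate series onto a common
  within-subject grid (never extrapolating), complete-case filtering,
  log10 transforms, half-open 12-h lag binning, and the first-12-h
  exclusion that guards S100B against its extracranial (multitrauma) peak.
* **Correlation** — repeated-measures ("momentary") correlation via the
  common-slope ANCOVA decomposition, and per-patient lagged
  cross-correlation on original-scale 12-h bins, pooled across patients
  with t-intervals; peak-lag comparison across the three pairs
  (CSF→Q_A, Q_A→blood, CSF→blood) yields a verdict on whether the
  CSF-to-blood delay is barrier-mediated.
* **Longitudinal models** — marginal GLS and linear mixed models
  (random intercept + slope) of log10 blood biomarker on time, time²,
  log10 CSF level and log10 Q_A, with ARMA(p,q) within-patient
  correlation; KPSS stationarity screening, AIC structure selection over
  25 (p,q) candidates, likelihood-ratio and sequential F tests, and
  Satterthwaite degrees of freedom.
* **Synthetic cohorts** — a seeded two-compartment generator: CSF decays
  exponentially; barrier disruption (per-subject, ~half the cohort)
  follows its own trajectory; blood is fed by a Q_A-proportional route
  and/or a delayed barrier-independent route and eliminated first-order;
  observations follow realistic 6 h/12 h schedules with lognormal assay
  noise and CSF pooling windows.

## A worked example

```r
library(bbbclear)

# How many patients does a study need to detect a CSF:blood correlation of
# 0.60 with 80% power (one-sided, alpha = 0.05)?
required_sample_size(r = 0.60, power = 0.80, alpha = 0.05)
#> [1] 15

# Simulate an S100B-like cohort (barrier-dependent clearance, 12 h
# transport delay) and run the whole pipeline:
cfg <- run_config(profile = "S100B_like", n = 16, seed = 1,
                  out_dir = "s100b_run")
res <- run_pipeline(cfg)
res$attribution
#> Lag attribution: bbb_mediated
#>   peaks: CSF:Q_A 0, Q_A:blood 1, CSF:blood 1
```

The peaks are in 12-h lags: blood S100B trails CSF S100B by one lag
(~12 h), and trails the barrier signal by the same lag, so the delay is
attributed to passage across the disrupted barrier — `bbb_mediated`. An
NSE-like cohort (`profile = "NSE_like"`: barrier-independent route, 24 h
delay) instead gives CSF:blood peak 2 with Q_A:blood peak 0 and verdict
`not_bbb_mediated`. The run directory contains the measurement and lag
tables, pooled cross-correlations, the fitted clearance-model table with
Satterthwaite p-values, a markdown report and a reproducibility manifest.

```r
res$final$beta[, c("term", "estimate", "p_satt")]
#>   term        estimate  p_satt
#> 1 (Intercept)  -0.352   0.29
#> 2 time_d       -0.185   1.2e-07
#> 3 time_d2      -0.0373  8.3e-06
#> 4 csf          -0.0528  0.72
#> 5 qa            0.362   0.014
```

Here `qa` (log10 albumin quotient) is retained at the 5% level: in this
cohort the barrier state independently predicts blood S100B, as the
generating model says it should.

A thin command-line wrapper ships in `inst/scripts/bbbclear`
(`simulate`, `run`, `power` subcommands).

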