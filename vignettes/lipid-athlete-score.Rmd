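---
title: "Methods: the lipid athlete score, its cut-off machinery and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lipid athlete score, its cut-off machinery and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscore)
```

## The screening problem

Competitive athletes fall outside the validity range of the standard
cardiovascular risk calculators: those are built for the over-40 general
population and ignore physical fitness, while athlete cohorts are young,
lean, and screened annually with a full fasting lipid panel. In that
setting dyslipidemia is the most prevalent modifiable risk factor, and the
operational questions are (i) which lipid abnormality definitions to apply,
(ii) where to place an athlete-specific cut-off on the LDL/HDL atherogenic
index, and (iii) how to combine lipid and host factors into an actionable
risk tier. `lipidscore` implements all three stages plus a calibrated
synthetic cohort so the pipeline is fully testable without individual-level
athlete data, which are not publicly available.

## Risk-factor definitions and boundary conventions

`classify_risk_factors()` evaluates, per record: BMI (weight/height²),
Mosteller body surface area (√(height·weight/3600)), waist/hip and LDL/HDL
ratios, and the boolean screening flags. Two dyslipidemia definitions
coexist deliberately:

* *original*: LDL ≥ 115 mg/dL, or HDL < 40 (male) / < 50 (female) mg/dL,
  or LDL/HDL > 2.78;
* *revised*: LDL ≥ 115 mg/dL or LDL/HDL ≥ 1.90.

Boundary conventions follow the printed inequality symbols of the source
definitions rather than a uniform convention: LDL and the new ratio
cut-off are inclusive, the old ratio cut-off, triglycerides (> 150
mg/dL), waist (> 94/80 cm) and fat-mass (> 22 %/32 %) limits are strict.
Every threshold lives in `threshold_config()` and can be changed; the
defaults are the screening values above. Since the new ratio cut-off is
below the old one, the revised definition differs from the original
exactly by (a) adding the ratio band [1.90, 2.78] among athletes with
normal LDL and HDL and (b) dropping the isolated-low-HDL athletes; the
test suite asserts this set identity on every cohort it touches.

Two distinct adiposity notions exist on purpose: the *overweight*
risk-factor flag is waist-based (waist above the sex limit, or BMI > 30)
to avoid misclassifying muscular athletes, while the score's *adiposity
minor criterion* is BMI-or-fat-mass based (below). Hypertension and
diabetes are taken from the recorded clinical history; numeric
blood-pressure and glucose fields are not part of the record schema
because athlete screening histories, not raw measurements, define these
factors in practice (the configured 140/90 mmHg and 126 mg/dL limits are
retained in `threshold_config()` for completeness).

Records lacking LDL or HDL are never silently zero-filled: they classify
as `NA` and are excluded from scoring and cut-off analysis by
`eligible_records()`, together with athletes on lipid-lowering therapy.

## Maximum-efficiency cut-point selection

`max_efficiency_cutoff()` chooses, for the decision rule "positive if
marker ≥ t", the threshold maximising *efficiency* — the overall
proportion correctly classified, (TP + TN)/N. Candidate thresholds are the
observed unique marker values plus a `+Inf` sentinel representing the
call-nobody-positive rule; the sentinel guarantees the chosen efficiency
never falls below the majority-class rate, while the tie-break toward the
*smallest* qualifying threshold (which maximises sensitivity at equal
efficiency, configurable to `"largest"`) keeps the reported cut-off at an
attainable observed value whenever one is equally efficient. The
`roc_auc()` AUC is the Mann–Whitney probability that a random positive
outranks a random negative (ties counted half), which equals the
trapezoidal area under the empirical ROC curve; both identities are
enforced against independent brute-force oracles in the tests.

Interval choices: Se/Sp/PPV/NPV carry Clopper–Pearson exact two-sided 95 %
intervals — conservative, assumption-free and reproducible — and the AUC
carries a Hanley–McNeil standard-error interval clipped to [0, 1]. (The
original analyses used a proprietary ROC routine whose interval method is
undocumented; exact intervals are the defensible default.) Undefined
ratios (e.g. PPV when nothing is called positive) are reported as missing,
never as zero. Orientation is fixed to "higher = more positive": an AUC
below 0.5 (as happens for HDL against dyslipidemia, where the marker is
protective) is reported as-is with a warning rather than silently flipped.

## The score and the classification grid

`count_criteria()` counts two major criteria — LDL ≥ 115 mg/dL and
LDL/HDL ≥ 1.90, assessed independently so both can hold — and four minor
criteria: male sex; adiposity (BMI ≥ 30 kg/m² or sex-specific high body
fat); family history of dyslipidemia; and any conventional CV risk factor.
Three deliberate readings were required to make the published tier rules a
total function:

* *CV risk factors count once.* Smoking, hypertension and diabetes are
  listed as a single criterion line, so an athlete with all three still
  contributes one minor. `cv_per_factor = TRUE` switches to per-factor
  counting for sensitivity analysis.
* *Zero criteria means no risk.* The published no-risk clause enumerates
  "1 M or 1 m" only; athletes with no criteria at all must land somewhere,
  and the only monotone completion folds (0 M, 0–1 m) into no-risk.
* *The "≥ 2 m" low-risk clause is the zero-major branch.* Read otherwise
  it would contradict "1 M + ≥ 2 m → medium"; the zero-major reading
  yields the unique complete, single-valued, monotone grid, which the
  tests verify by exhaustive enumeration of all 15 (majors, minors) pairs.

The adiposity minor uses BMI ≥ 30 (inclusive) by default: the source
material states the boundary both ways, and at the one-decimal precision
of recorded BMI the choice is immaterial; `adiposity_bmi_inclusive =
FALSE` restores the strict reading. Endurance sport is recorded as a
protective factor in the tier documentation but never alters the assigned
category — no operational rule for it was ever defined, so inventing one
would be over-reach.

## The synthetic cohort generator

`generate_cohort()` emulates a screening cohort of 957 Olympic athletes.
Everything that was published as a summary statistic is a configured
parameter with that published value as default: sport-category proportions
(32.5/12.8/27.6/27.1 % for power/skills/endurance/mixed), male share per
sport, age 27.1 ± 5 years truncated to [15, 47], per-sex LDL, HDL and
triglyceride means ± SD, per-sex weight/BMI/fat/waist distributions,
sport-level HDL and anthropometric group means, and the risk-factor
prevalences (smokers 8 %, family history of atherosclerosis 23.5 %, of
dyslipidemia 8.1 %, hypertension 0.4 %, diabetes 0.3 %, alcohol 58 %).

The *joint* structure was never published and is modelled:

* **(LDL, HDL) per sex is bivariate normal.** Modelling the two components
  rather than the ratio makes the ratio's distribution emergent and
  right-skewed — which is what reconciles modest mean ratios (1.76 male,
  1.36 female) with a 19.6 % exceedance of 1.90; no normal model of the
  ratio itself can do that.
* **The residual correlation is calibrated, not assumed.**
  `calibrate_ratio_correlation()` bisects the correlation (using common
  random numbers, exploiting that the exceedance of LDL − 1.9·HDL ≥ 0 is
  monotonically decreasing in it) until the simulated ratio-exceedance
  matches the 19.6 % target; the default 0.59 is the frozen output of that
  calibration. A closed-form two-component normal-tail oracle checks the
  machinery in the tests.
* **Sport effects are mean- and variance-preserving.** Sport offsets are
  derived from the sport-level group means, centred per sex, and the
  within-group residual SDs are shrunk by the between-sport variance —
  so the per-sex marginal means and SDs stay exactly at their configured
  (published) values while the sport-level means land on theirs. This is
  what reconciles the sport-level and sex-level tables simultaneously.
* **Family history and adiposity shift LDL as centred contrasts.** A
  family history of dyslipidemia adds a 16 mg/dL LDL contrast (frozen from
  calibrating the univariate odds ratio into the published 2.65–2.82
  band), and LDL couples to standardised body fat at 8 mg/dL per SD
  (chosen once to echo the published lipid gradient across fat-mass
  classes); both are mean-centred and subtracted from the residual LDL
  variance, so the marginal LDL moments are untouched.
* **Internal consistency.** Total cholesterol is constructed
  Friedewald-consistently (TC = LDL + HDL + TG/5 + noise, residual SD 5
  mg/dL) instead of sampled marginally; triglycerides are log-normal with
  per-sex moment matching (the published SDs, near the means, rule out
  normality); height is implied from jointly normal weight and BMI
  (correlation 0.8), giving realistic statures without a published height
  distribution; hip follows from waist and a per-sex waist/hip ratio.
* **Endurance carries no obesity.** Endurance records are resampled until
  BMI < 30 and body fat is below the sex ceiling, mirroring the observed
  zero counts in that group. This deliberately trims the endurance
  adiposity tail, which is why the parameter-recovery test exercises the
  clean parametric layer with this resampling switched off — with it on,
  the male BMI SD sits a hair below its configured value by construction.

What the generator does **not** emulate: measurement error and laboratory
drift over a decade of screening; age–lipid and age–adiposity trends
(published only as a dichotomised odds ratio); any sport–sex interaction
beyond composition; non-Gaussian dependence (the copula is Gaussian); and
the exact per-combination criteria-count histogram, which was published
only as an unlabelled figure. Tests passing on this cohort therefore
demonstrate that the *pipeline* is correct and that the published
cohort-level numbers are jointly reachable under a plausible model — not
that the model captures every feature of real athlete data.

## Numerical choices and degenerate inputs

* Truncated normals are sampled by inverse-CDF transformation (exact, no
  rejection); the bivariate lipid and anthropometric draws use bounded
  resampling loops that abort with a configuration error if the
  configured means cannot produce valid records.
* Cut-off analysis on a single-class condition, scoring an empty eligible
  set, and odds ratios with two empty margins are hard errors or explicit
  missing values, never silent defaults. A zero cell in a 2×2 table
  triggers the Haldane–Anscombe +0.5 correction (Woolf intervals
  otherwise).
* Generation restores the caller's RNG state, so cohort simulation never
  perturbs a surrounding analysis script.
* Reported percentages in pipeline artifacts are rounded half-up to one
  decimal, with raw proportions emitted alongside.

## Problem sizes used by the test suite

Oracle-equivalence tests run 200 random instances of up to 50
observations; parameter recovery uses a single cohort of 50 000 records
with a 3-standard-error criterion; the cohort-level reproduction checks
average 20 seeds at n = 957, the study-scale cohort size; directional
properties (sex odds ratio above 1, endurance under-representation in the
high tier) aggregate 100 and 30 seeds respectively. These sizes keep every
stochastic assertion comfortably powered while the whole suite runs in
well under a minute.

## Limitations

The score itself is a theoretical screening tool that has not been
clinically validated, and this package inherits that status: it
reproduces the construction, not an outcome model. All joint structure in
the generator is calibrated or chosen, so second-order statistics not
targeted by the calibration (e.g. the exact shape of the criteria-count
distribution) should not be read as predictions. The waist/hip ratio is
stored and reported descriptively but drives no criterion, because no
measurement protocol or cut-off was ever specified for it.
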