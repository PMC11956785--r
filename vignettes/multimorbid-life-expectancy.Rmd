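---
title: "Multimorbid life expectancy from panel data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbid life expectancy from panel data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmle)
```

`mmle` implements an incidence-based, discrete-time multistate Markov
pipeline for estimating truncated life expectancy (LE) and multimorbid life
expectancy (MMLE) — the expected years lived with two or more chronic
conditions — from longitudinal panel data of the kind collected by the South
African National Income Dynamics Study (NIDS): biennial interview waves,
self-reported chronic conditions, measured blood pressure, household-reported
deaths, and survey design weights. This vignette documents the model, its
assumptions, the conventions the implementation fixes where the published
methodology leaves choices open, and what the synthetic-data generator does
and does not emulate.

## State space and data preparation

Each person-wave is classified into one of four states from a count of 14
chronic conditions (Alzheimer's disease, arthritis, asthma, cancer,
diabetes, emphysema, epilepsy, heart problems, HIV, hypertension, kidney
problems, psychological/psychiatric disorders, stroke, tuberculosis):

* **no disease** (0 conditions), **one disease** (1), **multimorbidity**
  (2 or more), and **death**, with the total order
  `no_disease < one_disease < multimorbid < dead`.

Hypertension can be taken from the recorded indicator or re-derived from the
per-wave means of repeated blood-pressure measurements: systolic ≥ 140 mmHg
*and* diastolic ≥ 90 mmHg *and* a systolic–diastolic difference ≥ 15 mmHg.
The third clause is implemented literally as a conjunct; whether it is meant
as a pulse-pressure plausibility filter is not documented in the published
NIDS methodology, so `classify_hypertension(require_difference = FALSE)` exposes
the two-clause variant for sensitivity work. A missing pressure yields an
unknown (`NA`) condition rather than a silent negative, so the record flows
to the missing-data path.

Chronic conditions are treated as irreversible: a state sequence may never
step down the order. Observed reversals (reporting noise, a condition not
re-reported at a later wave) are repaired by **carry-forward of the highest
state attained** (`enforce_monotone_states()`), not by dropping waves. The
alternative — discarding reversing records — shrinks the sample and biases
towards short panels; carry-forward preserves sample size and matches the
chronicity semantics of the state definitions. A death followed by a living
observation is treated as an unrepairable data-integrity error.

The exclusion cascade removes (a) individuals observed at exactly one wave
and lost to follow-up (an individual with one interview plus a subsequent
household-reported death is informative and kept), (b) individuals without
two valid adult interviews (one suffices when a death record completes the
trajectory), and (c) individuals missing essential socio-demographic or
vital-status fields. The tally identity
`final = initial − single-wave − non-response − missing` is enforced
structurally.

Each retained individual contributes one **baseline pseudo-transition** —
their first observed state counted as a self-move, reflecting chronic status
acquired before entering the panel — plus one record per consecutive pair of
valid waves. Pairs separated by a skipped wave are counted as one biennial
transition (the methodology models a single biennial probability and counts
two to five transitions per person); `drop_gapped = TRUE` removes them for
sensitivity. A wave with an incomplete disease block contributes no
transition; its flanking valid waves pair up.

## Transition model

Within each sex stratum and for each transient origin state $i$, the
biennial probability of moving to destination $j$ follows a multinomial
logit in exact age and covariates,

$$\log\frac{p_{ij}}{p_{ii}} = \alpha_{ij} + \beta_{1,ij}\,\mathrm{Age}
 + \beta_{2,ij}\,\mathrm{Urban} + \gamma_{ij}'\,\mathrm{Cov},$$

with destination sets restricted by irreversibility: from no disease all
four states are reachable; from one disease only
{one disease, multimorbidity, death}; from multimorbidity only
{multimorbidity, death} (a binary logit). The **reference destination is
"remain in the same state"**: the published model form fixes the reference
to the no-disease state, which is only well-defined from the no-disease
origin; per-origin reference-to-self is the natural generalization
consistent with the admissible-destination structure, and it leaves the
implied probabilities invariant to the choice.

Four covariate sets mirror the published NIDS analysis: `M1` age + urban
residence; `M2` adds race (African reference); `M3` adds education
(less-than-secondary reference); `M4` adds a simplified race × education
interaction in which the Asian/Indian group is excluded and education is
dichotomized into less-than-secondary versus secondary-or-more.

Point estimation is a design-weighted maximum likelihood fit
(`nnet::multinom`) with weights normalized to mean one within stratum. The
default variance–covariance is a **cluster-robust sandwich** (clustered on
individual) assembled from the weighted score and observed information: it
absorbs both the weight variability and the repeated records per person,
which is the implementable reading of a vcov that "accounts for the complex
survey design" when the full two-stage design (PSUs, strata) is not part of
the input schema; `vcov_type = "model"` gives the plain inverse weighted
information. Full design-based replicate variance is out of scope.

Predicted probability rows are softmax evaluations over the admissible
destinations with **exact zeros** at reverse destinations; the residence
covariate is set to its weighted sample proportion (marginal
standardization) and categorical covariates to the stratum of interest.

## Life-table engine

Predicted rows are assembled into 4 × 4 row-stochastic matrices indexed by
2-year age intervals. Conventions, fixed where the published methodology leaves choices open:

* **Age grid**: interval starts at 20, 22, …, strictly below the truncation
  age — 33 matrices for ages 20 to 85 (23 when starting at 40). "Until age
  85" cannot land exactly on 85 with 2-year rows from age 20; by default the
  final interval is credited in full (an effective horizon of 86), and
  `half_final_interval = TRUE` credits half of it to approximate the bound
  exactly.
* **Occupancy**: the state at an interval *start* is credited with the full
  2-year step, the discrete-chain fundamental-matrix reading — certain death
  in the first interval still yields 2 years, and a no-exit chain yields
  exactly 66. A midpoint prediction age is available
  (`prediction_age = "midpoint"`).

Expected years per state follow from the fundamental matrix
$N = (I - U)^{-1}$ of the age-expanded transient chain (state × age
interval; $U$ is block-superdiagonal, so $N$ is finite because the last
interval exits the transient set). Every call is cross-checked against
direct forward accumulation of occupancy vectors; the two must agree to
$10^{-9}$ or the computation aborts. A seeded Monte Carlo trajectory oracle
(`mc_oracle()`) simulates the same chain under the same occupancy convention
and is used throughout the tests as an independent check.

Origin-weighted LE and MMLE average the conditional expectancies over the
design-weighted distribution of baseline states among individuals aged 20 up
to (but below) 30 — a window rather than exact age 20, to stabilize the
weights — computed per sex. Design weights enter this distribution for
consistency with the weighted fit (the methodology does not state whether
they did). For the age-40 analysis the window shifts analogously to 40–49;
this too is a convention the published methodology leaves open.

## Confidence intervals

CIs for weighted LE and MMLE propagate the coefficient variance–covariance
through the expectancy functional by the delta method: the gradient with
respect to the full stacked coefficient vector of a sex stratum is computed
by central finite differences (step $10^{-5}$ on the coefficient scale — the
functional is smooth and the published derivation's analytic gradients are
not reproduced here), the variance is $g' V g$ with $V$ block-diagonal over
origins, and the interval is the asymptotic-normal point ± $z_{1-\alpha/2}$
SE. A negative lower limit is clamped to zero — negative expectancies are
impossible — and flagged. The percentage of LE with multimorbidity is
reported without a CI, matching the display convention of published tables.

## The synthetic-data generator

`simulate_panel()` produces NIDS-like panels with known generative dynamics
so that every downstream stage is testable without restricted microdata and
parameter recovery can be verified against truth. Its defaults are the study
conditions used throughout the package's validation and were fixed once:

* 18,030 adults, five biennial waves, baseline ages uniform on [20, 90]
  (the panel's age pyramid is not published in detail), interview ages jittered ±0.5
  years so the continuous age covariate is exercised;
* per-sex baseline state distributions (76/18/6 per cent for males,
  65/25/10 for females) and per-sex transition dynamics whose intercepts are
  calibrated analytically (`calibrate_coefficients()`) to reproduce the
  pooled biennial transition fractions observed in the NIDS panel at the
  per-sex mean interview age, with age slopes 0.035 (disease incidence) and
  0.07 (death) per year of age and urban effects +0.1/−0.1 on the log-odds
  scale — gentle incidence gradients and a faster mortality gradient,
  typical of adult chronic-disease schedules;
* covariate margins from the panel's published composition (60 per cent
  female, 80 per cent African, 50 per cent urban, …), lognormal(0, 0.5²)
  design weights, and independent 15 per cent per-wave attrition (chosen so
  that roughly half of simulated individuals complete all five waves, as
  observed; published attrition summaries describe patterns but no model, so a
  state-dependent attrition multiplier is exposed as a parameter rather than
  asserted);
* deaths between waves surface at the following wave (household-report
  convention); dropout before that wave leaves the death unobserved.

The generator assigns concrete conditions (by baseline prevalence weights,
hypertension the most common) only as far as the state definitions require
— zero, one, or two conditions — and blood-pressure means consistent with
the hypertension rule. It does **not** emulate household clustering, the
two-stage sample design, calendar time, recall bias, condition-specific
progression, or more than two concurrent conditions; passing tests
demonstrate correctness of the estimation machinery under a correctly
specified model, not robustness to those real-data features.
`inject_reversal_noise()` adds apparent recoveries for exercising the
monotone repair.

## Validation design and problem sizes

The package's own validation, in `tests/testthat/test-acceptance.R`, uses
problem sizes chosen to make each check sharp:

* exact arithmetic on the packaged published-estimate fixture (28 strata
  rows; every quoted sex gap and education gain re-derived from cells);
* oracle equivalence on 20 seeded random valid matrix sets at 100,000
  trajectories (3 Monte Carlo SEs), exact agreement on deterministic
  chains, and the geometric-chain closed form $2(1-p^{33})/(1-p)$ to
  $10^{-9}$;
* parameter recovery on six independent panels of 50,000 individuals:
  the replicate-mean fitted weighted LE and MMLE must lie within ±0.5 years
  of the truth implied by the generative coefficients, computed through the
  same matrix engine, with the origin distribution held at its generative
  truth on both sides so the comparison isolates the coefficients (the
  sampling SD of a single 50,000-person panel is ≈ 0.3 years, so averaging
  makes ±0.5 a ≈ 4σ check); Wald coverage of the generative coefficients
  pooled across replicates must reach 90 per cent;
* delta-method calibration on 500 replicates of 5,000 individuals: per-sex
  empirical coverage of the 95 per cent CI for weighted LE within 95 ± 3
  percentage points. These replicates fit with
  `include_baseline = FALSE` and evaluate the functional at the true origin
  distribution: the baseline pseudo-transition is a data-construction
  convention of the survey (and stays the pipeline default), but it is not
  part of the generative dynamics, and the delta CI propagates coefficient
  uncertainty only — both choices keep the estimand equal to the quantity
  whose truth is known.

## Known limitations

* The multinomial-logit vcov is cluster-robust but not fully design-based;
  PSU/stratum information is not part of the input schema.
* Age enters linearly on the log-odds scale, as in the published
  analysis; strongly non-Gompertz mortality would need a different
  covariate basis.
* All inter-wave transitions are treated as biennial regardless of the
  realized gap; `drop_gapped` is the only mitigation offered.
* The four-state space collapses disease identity; sensitivity variants
  re-derive states from raw flags (removal of a condition changes counts at
  source, never by post-hoc filtering of states).
* Published stratified estimates packaged as the fixture come from
  restricted microdata; they anchor arithmetic consistency checks, not
  replication.
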