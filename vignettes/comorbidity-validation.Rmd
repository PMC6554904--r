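---
title: "Comorbidity scoring and its validation: models, design choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity scoring and its validation: models, design choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readmorbid)
```

This vignette is the package's own account of its methods: the scoring
rules, the synthetic cohort model, the statistical machinery, and the
places where the design was genuinely open and a choice had to be made.

## 1. The two comorbidity measures

The Charlson Comorbidity Index (CCI) summarises 17 disease categories into
a single weighted count. The package ships both weight schemes in
`category_registry("charlson")`: the original weights (1, 2, 3 or 6 per
category — e.g. peripheral vascular disease 1, metastatic solid tumour 6)
and the Quan 12-item modification, in which five categories (myocardial
infarction, peripheral vascular disease, cerebrovascular disease, peptic
ulcer, uncomplicated diabetes) receive weight 0 and the remaining twelve
carry weights in {1, 2, 4, 6}. No age points are ever added to the index:
in the validation models age is a separate continuous covariable, so adding
age bands to the score would double-count it.

The Elixhauser Method (EM) defines 31 binary categories and deliberately
does *not* weight them: each category enters the outcome model as its own
indicator. `elixhauser_profile()` therefore returns the ordered 0/1 vector
plus a count; the count is used only for descriptive tables
(`count_distribution()`), never as a model covariable.

## 2. Code lists

A code list maps opaque terminology tokens (Read codes) to categories.
Matching is **exact and case-sensitive** after whitespace trimming: Read
codes distinguish case, and published lists are already exploded to
individual codes, so no prefix or hierarchy expansion is performed.
Duplicate `(code, category)` rows are collapsed at load; the same code
appearing under two *different* categories of one measure is legitimate
(e.g. a tumour code serving both a lymphoma and a metastatic category) and
is surfaced by `validate_codelist()` for human review rather than deleted.
`merge_codelists()` models the multi-screener workflow used to develop such
lists: the union of the inputs plus a per-category report of codes found by
only a strict subset of screeners — exactly the items that need
adjudication. The merge is idempotent, commutative and associative, which
the test suite checks on randomly generated lists.

Real published lists are restricted-terminology derivatives and are not
redistributed here. `synthetic_codelists()` fabricates deterministic
stand-ins with the published sizes (5832 Charlson, 7156 Elixhauser
entries), category proportions that mimic how many codes each disease area
attracts, and uniqueness of codes within a measure. The synthetic lists
exercise every code-path the real ones would; they carry no clinical
content, and results computed with them say nothing about real Read-coded
records (see §7).

## 3. Look-back windows and flagging

`flag_comorbidities()` flags a category when at least one event carries a
mapped code with

```
index_date - W <= event_date < index_date
```

where `W` is 365 days, 5 × 365 days, or unbounded. Two boundary decisions
are deliberate:

* the window is **half-open at the index date**: diagnoses coded on the day
  of the fracture admission describe the acute event, not pre-existing
  comorbidity;
* the lower bound is inclusive, so an event exactly 365 days before index
  is inside the one-year window.

One event suffices to flag a category; no "two codes on separate dates"
rule-out filter is applied. Unmapped codes are ignored silently, because a
real record is dominated by non-comorbidity codes.

**Severity hierarchies.** When a patient carries codes for both a mild
condition and its severe counterpart, the default rules clear the milder
flag (Charlson: complicated diabetes ⊳ uncomplicated, moderate/severe liver
⊳ mild, metastatic tumour ⊳ any malignancy; Elixhauser: complicated
hypertension ⊳ uncomplicated, metastatic cancer ⊳ solid tumour, complicated
diabetes ⊳ uncomplicated). Hierarchies interact with windows in a subtle
way: widening the window can reveal the severe condition and thereby
*clear* a mild flag that the narrow window had set, so the resolved flag
sets do not strictly nest. The raw (pre-hierarchy) flag sets always nest,
and the resolved indices and counts remain monotone because every severe
category carries at least its superseded partner's weight and the rules are
one-to-one. The tests check exactly these two statements. Pass
`hierarchy = FALSE` to `comorbidity_profiles()` for a no-hierarchy reading.

**Count bins.** Descriptive tables bin comorbidity counts as 0, 1, 2, 3, 4,
5, >6. That labelling leaves no bin for exactly 6; `count_distribution()`
assigns 6 to the terminal bin so the partition is exhaustive, and exposes
`bin_edges` for any other convention.

## 4. The synthetic cohort generator

The generator's defaults are the study conditions the package is validated
under; they are set once, from the published cohort description and from
what is clinically realistic, and are not tuned per analysis.

* **Demographics.** Sex is 1 = female with probability 0.751. Age at index
  is `round(95 − G)` with `G ~ Gamma(shape, rate)` fitted at configuration
  time so the quartiles hit 75 / 82 / 87 years, truncated to [60, 104] — a
  left-skewed distribution appropriate to an elderly fracture population.
  Index dates are uniform over 1999-01-01 … 2013-10-09; registration starts
  3 years + U(1, 9125) days before index, enforcing the ≥3-year
  up-to-standard rule constructively. Year of birth is index year minus
  age, the convention of databases that store year of birth only.
* **Matching.** Controls are synthesized rather than sampled, so exact
  matching on (sex, integer age) never fails; each case gets
  `control_ratio` controls (default 2) who inherit the case's index date as
  their look-back and follow-up reference date. The source study does not
  state the controls' reference-date convention; the matched-case-date
  convention used here is the standard one for matched designs.
* **Comorbidity prevalence.** Per-category prevalences are not published as
  numbers (they appear only in figures), so the defaults encode plausible
  relative magnitudes (hypertension and depression common, HIV rare),
  rescaled by a single solver (`uniroot`) so the expected fraction of cases
  with *zero* flagged categories matches the published marginals: 27.6%
  with no Charlson category and 9.2% with no Elixhauser category on the
  complete record. Controls use the same prevalences scaled by 0.79, which
  reproduces the published control marginals (36.6% / 15.3%) under the same
  independence model. Only the zero bins are calibrated; the rest of the
  count distribution follows from independence and is close to, but not
  identical to, the published table.
* **Events.** Each present flag emits `1 + Poisson(events_per_flag − 1)`
  events (default mean 3), coded by a uniform draw from the category's
  list, dated uniformly over `[registration_start, index_date)`. An
  optional `recent_fraction` concentrates that share of events into the
  final pre-index year to exercise look-back sensitivity. Because synthetic
  codes are unique within a measure and all events predate the index, the
  engine recovers the latent flag matrix *exactly* under the
  complete-record window — the round-trip identity the tests assert.
* **Mortality.** 30-day death is Bernoulli with log-odds
  `−9.1 + 1.6·case + 0.06·age − 0.35·female + Σ β_k·flag_k`; survivors face
  the analogous (30, 365] model with intercept −7.4 and case excess 0.9.
  Default `β_k` put weight on Charlson categories in proportion to their
  original weights (0.10 per weight point) plus graded effects for
  Elixhauser-only categories, so both measures carry real signal. The
  intercepts were chosen so the default cohort shows roughly 8% 30-day and
  25% one-year case fatality with controls several-fold lower — the
  accepted epidemiology of hip fracture in the elderly. Death dates fall
  uniformly in the realized window (days 0–30 or 31–365, boundaries
  inclusive). The latent flags of the two measures are drawn
  *independently*, even for categories the measures share; see §7.
* **Seeding.** One root seed is hashed with a stage label into independent
  per-stage streams (`cases`, `controls`, `events`, `mortality`), so adding
  a stage never perturbs earlier stages' draws, and every random routine
  restores the caller's RNG state. Identical config + seed reproduce
  byte-identical output files.

## 5. Validation statistics

**Logistic models.** The model menu is fixed — base (age + sex), base +
CCI, base + 31 EM indicators, each comorbidity block alone, and the 17
Charlson indicators as individual covariables — with no stepwise selection.
Fitting is plain maximum likelihood (IRLS, tolerance 1e-8, ≤100
iterations), deterministic by construction. Constant or perfectly collinear
columns (a category with zero prevalence in a stratum) are dropped with a
warning, mirroring what standard software does; complete separation is
detected from a diverging linear predictor and flagged as non-convergence.
Day-30 and day-365 outcome boundaries are inclusive. Cases and controls are
always analysed separately; the matched design is never collapsed into a
conditional (case-control) likelihood, and the reported AUROCs are
in-sample (apparent) discrimination, as is conventional for comorbidity
measure comparisons.

**AUROC and the DeLong machinery.** `auroc()` is the Mann–Whitney
estimator with ties counted ½, computed through midranks; its variance uses
DeLong's structural components, with the midrank identity giving exact tie
handling in O(n log n). The 95% CI is the normal approximation, clipped to
[0, 1]. `compare_roc()` implements the correlated-curves equality test: the
k AUCs' covariance is estimated from the paired components, a
successive-difference contrast forms a chi-square with k − 1 df; with k = 2
this is exactly the squared paired z. Identical score vectors make the
contrast covariance singular; the pseudo-inverse path returns statistic 0
and p = 1 rather than an error. A paired, outcome-stratified bootstrap
(`bootstrap_roc_test()`) is included as a cross-check, not a default. The
test suite cross-validates AUC, variance and the two-curve p-value against
pROC and against exhaustive pair counting.

A calibration subtlety worth recording: validating the test's type-I error
requires score vectors *independent* of the evaluation outcomes. Comparing
two uninformative models scored **in-sample** is not a clean null — fitting
orients each noise covariate toward the outcome, and the resulting folded
AUC differences make the comparison strongly conservative. The acceptance
suite therefore fits the uninformative models on training data and scores
held-out subjects, where the empirical rejection rate sits at the nominal
5% (checked over 2000 replicates at n = 300).

**Kaplan–Meier.** `km_estimate()` wraps the product-limit estimator from
the survival package, capping follow-up at 365 days (administrative
censoring), and returns the step function in long format per index stratum.
The tests pin it to hand-computed product limits and to the empirical
survival function in the censoring-free case.

## 6. Problem sizes used by the tests

The suite runs at deliberately desk-friendly sizes chosen to keep binomial
and AUC sampling error well inside the asserted bounds: demographic
calibration at 10,000 cases (±2% on the female fraction, ±1 year on the
median age); flag-frequency and death-rate checks at 3σ binomial bounds
(n = 10,000 and 25,000); logistic parameter recovery at n = 20,000 within
3 SE; the ROC type-I experiment at 2000 replicates of n = 300; and the
EM-versus-CCI ordering at 20,000 cases over 10 seeds. The acceptance script
simulates 10,000 cases with 2:1 controls.

## 7. What the synthetic validation does and does not show

The generator reproduces the *structure* of a matched primary-care cohort,
not its content. Passing tests demonstrate that the scoring engine is exact
(round-trip flag recovery), that the window logic, weights and hierarchy
behave as specified, that the statistical machinery is calibrated, and that
the pipeline recovers known generating parameters. They do not certify the
clinical validity of any particular code list, and the AUROC magnitudes
produced here are properties of the synthetic mortality model, not of hip
fracture epidemiology.

Known simplifications: latent comorbidity flags are independent across
categories *and* across the two measures, so shared categories (e.g.
congestive heart failure) are uncorrelated between CCI and EM — real
records would couple them, and real EM–CCI AUROC gaps would be smaller than
engineered EM-only-driver scenarios suggest; event dates are uniform over
the record rather than clustered near diagnosis or death; there is no
practice-level clustering, no data-quality (up-to-standard) modelling, no
coding intensity drift over calendar time; and the mortality simulator is
the same model family the validation fits (intentionally, so parameter
recovery is a clean test — a `misspecify` switch adds an age × sex
interaction for robustness experiments, off by default).
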