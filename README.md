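# readmorbid

Comorbidity risk adjustment for Read-coded primary care databases:
Charlson and Elixhauser scoring from clinical code lists, plus the
validation analyses that compare the two measures' ability to predict
mortality after hip fracture.

## The problem

UK primary-care research databases (CPRD GOLD, THIN) record diagnoses as
**Read codes** — case-sensitive alphanumeric terminology tokens. Healthcare
researchers comparing outcomes across providers or populations must adjust
for comorbid disease, usually through one of two summary measures:

* the **Charlson Comorbidity Index (CCI)**: 17 disease categories, each with
  an integer weight *w<sub>k</sub>* ∈ {1, 2, 3, 6} (peripheral vascular
  disease 1, …, metastatic solid tumour 6); the index is
  CCI = Σ<sub>k</sub> w<sub>k</sub> · 1[category k present]. The Quan
  12-item modification re-weights with *w<sub>k</sub>* ∈ {0, 1, 2, 4, 6},
  dropping five categories.
* the **Elixhauser Method (EM)**: 31 binary categories entered as separate
  covariables in the outcome model rather than summed into one score.

Computing either from a Read-coded record requires (a) a code list mapping
thousands of individual Read codes into the categories, (b) machinery that
turns a patient's dated events into category flags under a **look-back
window** (1 year, 5 years, or the complete record before the index date),
and (c) a validation framework: logistic regression models for 30- and
365-day mortality, AUROC with DeLong confidence intervals, tests of
equality for correlated ROC curves (the analysis behind Stata's `roccomp`),
and Kaplan–Meier curves by index stratum.

`readmorbid` implements all three layers, together with a synthetic
hip-fracture case–control cohort generator that emulates the structure of a
CPRD-style extract (index events 1999-01-01 to 2013-10-09, ≥3-year prior
registration, 2:1 age/sex-matched controls, median age 82, 75.1% female),
so the entire pipeline is runnable and testable without access to
restricted patient data. The shipped code lists are deterministic
*synthetic* stand-ins with the published list sizes (5832 Charlson and 7156
Elixhauser entries); real published lists in `code,term,category` CSV
format drop straight into `load_codelist()`.

## Worked example

```r
library(readmorbid)

coh <- simulate_cohort(generator_config(n_cases = 2000), seed = 42)
coh
#> <cohort> 2000 cases, 4000 controls; 54033 coded events
#>   30-day deaths: 161 cases / 66 controls

pr <- comorbidity_profiles(coh, window = "complete_record")
round(100 * count_distribution(pr, coh, "charlson"), 1)
#>       role
#> binned case control
#>     0  27.9    36.5
#>     1  36.4    38.6
#>     2  25.1    19.4
#>     3   8.3     4.3
#>     4   1.9     1.1
#>     5   0.2     0.1
#>     >6  0.0     0.0

res <- run_validation(coh, windows = "complete_record",
                      outcomes = "death_30d",
                      models = c("base", "base_em", "cci_alone", "em_alone"),
                      populations = "case")
res
#> <validation results> 4 model fits
#>   population   outcome     model          window                 auc
#> 1       case death_30d      base complete_record 0.645 [0.605-0.685]
#> 2       case death_30d   base_em complete_record 0.691 [0.650-0.733]
#> 3       case death_30d cci_alone complete_record 0.588 [0.543-0.634]
#> 4       case death_30d  em_alone complete_record 0.630 [0.584-0.677]
#>     comparison p_value
#> 1         <NA>      NA
#> 2      vs_base 0.00914
#> 3         <NA>      NA
#> 4 vs_cci_alone 0.19675
```

Reading the output: 27.9% of synthetic cases carry no Charlson comorbidity
(controls are healthier at 36.5%); adding the 31 Elixhauser indicators to
the age + sex base model lifts the 30-day mortality AUROC from 0.645 to
0.691, and the DeLong test of ROC-curve equality puts p = 0.009 on that
improvement — the qualitative pattern (EM adds more discrimination than the
CCI) that motivates preferring the Elixhauser method.

Scoring primitives are available directly:

```r
f <- setNames(logical(17), category_registry("charlson")$category)
f[c("pvd", "mets")] <- TRUE
charlson_index(f, "original")  # 7  (1 + 6)
charlson_index(f, "quan")      # 6  (0 + 6)
```

An end-to-end reproducible run (cohort CSVs, per-window profiles,
`results.csv`, Kaplan–Meier table, manifest with seed and config hash) is
one call: `run_all(run_config(out_dir = "my_run", seed = 1))`.

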