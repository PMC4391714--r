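# comorbrisk

Age- and sex-stratified screening of diabetes comorbidities from two-year
ICD-10/ATC claims data.

## What it does, and for whom

Nationwide claims registries let an epidemiologist test *every* diagnosis
at once for association with an index disease instead of running one
cohort study per comorbidity. `comorbrisk` implements that screening
pipeline for type 1 (E10) and type 2 (E11) diabetes on two-year claims
panels:

* **Relative-risk screen.** For each candidate 3-character ICD-10 code
  *x*, five-year age group *t* ∈ {[0,5), …, [90,95)} and diabetes type, a
  2×2 table (a, b, c, d) of diabetes by diagnosis is built and

  RR(x,t) = [a/(a+b)] / [c/(c+d)]

  is estimated with its Katz log-normal 95% CI, tested by a Pearson
  chi-squared test, and controlled by the Benjamini–Hochberg procedure at
  false-discovery rate α within each (age group × type) family. A code
  significant in at least one age group is a comorbidity; at α = 0.01, a
  list of *n* discoveries is expected to contain 0.01·*n* false ones.
* **Sex ratio.** For any binary attribute *x* (diagnosis, ATC drug group,
  or a bin of the per-patient diagnosis/prescription count),

  SR(x,t) = log[(1 + D_m(t)/D_m(x,t)) / (1 + D_f(t)/D_f(x,t))]

  among diabetic patients — positive for female excess, zeroed when a
  chi-squared independence test is not significant at p = 0.05.
* **Lead/lag indicators.** I_lead(d_i,x) = p(x,t₂ | d_i,¬x,t₁) −
  p(x,t₁ | d_i,¬x,t₂) measures whether *x* tends to be newly coded (as a
  main diagnosis) *after* diabetes; I_lag exchanges the roles. Significance
  comes from 1000 surrogate datasets in which each patient's diagnosis-year
  labels are randomly permuted (p < 0.01).
* **Validation.** Recall R(α) against a packaged, curated list of 22
  well-established diabetic complications.
* **Synthetic data.** Such registries are not publicly deposited, so
  `simulate_population()` generates structurally realistic two-year claims
  with planted relative-risk, sex and temporal-lead effects and returns
  the ground truth — the whole pipeline is testable and calibratable
  offline.

## Worked example

```r
library(comorbrisk)

cfg <- sim_config(n_patients = 50000, seed = 42)   # planted defaults
sim <- simulate_population(cfg)
cohort <- build_cohort(sim$data)
cohort
#> <claims_cohort> 49004 patients (definition: inpatient), 515 DM1, 4861 DM2, ref. year 2007

cohort_summary(cohort)$counts
#>     group  male female total
#> 1:    DM1   225    290   515
#> 2:    DM2  2062   2799  4861
#> 3: cohort 21114  27890 49004

screen <- run_cooccurrence(cohort, alpha = 0.01)
screen
#> <cooccur_result> 1596 scheduled tests, alpha = 0.01: DM1 1, DM2 22 comorbidities (union 22)
recall(screen$comorbidities$union)
#> [1] 1
expected_false_positives(length(screen$comorbidities$union), 0.01)
#> [1] 0.22

st <- surrogate_test(cohort, "E11", "I50", "F", n_surrogates = 250, seed = 42)
sprintf("I_lead = %.3f, p_lead = %.3f", st$i_lead, st$p_lead)
#> [1] "I_lead = 0.041, p_lead = 0.000"
```

Reading the numbers: 42 candidate codes × 19 age groups × 2 types give
1596 scheduled tests. At this cohort size the type 1 stratum is thin
(515 patients), so only one code clears FDR control for DM1, while all 22
codes with planted effects are recovered for DM2 — recall 1.0 against the
reference list, with 0.22 expected false positives among the 22
discoveries. The planted temporal effect for heart failure (I50) in
female type 2 patients yields a positive lead indicator whose value is
never reached by 250 year-permuted surrogates (p < 1/250): diabetes leads
the new heart-failure codings.

`run_pipeline(pipeline_config(...), outdir)` chains all stages and writes
each result as a delimited file plus a JSON manifest; outputs are
byte-identical for identical configuration and seed. See the vignette
(`vignettes/comorbidity-screening.Rmd`) for the model, conventions and
design choices.

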