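---
title: "Age- and sex-stratified comorbidity screening from claims data"
author: "comorbrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age- and sex-stratified comorbidity screening from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbrisk)
```

## The problem

Nationwide claims registries record, for essentially every person in a
country, the ICD-10 codes of their hospital diagnoses and the ATC codes of
their prescriptions. Such data make it possible to screen *every* candidate
disease at once for association with an index condition — here type 1
(E10) and type 2 (E11) diabetes mellitus — rather than studying one
comorbidity per cohort study. `comorbrisk` implements such a screening
pipeline for two-year claims panels:

1. **Cohort construction** with the registry's inclusion/exclusion rules.
2. **Relative-risk screening**: one 2×2 diabetes-by-diagnosis table per
   candidate code, five-year age group and diabetes type, with chi-squared
   tests and Benjamini–Hochberg (BH) false-discovery-rate (FDR) control.
3. **Sex ratios**: a smoothed log ratio comparing female and male
   co-occurrence rates among diabetic patients.
4. **Lead/lag indicators**: do patients acquire a diagnosis *after* the
   diabetes diagnosis more often than the reverse? Significance by a
   surrogate-data permutation test.
5. **Validation**: recall against a curated list of 22 well-established
   diabetic complications.

Registries of this kind are not publicly deposited, so the package ships a
synthetic claims generator that emulates the *structure* of such data and
plants known effects. Every statistical property claimed below is checked
by the test suite on that generator.

## Cohort rules

Patients deceased in the study window are removed, as are patients older
than the configurable maximum age. Age is computed as `reference_year -
birth_year`, with the reference year defaulting to the second study year
(the data carry only birth years, so any within-year precision is
illusory anyway). The nineteen age groups are the half-open intervals
[0,5), …, [90,95); we therefore exclude ages ≥ 95 so that the groups
partition the cohort exactly. Diabetes membership is assigned from any
E10/E11 diagnosis event, main or side, in either year; a patient carrying
both codes belongs to both groups, and each analysis uses its own type's
membership with all other same-age patients (including those of the other
type) as comparator. An alternative, prescription-based cohort definition
(any ATC `A10` dispensation marks a diabetes patient) is available for
robustness checks.

## Relative-risk screen

For code $x$, age group $t$ and diabetes type $i$, the 2×2 table counts
$a$ (diabetic, has $x$), $b$ (diabetic, no $x$), $c$ (comparator, has
$x$), $d$ (comparator, no $x$); "has $x$" means any main or side
diagnosis in either year. The relative risk and its Katz log-normal 95%
confidence interval are

$$RR = \frac{a/(a+b)}{c/(c+d)}, \qquad
\exp\Big(\log RR \pm z_{0.975}\sqrt{\tfrac1a - \tfrac1{a+b} + \tfrac1c -
\tfrac1{c+d}}\Big).$$

(The CI method is a package choice; the Katz interval is the standard
large-sample interval for a risk ratio.) Independence is tested by the
Pearson chi-squared statistic on the table (1 df, no continuity
correction by default; Yates available by flag). BH control at level
$\alpha$ is applied separately within each (age group × type) family,
counting only the tests actually performed. A code significant in at
least one age group for a type enters that type's comorbidity list; by
the method's reporting convention, cells that were skipped or not
significant report $RR = 1$ (the unmodified estimate is kept in
`rr_raw`).

### The cell rule

A test is only performed when the table is large enough. The classical
prescription is a threshold on each table entry; we additionally require
every *expected* cell under independence to reach the same threshold
(default 10 for both, `min_cell` / `min_expected`). The reason is a
selection effect we measured during calibration: a cell whose expected
count is 2–7 can only reach an observed count of 10 by fluctuating far
upward, and for such tables the chi-squared approximation understates
far-tail p-values by orders of magnitude (Fisher's exact test on the
same tables agrees with neither). With observed-only gating the
per-family false-discovery proportion on null data was ≈ 0.04 at
$\alpha = 0.01$; adding the expected-count condition — the textbook
validity condition for the chi-squared approximation — brings it to
≈ 0.01 or below. Setting `min_expected = 0` restores the literal
observed-cell rule.

### What FDR control guarantees

BH controls the *expected false-discovery proportion within one testing
family*. The calibration tests therefore measure the mean per-family FDP
(19 age groups × 2 types per replicate) on all-null synthetic data.
Note that under a global null the per-family FDP is the indicator of any
rejection, so its mean is also the per-family probability of a false
family; pooled statements about the expected number of false comorbidities
at a given discovery count are provided by `expected_false_positives()`
($\alpha \times$ discoveries).

## Sex ratio

With $D_f(t)$, $D_m(t)$ female/male diabetic patients in age group $t$
(pooled over both types by default) and $D_f(x,t)$, $D_m(x,t)$ those
carrying attribute $x$,

$$SR(x,t) \;=\; \log\!\left[\frac{1 + D_m(t)/D_m(x,t)}
{1 + D_f(t)/D_f(x,t)}\right],$$

which is zero at equal proportions, positive when the attribute is more
likely in females, negative for males, and antisymmetric under swapping
the sexes. The "1 +" smoothing inside each per-sex term is kept exactly.
The orientation of the quotient is chosen so that the stated sign
convention (positive = female excess) holds; the inverse orientation is
available as `sr_orientation = "inverse_printed"` because the flattened
one-line rendering of the formula is ambiguous about which sex sits in
the numerator. Attributes are any binary predicate over a patient's
record: a diagnosis code, an ATC prefix (e.g. `N05`, psycholeptics), or
a bin of the per-patient diagnosis/prescription count. A value is set to
zero when the chi-squared independence test on
$[[D_f(x,t), D_f(t)-D_f(x,t)], [D_m(x,t), D_m(t)-D_m(x,t)]]$ is not
significant at $p = 0.05$, or when either co-occurrence count is zero.

## Lead/lag analysis

For index diagnosis $d_i$ and candidate $x$, within one sex,

$$I_{lead}(d_i, x) = p(x, t_2 \mid d_i, \neg x, t_1) -
                     p(x, t_1 \mid d_i, \neg x, t_2),$$

where the first term is the fraction of patients with a $d_i$ diagnosis
(main or side) in year 1 and no $x$ in year 1 who acquire a *main*
diagnosis of $x$ in year 2, and the second term exchanges the years.
Requiring a main diagnosis makes the incident event a reason for the
hospital stay rather than an incidentally re-coded pre-existing
condition; the reverse-direction subtraction cancels symmetric coding
noise. $I_{lag}$ exchanges the roles of $d_i$ and $x$. The conditional
notation is read as conditioning on the year-1 (resp. year-2) state; an
indicator whose denominator is empty is reported `NA`. Pairs with fewer
than $z = 50$ same-sex patients carrying a main $x$ in year 2 together
with $d_i$ (either year, main or side — the most inclusive reading of the
threshold, flag-controlled) are excluded. The lag analysis for the type 1
index is restricted to patients aged ≤ 30, where type 1 onset actually
occurs.

Significance uses surrogate data: each patient's multiset of diagnosis
events keeps its codes and main/side flags, and the patient's own year
labels are re-assigned by a uniformly random permutation (prescriptions
untouched; a patient with all diagnoses in one year is invariant). The
p-value is the fraction of 1000 surrogates (250 in the scaled-down test
runs) whose indicator is $\ge$ the observed one — the conservative tie
convention; strictly-greater is available — with rejection at
$p < 0.01$. Internally the permutation is performed by sequential
sampling without replacement from each patient's year multiset,
restricted to the $d_i$/$x$ event slots; other diagnoses enter only
through their year counts, which is equivalent to permuting the full
multiset but orders of magnitude faster.

## The synthetic generator

`simulate_population()` draws, per patient: age from a hospitalised-
population pyramid (early-childhood bump, dip around age ten, monotone
rise into old age), sex (57% female, matching the skew of an inpatient
population), an independent deceased flag, and diabetes status from
age- and sex-banded prevalences (type 1 ≈ 0.6–1.2%, flat in age; type 2
rising from ≈ 0.2% before 30 to 16–18% above 70). Each candidate
diagnosis then occurs with probability
`baseline × age_profile(age) × sex_effect (females) × RR effect
(diabetics)`, capped at 1 — effects act multiplicatively on the
per-window *risk*, matching the relative-risk estimand. An occurring
condition is coded in both years with probability `persistence` (0.5) and
otherwise in year 1 or year 2 with equal probability, so the null
generator is exchangeable in the year labels by construction — exactly
the null hypothesis of the permutation test. Planted lead effects add,
for patients with a year-1 diabetes diagnosis and no year-1 occurrence
of the code, a fresh year-2 main diagnosis with probability
$(\lambda - 1) \times$ the patient's baseline probability. Prescriptions
are generated analogously; antidiabetic drugs (`A10`) are strongly
enriched in diabetic patients so the prescription-based cohort definition
is exercisable. `planted_truth()` returns, deterministically, the effects
a correct analysis should recover.

What the generator does **not** emulate: within-year event timing,
regional or household structure, coding-quality artefacts, mortality that
is correlated with disease burden (the deceased flag is independent and
exists to exercise the exclusion rule), and code–code correlations beyond
those induced by diabetes. Passing tests therefore demonstrate the
statistical machinery — calibration, power, sign conventions, temporal
detection — not robustness to every real-data bias.

A deliberate implementation note: the generator uses a single seeded
stream with vectorised draws, so datasets are reproducible for a fixed
(seed, configuration) pair, but changing `n_patients` re-draws everyone
(per-patient sub-streams were rejected as prohibitively slow in R at the
population sizes used).

## Problem sizes used in the checks

The packaged experiments use sizes at which every quantity is
well-resolved on a laptop-class machine: FDR calibration on 20 null
datasets of 50 000 patients × 200 candidate codes (mean per-family FDP
≤ 0.03 at α = 0.01); recovery of a planted RR = 4 (type 2, ages 60–80)
from the per-cell Katz 95% CIs in ≥ 90% of band cells over 20 seeds;
sign recovery of a planted two-fold female excess in ≥ 95% of non-zeroed
sex-ratio cells; permutation-test calibration over 100+ (code, sex)
pairs on a year-exchangeable 40 000-patient dataset with 250 surrogates
(rejection rate ≤ 0.02 at p < 0.01) plus detection of planted λ = 3
lead pairs; and full recall of the 22-code reference list when all its
codes carry planted RR = 4. Oracle tests compare every estimator against
naive brute-force implementations on ≥ 1000 random instances at 10⁻¹⁰
relative tolerance.

Recovery experiments give planted codes an ample baseline frequency
(≈ 6–8% per window) so that expected counts clear the cell rule and the
z-threshold; that is a statement about the experiments' power, not about
the estimators.

## Numerical and degenerate-input conventions

* Relative risk is `NA` when a margin or the comparator numerator is
  zero; such cells are "not computed".
* Chi-squared is `NA` at a zero margin; in the sex-ratio gate a
  degenerate margin yields p = 1 (no evidence), and zero co-occurrence
  in either sex zeroes the cell with reason `"zero co-occurrence"`.
* BH treats `NA` p-values as outside the family.
* In surrogate datasets an empty denominator contributes probability 0
  (the observed data of a tested pair never has one, since such pairs are
  reported `NA` and not tested).
* BH boundary is inclusive (`p ≤ (k/m)α`); permutation p-values use the
  `≥ observed` tie convention.
* All probability products in the generator are capped at 1 before
  sampling.

## A small end-to-end run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = sim_config(n_patients = 20000),
  leadlag = list(z = 30, n_surrogates = 250),
  seed = 1
)
res <- run_pipeline(cfg, outdir = "run1")
res$manifest$recall
```

The output directory then contains the demographics/events interchange
files, the planted-truth sidecars, per-type co-occurrence tables
(`code, age_group, RR, CI, p, significant`), the sex-ratio and lead/lag
tables, recall per FDR level, and a JSON manifest with the seed and
configuration hash. Identical configuration and seed give byte-identical
stage outputs.

## Limitations

* Two study years only: lead/lag is a tendency statistic, not a
  time-to-event model, and says nothing about latency.
* No confounder adjustment beyond age/sex stratification — the screen is
  deliberately a stratified cross-tabulation; use it to rank hypotheses,
  not to estimate causal effects.
* The reference list is recall-oriented and known-incomplete, so
  precision is undefined and not reported.
* The chi-squared far tail is trusted only where expected counts reach
  the cell rule; at registry scale this is immaterial, at small cohort
  sizes it censors many young age groups for type 1 analyses.
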