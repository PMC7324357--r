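---
title: "Methods: DELTA-P score validation, statistics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DELTA-P score validation, statistics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltap)
```

## The clinical problem

Lambert-Eaton myasthenic syndrome (LEMS) is an autoimmune disorder of the
neuromuscular junction mediated by antibodies against P/Q-type voltage-gated
calcium channels (VGCC). Roughly half of LEMS patients harbour a small-cell
lung cancer (SCLC) driving the autoimmune response, and early tumour
detection improves survival, so every newly diagnosed LEMS patient enters an
intensive PET/CT screening programme. The DELTA-P score stratifies that
programme: it sums six binary clinical items assessed within three months of
symptom onset —

| Item | Definition | Cut-off |
|------|------------|---------|
| D | bulbar/neck weakness | present |
| E | erectile dysfunction (males) | present; females scored 0 |
| L | weight loss | ≥ 5 % |
| T | tobacco use at LEMS onset | current |
| A | age at onset | ≥ 50 years (inclusive) |
| P | Karnofsky performance score | < 70 (strict) |

giving an integer score 0–6. Higher scores carry a stepwise higher SCLC
risk. The 5-point DLTA-P variant drops item E, whose onset is hard to date
in an elderly, comorbid population. This package implements the full
validation workflow for such a score — scoring, per-score risk, univariable
and multivariable statistics, ROC discrimination, screening schedules — plus
a calibrated synthetic-cohort generator, because no patient-level dataset
for this disease is publicly deposited.

## Scoring rules and missingness

`derive_items()` applies the cut-offs exactly as printed above: age is
inclusive at 50, Karnofsky strict at 70, and item E is forced to 0 for
female patients regardless of the recorded field, so women are fully
scoreable on the 6-point scale. When both the raw Karnofsky value and the
dichotomised `karnofsky_lt70` flag are present they must agree; a
contradiction is an error naming the patient, never a silent choice.

A missing item makes the score undefined (`NA`) rather than being imputed
as 0: imputing "absent" would bias scores — and therefore screening
intensity — downward, the unsafe direction. Every analysis excludes
unscoreable patients listwise and reports how many were excluded. The
DLTA-P variant removes E from both the sum and the missingness accounting,
so a patient missing only E still receives a 5-point score. By
construction `deltap - dltap` equals the E item wherever both are defined,
which the test suite checks on fuzzed cohorts.

The three-month onset window is a property of data collection, not of the
scoring arithmetic: the cohort file records whether each feature was present
within the window, and the package treats that flag as authoritative.

## Statistical primitives

The estimators the validation relies on are implemented in the package and
each is cross-checked in the test suite against an independent route
(enumeration oracles, closed forms, and the reference implementations in
`stats`, `survival` and `pROC`):

* **Fisher's exact test** (`fisher_exact()`): two-sided p by
  probability-mass summation over the hypergeometric support, with a
  relative slack of 1e-7 when comparing table probabilities to the observed
  one — the convention of mainstream clinical software. The odds ratio is
  the cross-product ratio with a Woolf log-normal interval; zero cells get
  the Haldane–Anscombe 0.5 correction and are flagged. Tables with an empty
  margin are rejected as degenerate.
* **Mann–Whitney U** (`mann_whitney()`): exact two-sided p by the
  shift-algorithm null distribution when the pooled sample is ≤ 20 with no
  ties; otherwise a normal approximation with tie-corrected variance and a
  0.5 continuity correction. Fully degenerate data (all values identical)
  return p = 1.
* **Logistic regression** (`logistic_fit()`): Newton/IRLS from zero start,
  convergence at score-norm < 1e-8, at most 50 iterations, with large steps
  damped to length 10. Wald 95 % limits (LCL/UCL) match the presentation of
  clinical multivariable tables. Constant covariates and
  complete/quasi-separation (diverging coefficients or exploding standard
  errors) raise structured errors naming the covariate.
* **Median with exact CI** (`median_with_ci()`): the symmetric
  order-statistic pair with the largest rank k whose exact binomial coverage
  is ≥ 95 %. Below n = 6 no such pair reaches 95 %, so the whole range is
  returned with a warning.
* **Kaplan–Meier and log-rank** (`km_curve()`, `survival_compare()`):
  product-limit curves per group, median at the first time survival reaches
  0.5, and the unstratified two-group log-rank chi-square. No Cox model is
  fitted — the validation reports none.

No multiple-testing correction is applied anywhere, matching the reporting
style of the original analysis; consumers comparing many rows should apply
their own.

## Discrimination analysis

`auc_with_ci()` uses the pairwise (Mann–Whitney) AUC estimator with ties
credited one half — the natural choice for an integer score where ties are
the norm — and the DeLong placement-value variance. The paired comparison
of two scores on the same patients (`compare_auc_paired()`) uses the DeLong
covariance; disjoint subgroups (`compare_auc_independent()`) combine
standard errors in quadrature. Both contrasts are two-sided. DeLong's
estimator is used rather than the older table-based Hanley–McNeil
correlation because it is its consistent nonparametric successor and the de
facto standard for correlated ROC areas; this is a deliberate, documented
choice of method.

`analytic_auc_from_item_probs()` computes the exact score distribution per
group by convolving six independent Bernoulli items (dynamic programming
over the 7 score states) and returns the exact AUC
P(S_case > S_control) + ½ P(equal). It serves as the analytic oracle for
the empirical estimator: large simulated cohorts from the generator must
converge to it, and the test suite verifies agreement with a 10^6-draw
Monte-Carlo estimate within 0.003.

## The per-score risk table and item performance

`risk_table()` divides SCLC count by total count at each score, attaching
Wilson 95 % intervals — chosen over Wald intervals because per-score strata
are small (a handful of patients at the extremes) and Wilson keeps sensible
coverage there. An empty stratum has an *undefined* risk, never 0: "no
patients scored 6" and "patients scoring 6 never had SCLC" are different
statements. Dichotomised fractions (scores 0–1; 3 and above) summarise how
much of the cohort falls in the low- and high-intensity screening strata.

`item_performance()` classifies each patient, per item in turn: a 1 in an
SCLC patient or a 0 in a cancer-free patient is correct; the other two
cells are incorrect. Percentages are of the whole cohort, as in the
published table. `compare_items()` then tests each item's correct/incorrect
totals against the pooled totals of the other five with a two-sided Fisher
test and flags the lowest-accuracy item. The published analysis states that
the E item performed significantly worse than the rest but not *how* that
was tested; item-vs-pooled-rest on the correct/incorrect totals is this
package's interpretation, chosen because it uses only quantities the
performance table itself defines. It reproduces the qualitative finding
(E is the weakest item, p < 0.01 on the published counts) though not
necessarily the exact printed p-value.

## Screening schedules

All patients are scanned at month 0. Scores 0–1 get one repeat at 6 months;
score 2 gets six-monthly scans to 24 months; scores 3–6 get a repeat at 3
months "then every six months for two years". That last phrase is ambiguous:
counted from the month-3 scan it gives 9, 15, 21 (ending at the 24-month
horizon); restarted on the calendar grid it gives 6, 12, 18, 24. Both
readings are implemented; the offset grid (0, 3, 9, 15, 21) is the default
because it follows the sentence order, and `high_grid = "aligned"` selects
the other. `detection_summary()` reports the empirical fractions of SCLC
tumours confirmed within 6 and 12 months and lists late detections with
their scores — detection times are data, not modelled; scan sensitivity and
tumour growth are out of scope.

## The synthetic cohort generator

No patient-level data accompany the published validation, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, calibrated to the published group-level summaries:

* 87 patients, SCLC prevalence 44/87, male fractions 16/44 (SCLC) and
  17/43 (NT);
* item probabilities equal to the exact published count ratios per group,
  with E drawn for males only (9/16 and 8/17) and forced to 0 in females;
* ages integer-uniform within the published group ranges, on the side of 50
  matching the drawn A item (the resulting group medians sit within a few
  years of the published 65 and 58);
* VGCC positivity 42/44 and 36/43; titres log-normal around the published
  medians 448 and 209 pM with log-SD 1.0 — the published table prints only
  medians, so the spread is an explicit generator choice;
* survival exponential with medians 15.6 (SCLC) and 50 (NT) months,
  administratively censored at 100 months (the upper end of the published
  follow-up range); NT follow-up uniform on 36–100 months, respecting the
  3-year cancer-free requirement;
* SCLC tumour-detection times from a fixed mixture — 91 % log-normal
  centred on 0.5 months (log-SD 0.6), 7 % uniform on 6–12 months, 2 %
  uniform on 12–30 months — whose population fractions within 6 and 12
  months are exactly the published 91 % and 98 %.

Items are conditionally independent given group by default, because the
publication constrains only the marginals. A latent-severity Gaussian
copula (`rho > 0`) is available to stress-test the statistics under
within-patient dependence; it thresholds correlated latent normals at the
same marginal probabilities, so item frequencies are preserved. Under
independence, conditional independence of items given group makes the true
SCLC posterior exactly logistic with coefficients equal to the per-item
log odds ratios — which is what makes the multivariable parameter-recovery
tests well-posed.

What the generator does *not* emulate: the true joint distribution of items
within patients (not identifiable from the published per-score risks),
site/centre effects, secular trends, and any correlation between titre,
survival and the clinical items. Passing tests on simulated cohorts
therefore demonstrate the correctness of the estimators and pipeline under
the published marginal structure, not the reproduction of the original
cohort's joint behaviour — in particular the published empirical AUC of
82.5 % reflects that unknown joint, while the analytic AUC implied by
independent items at the published marginals is 86.6 %.

`fixture_table1()` complements the stochastic generator with a fixed,
RNG-free 87-patient cohort whose per-group marginal counts equal every
published binary row exactly. The joint structure — unconstrained by the
publication — is fixed by a documented rotation: item j is assigned to its
k_j patients at positions offset_j + i·step_j (mod group size), with
offsets staggered and strides coprime to both group sizes so the item
combinations are spread rather than blocked. Survival and detection fields
are deterministic spreads whose Kaplan–Meier medians equal the published
15.6/50 months and whose detection fractions are the published 91 %/98 %
with median 0.5 months. This fixture is what the end-to-end determinism
checks and the acceptance script run on.

One published inconsistency is deliberately left unreconciled: the item-A
row of the published item-performance table (42 + 16 correct) disagrees
with the age counts of the clinical summary table (40/44 and 30/43), so the
fixture — built on the summary-table marginals — yields 53 correct for A,
not 58. The accuracy arithmetic itself is verified on the printed counts
directly. Similarly, two printed univariable p-values (both impotence rows,
and the weight-loss row's 0.0006) cannot be reproduced by any standard
two-sided Fisher test on the printed counts; the implementation is not
tuned to match them.

## Numerical choices and degenerate inputs

* Percentages print as whole numbers using two-stage half-up rounding (one
  decimal, then integer), which reproduces every percentage in the
  published tables (e.g. 26/43 → 60.5 % → 61 %); full precision is retained
  in all JSON output.
* p-values are never truncated or floored in computation; comparisons to
  published values account for the publication's apparent truncation (e.g.
  a computed 0.0158 printed as 0.015).
* Fisher's probability comparison uses the 1 + 1e-7 relative slack;
  without it, floating-point noise drops equal-probability tables from the
  two-sided sum.
* Degenerate inputs fail loudly and specifically: empty margins, all-one
  outcomes, constant covariates, separation, no events, single-class ROC
  labels. `run_validate()` converts such failures into structured
  "unavailable" report sections with the reason, so one degenerate
  subgroup cannot sink an entire report.
* Reports carry a manifest (package version, options, an FNV-1a hash of the
  input) and contain no timestamps, so identical inputs produce
  byte-identical bundles.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on generated data at
deliberately modest sizes: exhaustive Fisher enumeration over all 2×2
tables with total ≤ 40; generator frequency recovery and analytic-AUC
convergence at n = 50,000; the Monte-Carlo AUC oracle at n = 10^6;
bootstrap comparison of the DeLong variance with 2,000 resamples at the
study size n = 87; and power-style properties (titre separation, log-rank,
multivariable recovery) at the study's group sizes across 10–20 fixed
seeds. These sizes were chosen to make sampling noise negligible relative
to each tolerance while keeping a full run in about a minute.

## Known limitations

* The score's item weights are taken as fixed and equal; re-deriving
  weights from new data is explicitly out of scope.
* The screening-schedule evaluation treats detection times as given; it
  cannot say whether a different schedule would have found tumours earlier.
* Wald intervals for logistic odds ratios degrade near separation; the fit
  reports separation rather than returning untrustworthy intervals.
* The paired AUC contrast assumes large-sample normality of the DeLong
  statistic; at n well below the study size its p-values are approximate.
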