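---
title: "Validating the EGSYS syncope score: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the EGSYS syncope score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egsys)
```

## The rule and its two weight sets

EGSYS is an additive integer score over bedside clinical items, designed
to separate cardiac from noncardiac syncope. The package implements both
published weight sets. The univariate variant (EGSYS-U) scores ten items,
including two "absence" items (+1 for no precipitating/predisposing
factors, +1 for no prodromes) and four negatively weighted vasovagal-type
features; it spans [−6, 11]. The multivariate variant (EGSYS-M) scores six
items and spans [−2, 12]. A total of **3 or more** (boundary inclusive)
flags the patient as at risk of a cardiac cause; `coef()` on a fitted
validation object prints both columns.

Two readings of the published table needed a decision:

* **Co-occurring negative items are summed.** Blurred vision (−1) and
  autonomic prodromes (−2) can both apply to one patient in EGSYS-U; the
  rule is described as a plain sum and no exclusivity is stated, so the
  scorer sums them. The theoretical minimum of −6 requires all four
  negative items at once.
* **Effort and supine syncope are standalone indicators.** EGSYS-M weights
  them separately (+3/+2) while EGSYS-U scores their union (+2). The data
  model carries both as top-level booleans, authoritative for scoring; the
  CSV reader fills them from the precipitating-factor codes
  (`syncope_during_effort`, `syncope_supine`) only when the booleans are
  absent. The scorer allows both to be true (3+2), but the generator never
  co-produces them — one faint has one position/activity.
* **Age is strictly greater than 64**, and the combined
  ECG/cardiopathy item is true if either half is.

An exhaustive enumeration over all 640 reachable indicator patterns
(7 free booleans × 5 prodrome states) is tested against an independently
transcribed weight table; it fixes the ranges above and caught a real
operator-precedence bug during development, which is why the suite keeps
the enumeration rather than a handful of spot checks.

## The synthetic cohort generator

No patient-level data are deposited for the validation study the package
mirrors, so `simulate_cohort()` generates cohorts with the two-class
statistical structure the analysis assumes. Its defaults *are* the study
conditions: n = 198, cardiac prevalence 115/198, and class-conditional
item frequencies taken from the published cardiac-vs-noncardiac
comparison, e.g. palpitations/dyspnea 51/115 vs 8/83, abnormal
ECG/cardiopathy 101/115 vs 32/83, age > 64 in 67/115 vs 20/83.

Choices where the published tables underdetermine the model:

* **Conditional independence given class.** Only marginal per-class counts
  are published, no correlation structure; independence is the
  maximum-entropy completion. Consequences are discussed below.
* **Prodrome state as one categorical draw.** "No prodromes", blurred
  vision and autonomic prodromes are jointly constrained (autonomic
  prodromes require a non-empty prodrome set). Each class draws one of
  {none, blurred only, autonomic only, blurred+autonomic, other}. In the
  noncardiac class the published marginals (9 none, 29 blurred,
  49 autonomic of 83) force at least 4 patients with blurred *and*
  autonomic prodromes; the default uses exactly that minimal overlap.
  The autonomic split (18/115 vs 49/83) is the one consistent with the
  published odds ratio near 0.13.
* **Effort/supine class splits.** The published supine row (9 patients
  overall) has no recoverable class split; the default uses 7/115 vs 2/83,
  and effort 29/115 vs 22/83, which reproduce the overall counts and an
  effort odds ratio near 0.94. Both are configurable.
* **Cardiopathy is not simulated separately.** The combined
  ECG/cardiopathy item is realised as a single random ECG finding; the
  published tables never separate the cardiopathy-only presentation.
* **Ages** are a two-point mixture: uniform on 18–64 or 65–95 according to
  the age item. Only the >64 indicator matters downstream.

Under a fixed `seed` generation is bit-reproducible and leaves the
caller's RNG stream untouched.

### What the generator does and does not emulate

Parameter-recovery tests (n = 2×10⁵, every class-conditional frequency
within 4 standard errors) and plug-in odds-ratio convergence show the
generator hits its calibration. But independence between items is a real
simplification: in patients, abnormal ECG, age and effort syncope are
positively correlated within class, which makes the items partially
redundant. Under independence every item contributes fresh information, so
the ten-item EGSYS-U is strictly more informative than the six-item
EGSYS-M here (population AUC ≈ 0.864 vs ≈ 0.820 at n = 2×10⁵), and the
paired DeLong comparison rejects equality in most study-sized cohorts —
whereas the real validation cohort showed nearly identical AUCs
(0.818 vs 0.805, p = 0.53). Passing tests therefore demonstrate correct
*machinery* (calibration, scoring, accuracy statistics), not that the
synthetic cohorts reproduce every between-score contrast seen in real
patients. The directional properties that are robust to this — cardiac
patients outscore noncardiac ones, AUCs well above chance, Youden optimum
at 3 in the majority of seeds for both variants — are asserted across
100 seeds.

## Diagnostic statistics

All screening statistics are computed from explicit confusion-matrix
counts with the positive rule *score ≥ cut-off*.

* **Proportion intervals**: Wilson score interval by default (closed
  form; well-behaved at extreme proportions), exact Clopper–Pearson via
  beta quantiles, and Wald for completeness. The validation study does not
  state its CI method and its printed intervals match no standard method
  exactly, so printed CIs are never asserted; the Wilson bounds are
  instead verified against an independent root-solve of the score-test
  inequality.
* **Likelihood ratios, two conventions.** The standard forms are
  sens/(1−spec) and (1−sens)/spec with Simel log-method intervals. The
  validation table the package mirrors prints, under the "likelihood
  ratio" heading, the *posttest odds* PPV/(1−PPV) and (1−NPV)/NPV — a
  prevalence-dependent quantity. Both are computed and labelled;
  reproducing the published table requires the odds form, correctness
  requires the standard form. One published PPV row (57.00 with an
  interval of 66.84–81.75) is internally impossible; the matrix-consistent
  value of 75.00 is what the package reports.
* **2×2 tables**: odds ratio by the cross-product with Woolf logit
  intervals (Haldane 0.5 on zero cells, opt-in); association p-values by
  Pearson chi-square without continuity correction, Fisher's exact by
  flag. Counts are coerced to double before the cross-product so large
  simulated tables cannot overflow integer arithmetic.
* **ROC and AUC**: thresholds sweep every observed score plus ±∞
  sentinels, so the curve always carries (0,0) and (1,1). The trapezoidal
  area is tested to equal the O(n²) Mann–Whitney concordance (ties ½)
  exactly, and against pROC as an external cross-check.
* **DeLong comparison**: midrank placements per score, 2×2 covariance of
  the placement vectors, normal test on the AUC difference. Identical
  scores give p = 1 by construction (zero variance is treated as no
  evidence of difference, not an error). The null distribution of
  p-values is checked for uniformity (KS < 0.05 at 2000 replicates) and
  the variance against a bootstrap oracle.
* **Youden cut-off**: maximises tpr − fpr over finite thresholds; ties
  break toward the *higher* threshold, which minimises false positives at
  equal J. The published analysis does not state its tie rule.
* **Sample size**: `n = z² p(1−p)/d²`, truncated by default — the mode
  that reproduces the published planning figure of 138 at
  (0.90, 0.05, 95%); `ceiling` is available and gives 139.

## The validation pipeline

`egsys_validation()` scores all patients first and only then excludes the
unknown-origin ones from accuracy denominators, so excluded patients'
scores still appear in the per-patient file and the run log summarises
them (mirroring how such exclusions are reported in practice). Welch's
t-test backs the mean-score comparison — the original analysis names no
test; Welch avoids the equal-variance assumption, which visibly fails
between classes here. Single-class and all-unknown cohorts abort with a
diagnostic rather than returning degenerate statistics.

`write_validation()` persists six files (per-patient scores, item table,
accuracy JSON, ROC points, summary JSON, run log) with fixed column
order, LF line endings and no timestamps, so identical inputs produce
byte-identical bundles — the property the determinism tests assert.

## Problem sizes used by the test-suite

Simulation-backed checks run at sizes chosen to make sampling error
negligible relative to the asserted tolerances while keeping the suite
quick: parameter recovery at n = 2×10⁵; interval coverage at 10⁴
replicates per (p, n) cell; DeLong null uniformity at 2×10³ replicates of
70-patient cohorts; AUC–concordance equivalence up to n = 500; the
stochastic directional properties at 100 seeds of the study size n = 198.

## Known limitations

* Item independence given class, as discussed: contrasts *between* the
  two score variants on synthetic cohorts are systematically sharper than
  in real data.
* The generator does not simulate vital signs, follow-up, or the
  unknown-origin exclusion process; unknown-diagnosis handling is
  exercised by tests that relabel patients.
* Weights are constants of the rule; the package deliberately does not
  refit them, and no outcome/mortality modelling is included.
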