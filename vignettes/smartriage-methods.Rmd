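---
title: "Evaluating ordinal sepsis triage scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ordinal sepsis triage scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartriage)
```

## The scores

Both scores in this package are sums of inclusive one-point criteria
evaluated on vital signs measured at emergency-department triage.

The **S-S.M.A.R.T** score (0--4) awards one point for each of:

| component | quantity | criterion |
|---|---|---|
| shock | shock index = HR / SBP | >= 1.0 |
| mental status | Glasgow Coma Scale total | <= 14 |
| age | age in whole years | >= 65 |
| respiratory failure risk | ROX index = (SpO2 / FiO2) / RR | <= 10 |

The shock index replaces a static blood-pressure cutoff with a dynamic
measure of circulatory compromise; the ROX index folds oxygen saturation,
oxygen requirement and respiratory rate into one quantity, so a patient
breathing fast on high-flow oxygen with borderline saturation is flagged
even when each vital alone looks tolerable. The **qSOFA** comparator (0--3)
is operationalised with the Sepsis-3 conventions — respiratory rate >= 22
breaths/min, systolic blood pressure <= 100 mmHg, GCS <= 14 — because the
bedside definition names the three components without fixing numeric
thresholds; these are the values every published validation uses.

Numerical conventions worth stating:

* All threshold comparisons are **inclusive** and applied to the derived
  quantity at full floating precision; the shock and ROX indices are never
  rounded before comparison.
* SpO2 enters as a percentage and FiO2 as a fraction (0.21--1.0). An FiO2
  above 1 is rejected with a unit-mistake hint rather than rescaled,
  because a silently accepted "21" would shift the ROX index a hundredfold.
* A missing FiO2 is taken as room air (0.21), with a logged note; charts
  routinely omit FiO2 for patients not on supplemental oxygen. No other
  vital is imputed: cohort scoring is complete-case with a per-record
  exclusion report.
* Non-integer ages are floored to whole years.

## ROC analysis for heavily tied scores

An integer score on a few hundred patients puts dozens of patients on each
value, so the empirical ROC curve has a handful of vertices and the usual
"probability a random event outranks a random non-event" definition needs a
tie rule. `auc_midrank()` uses the midrank convention — ties credit half —
which is the quantity the trapezoidal area under the tied ROC curve
computes, and the only convention under which AUCs published from grouped
ordinal data can be reproduced from the group counts. `roc_curve()` returns
one vertex per distinct cutoff (predicting an event when score >= cutoff)
plus the (0, 0) endpoint, and its trapezoidal area equals the midrank AUC
to machine precision, which the tests assert.

Variance and confidence intervals follow DeLong's nonparametric estimator
built from placement values, computed via midranks in O(n log n).
Intervals are normal-theory on the AUC scale and clipped to [0, 1];
implementations that use logit or other transforms can differ in the third
decimal, which is why the package reports the interval method explicitly.
`delong_test()` performs the paired comparison of two scores on the same
patients from the covariance of their placement values; identical score
vectors give z = 0, p = 1 by construction, and all p-values are two-sided.

Operating points are reported at every observed cutoff as percentages
(sensitivity, specificity, PPV, NPV) rounded to one decimal place only in
the display and CSV layers; internal values stay unrounded. Because no
selection rule for a "best" cutoff is universal, `evaluate_cohort()`
reports all cutoffs and flags the Youden optimum (maximal
sensitivity + specificity − 1, ties broken toward the higher, more
specific cutoff) rather than silently choosing one.

Association between score level and outcome uses the Pearson chi-square
test without Yates continuity correction — the convention for multi-level
score-by-outcome tables. Cells with expected counts below 5 are counted
and reported but do not switch the test to an exact alternative; Fisher's
exact test is out of scope here.

## The grouped reference cohort

The package bundles, in grouped form, a 401-patient emergency-department
suspected-sepsis cohort: per-score patient counts for both scores, the
overall outcome totals (30 deaths by day 7, 53 by day 30, 116 ICU
admissions), and per-score outcome rates printed to one decimal place.
Because an ordinal score's ROC analysis depends on the data only through
the per-score event and non-event counts, this grouped information
determines every AUC, operating point and stratified rate exactly —
patient-level records are unnecessary for reproducing them.

`reference_cohort()` reconstructs integer event counts as
round(rate × n) per stratum, then applies a largest-remainder repair
against the declared outcome total, failing loudly if any cell would have
to move by more than one count. For this cohort all six (score × outcome)
reconstructions reconcile exactly with no repair at all, which the
construction asserts; the repair path exists so that other grouped tables
with genuinely ambiguous rounding still reconstruct deterministically or
fail visibly instead of drifting.

Two published quantities are deliberately **not** reproduced. The paired
DeLong p-values comparing the two scores require the joint distribution of
(S-S.M.A.R.T, qSOFA) across patients, which grouped marginals do not
determine; `evaluate_reference()` therefore carries an empty comparison
block with a note, while patient-level evaluations compute the paired test
normally. Likewise the published AUC confidence intervals depend on
patient-level covariance structure only partially pinned down by the
margins; the package computes DeLong intervals from the reconstruction and
the tests check internal validity (interval brackets the estimate, valid
p-value behaviour) rather than agreement with printed interval endpoints.

## The synthetic vitals simulator

`simulate_cohort()` exists to give the scoring pipeline realistic-shaped
patient-level input whose score distribution is known exactly. For each
patient in a stratum targeting score *s*, a uniformly random subset of *s*
of the four criteria is chosen, and each vital is drawn uniformly from a
range that cleanly satisfies or cleanly fails its criterion (for example,
a satisfied shock criterion draws SBP in 70--100 mmHg and HR at or above
SBP; a failed ROX criterion draws room-air FiO2 with SpO2 94--100% and RR
10--20). The satisfied and unsatisfied ranges are disjoint in the derived
quantity, so re-scoring provably lands in the intended stratum — the
generator still re-scores and asserts. Outcomes are assigned to random
patients within each stratum with 7-day deaths nested inside 30-day deaths
(a death within 7 days is a death within 30); ICU admission is drawn
independently of death because no joint death-ICU distribution is targeted.

What the simulator does **not** emulate: physiological correlation between
vitals (a septic patient's tachycardia and tachypnoea co-occur; here they
are independent draws), measurement error, missingness patterns, or any
relationship between vital values and outcome *within* a score stratum.
Tests passing on simulated cohorts therefore demonstrate the correctness
of the scoring and evaluation machinery, not clinical validity on real
triage data.

Determinism: a single integer seed (default 20230810) drives all sampling;
the generator saves and restores the caller's RNG state, and identical
specifications produce byte-identical cohorts.

## Problem sizes and defaults

The default simulation targets are the reference cohort's strata
(50/172/102/51/26 patients over scores 0--4, 401 in total) with its
reconstructed per-stratum event counts — the study conditions themselves,
not a tuning knob. Property-style tests run the AUC implementation against
an exhaustive pair-counting oracle on a thousand random instances of up to
200 observations, and the simulation round-trip on dozens of random
specifications of up to ~150 patients; these sizes make the full suite run
in well under a minute while exercising every tie pattern an integer score
can produce.

## Known limitations

* Complete-case handling only; no imputation of missing vitals.
* No bootstrap or transformed AUC intervals, partial AUC, time-dependent
  ROC, calibration analysis, or trend (Cochran–Armitage) tests.
* The chi-square test is always the asymptotic Pearson form; sparse tables
  are flagged, not re-tested exactly.
* The simulator's uniform, independent vitals are a scoring-level
  emulation, not a physiological model.
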