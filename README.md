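# smartriage

Sepsis triage scores and their evaluation, for emergency-medicine and
biostatistics users who need to compute, validate or compare simple
ordinal risk scores built from triage vital signs.

## What it computes

The **S-S.M.A.R.T** score assigns one point for each of four criteria
measured at emergency-department triage:

| criterion | quantity | threshold |
|---|---|---|
| Shock | shock index = HR / SBP | ≥ 1.0 |
| Mental status | Glasgow Coma Scale | ≤ 14 |
| Age | whole years | ≥ 65 |
| Respiratory risk | ROX index = (SpO₂/FiO₂)/RR | ≤ 10 |

giving a score of 0–4, with **qSOFA** (RR ≥ 22, SBP ≤ 100 mmHg, GCS ≤ 14;
0–3) as the standard comparator. Around the scores sits the full
evaluation pipeline for tied ordinal predictors:

* **midrank AUC** — Pr(event score > non-event score) + ½ Pr(tie), the
  only AUC convention reproducible from grouped ordinal data — with
  DeLong variance and a Wald confidence interval clipped to [0, 1];
* **paired DeLong tests** comparing two scores on the same patients;
* **operating points** (sensitivity, specificity, PPV, NPV with the 2×2
  counts) at every score cutoff, with the Youden optimum flagged;
* **score-stratified outcome rates** and Pearson **chi-square**
  association tests (no continuity correction);
* **grouped-table expansion**: published per-score patient counts and
  outcome rates are reconstructed into exact patient-level
  (score, outcome) data — the package bundles a 401-patient
  emergency-department suspected-sepsis reference cohort in this form;
* a deterministic **vitals simulator** whose output re-scores exactly
  into requested score strata.

## Worked example

```r
library(smartriage)

# one patient: elderly, shocky, drowsy, hypoxic on 40% oxygen
smart_score(list(age = 70, heart_rate = 120, sbp = 90, gcs = 13,
                 spo2 = 90, fio2 = 0.40, resp_rate = 30))
#> [1] 4

# the bundled reference cohort, grouped by S-S.M.A.R.T score,
# expanded to patient-level (score, outcome) pairs for 7-day death
so <- expand_grouped(reference_cohort("smart"), "died_7d")

auc_midrank(so$score, so$label)
#> AUC 0.789 (95% CI 0.721-0.858), 30 events / 371 non-events

operating_point(so$score, so$label, 2)
#> Cutoff >=2: sens 90.0%, spec 59.0%, PPV 15.1%, NPV 98.6% (TP 27, FP 152, TN 219, FN 3)

stratified_rates(so, "score", "label")
#>   score   n events rate
#> 1     0  50      0  0.0
#> 2     1 172      3  1.7
#> 3     2 102     11 10.8
#> 4     3  51     10 19.6
#> 5     4  26      6 23.1
```

An AUC of 0.789 means a randomly chosen 7-day death scores higher than a
randomly chosen survivor about 79% of the time (ties counted half). At the
cutoff of 2 or more points the score catches 90% of the deaths while
clearing 59% of survivors; the 98.6% NPV is what makes a low score
reassuring at triage. The full six-block evaluation (both scores × three
outcomes), with Youden cutoffs and chi-square association:

```r
evaluate_reference()
#> Score evaluation: 6 block(s)
#>   smart  vs died_7d    AUC 0.789 (0.721-0.858), Youden cutoff >=2, chi-square p = 8.18e-07
#>   smart  vs died_30d   AUC 0.786 (0.728-0.844), Youden cutoff >=2, chi-square p = 2.22e-11
#>   smart  vs icu_admit  AUC 0.758 (0.708-0.809), Youden cutoff >=2, chi-square p = 1.04e-16
#>   qsofa  vs died_7d    AUC 0.699 (0.606-0.793), Youden cutoff >=2, chi-square p = 0.000402
#>   qsofa  vs died_30d   AUC 0.681 (0.610-0.752), Youden cutoff >=1, chi-square p = 0.000109
#>   qsofa  vs icu_admit  AUC 0.717 (0.666-0.768), Youden cutoff >=1, chi-square p = 1.77e-11
```

## Command line

The installed `exec/smartriage` script (or `smartriage_cli()`) exposes
three deterministic subcommands:

```sh
smartriage simulate --seed 42 --out runs/sim          # cohort.csv + metadata
smartriage score    --input runs/sim/cohort.csv --out runs/scored
smartriage evaluate --fixture reference --reproduce-reference --out runs/eval
```

`evaluate` writes `report.json` (full precision, the source of truth) plus
`report_operating_points.csv` and `report_rates.csv`; with
`--reproduce-reference` it also diffs every computed AUC and
operating-point cell against the bundled expected performance table and
fails on any mismatch.

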