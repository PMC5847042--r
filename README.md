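# pathies

Prognostic scoring and survival validation for ER-positive breast cancer
cohorts that switched adjuvant endocrine therapy.

## What it does

Postmenopausal women who remain disease-free after 2-3 years of adjuvant
tamoxifen must decide whether to extend endocrine therapy. The IHC4 score
summarises four routine immunohistochemical markers into one prognostic
index for distant recurrence:

    IHC4 = 94.7 x ( -0.100 ER_H/30 - 0.079 PgR/10
                    + 0.586 1[HER2 = 3+] + 0.240 ln(1 + 4 Ki67) )

with ER as the H-score (0-300), PgR and Ki67 as percent positivity, and
HER2 positive only at IHC 3+. Adding a clinical score over nodal status,
tumour size, grade and age >= 65 gives IHC4+C; a refitted "PathIES"
variant re-estimates the combined model for the switch population
(treatment, nodes, size and 0.0048 x IHC4). All scores are 100 x the Cox
linear predictor.

The package computes these scores from a patient-level cohort table,
stratifies each into quartile risk groups (Q1 / Q2-Q3 / Q4), and validates
their prognostic value against time to distant recurrence (TTDR: distant
recurrence or death from breast cancer/unknown cause; everything else
censors): Kaplan-Meier curves, log-rank tests, Cox hazard ratios by risk
group, univariable and backward-selected multivariable Cox models with
treatment forced in, a treatment-by-risk-group interaction test, and a
decile calibration plot of predicted vs observed 10-year distant-recurrence
probabilities (predicted risk = 1 - S0(t)^exp(score/100)).

Because no patient-level data are deposited for this population, a
calibrated synthetic-cohort generator (`generator_config()`,
`generate_cohort()`) reproduces the published cohort structure — marker
prevalences, IHC4 distribution, clinical frequencies, missingness,
event counts — with planted ground truth, so the entire pipeline is
testable end to end. It is intended for methods work and pipeline
validation, not as a substitute for real cohorts.

## Worked example

```r
library(pathies)
x <- generate_cohort(generator_config(seed = 1))   # 430-patient cohort
report <- run_pipeline(x$cohort)
print(report)
```

```
PathIES prognostic analysis report
  pathies 0.1.0; R 4.3.3; survival 3.8.3
  seed: 1
  alpha: 0.1; horizon: 120 months
  rows: input 430 = eligible 430 + excluded 0
  complete clinical cases: 357
  TTDR events: 84 (complete cases: 66)

Hazard ratios by quartile risk group (vs Q1):
 variant term   n    HR     95% CI       P
    ihc4 Q2Q3 430  1.59  0.85-2.97 1.5e-01
    ihc4   Q4 430  2.45  1.28-4.70 6.9e-03
   ihc4c Q2Q3 357  3.62 1.27-10.36 1.6e-02
   ihc4c   Q4 357 10.99 3.90-30.95 5.7e-06
 pathies Q2Q3 357  1.70  0.78-3.74 1.8e-01
 pathies   Q4 357  4.18  1.91-9.12 3.3e-04

Treatment x risk-group interaction: P = 0.68
```

Reading this: IHC4 alone separates the top quartile (HR 2.45 vs Q1) on all
430 eligible patients; adding the clinical score sharpens the separation
(HR 11.0) on the 357 complete cases; there is no evidence the treatment
effect differs across risk groups (interaction P = 0.68). The hazard in
this simulated cohort is driven by the combined score, which is why the
ihc4c rows separate most strongly. `report$calibration` holds the
predicted-vs-observed decile table, `report$multivariable` the
backward-selected Cox model (treatment forced), and `write_report(report,
dir)` serialises every table to CSV. A thin command-line wrapper lives at
`inst/cli/pathies_cli.R` (subcommands `all`, `score`, `simulate`).

Individual patients:

```r
ihc4_score(180, 50, "2+", 13)                      # -3.99
clinical_score(70, "Ngt3", 4.0, "G3")              # 429.834
pathies_score(100, "Ngt3", 4.0, "switch_to_exemestane")  # 401
```

The cohort-table schema is documented in
`system.file("extdata/data_dictionary.csv", package = "pathies")`.

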