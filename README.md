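# luscab

Validation toolkit for the **LUSCAB score** — a bedside prognostic score
combining **L**ung **U**ltra**S**ound findings, **C**linical data and
**A**ge in infant **B**ronchiolitis — built for emergency-department
decision support: ruling out the need for escalated respiratory support
(nCPAP/nBiPAP/invasive ventilation) in infants under six months.

The score is additive over six items:

| Item | Points |
|---|---|
| Age < 1 month | 1.5 |
| >3 B-lines per intercostal space, bilateral, anterior | 1.5 |
| Confluent B-lines, bilateral, anterior | 1 |
| Posterior subpleural consolidation < 1 cm | 1 |
| Posterior subpleural consolidation ≥ 1 cm | 3 |
| Modified Wood–Downes–Ferres (WDF) score ≥ 6 | 2.5 |

A total of **≥ 3.5 points flags high risk**; below 3.5 is the rule-out
side.  The WDF component is the six-item clinical severity score
(wheezing, retractions, respiratory rate, heart rate, inspiratory breath
sounds, cyanosis; total 0–14, mild ≤ 3 / moderate 4–7 / severe 8–14).

The package provides, in plain R:

* score calculators (`wdf_score`, `wdf_band`, `luscab_score`,
  `classify_high_risk`, `score_cohort`) with exact half-point arithmetic;
* diagnostic accuracy at a cutoff (`confusion_at_cutoff`,
  `diagnostic_stats`), empirical ROC with the Mann–Whitney AUC and DeLong
  95% CI (`roc_auc`), and reconstruction of 2×2 tables from published
  Se/Sp (`reconstruct_confusion`);
* Kaplan–Meier time-to-respiratory-support and the log-rank test
  (`km_fit`, `km_survival_at`, `logrank_test`);
* cohort descriptives and univariate comparisons (`summarize_numeric`,
  `compare_groups`, `compare_categorical`, `spearman_correlation`);
* a calibrated latent-severity **synthetic cohort generator**
  (`cohort_config`, `generate_cohort`) emulating the study population's
  marginal structure, so the whole pipeline runs without patient data;
* one-call orchestration (`run_validation`, `run_all`, `write_report`,
  `check_report`) and a thin CLI (`inst/cli/luscab`) with subcommands
  `score` / `describe` / `validate` / `survival` / `simulate` / `run-all`.

## Worked example

Simulate a 50-infant cohort from the calibrated generator, score it, and
run the full validation:

```r
library(luscab)
report <- run_all(n = 50, seed = 1)
report
#> Validation report: n = 50, cutoff 3.5 points
#>   LUSCAB median 2.50 (IQR 1.00-4.88)
#>   admission: AUC 0.71 (0.56-0.86), Se 48.6%, Sp 93.3%, PPV 94.4%, NPV 43.8%
#>   oxygen_therapy: AUC 0.78 (0.63-0.92), Se 68.4%, Sp 83.9%, PPV 72.2%, NPV 81.2%
#>   respiratory_support: AUC 0.87 (0.76-0.98), Se 80.0%, Sp 82.9%, PPV 66.7%, NPV 90.6%
#>   ncpap_bipap_mv: AUC 0.80 (0.51-1.00), Se 80.0%, Sp 68.9%, PPV 22.2%, NPV 96.9%
#>   respiratory_support within 24h: event-free 44.4% (>=cutoff) vs 90.6%, log-rank p = 0.000
#>   ncpap_bipap_mv within 24h: event-free 83.3% (>=cutoff) vs 96.9%, log-rank p = 0.094
```

Each accuracy row reads as: discrimination of the LUSCAB score for that
outcome (AUC with DeLong 95% CI), then sensitivity, specificity and
predictive values of the ≥ 3.5-point rule.  The high NPV for the
nCPAP/nBiPAP/MV row is the score's purpose: a low score argues that
escalated support will not be needed.  The survival lines compare
event-free proportions within 24 h between the two cutoff arms by the
log-rank test.  `write_report(report, "report.json")` emits the same
content as JSON (schema in `inst/schema/validation-report.schema.json`).

Published accuracy tables can be audited without patient data:

```r
cm <- reconstruct_confusion(0.875, 0.643, n_pos = 8, n_neg = 42)
cm
#>       event no event
#> test+     7       15
#> test-     1       27
round(100 * diagnostic_stats(cm)$npv, 1)
#> [1] 96.4
```

The same CSV-in/JSON-out workflow is available from a shell via
`inst/cli/luscab`, e.g.
`Rscript inst/cli/luscab run-all --simulate --n 50 --seed 1`.

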