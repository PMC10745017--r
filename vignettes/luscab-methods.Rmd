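---
title: "Methods: the LUSCAB score and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LUSCAB score and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luscab)
```

## The clinical problem

Acute bronchiolitis is the leading cause of hospital admission in infants,
and emergency departments must decide, often during seasonal surges, which
infants can be discharged safely and which are at risk of deteriorating to
the point of needing respiratory support.  Point-of-care lung ultrasound
adds objective information to the clinical examination: interstitial
involvement shows as vertical B-line artefacts (more than three per
intercostal space, or confluent), and small-airway obstruction and
atelectasis show as subpleural consolidations.

The LUSCAB score (Lung UltraSound findings, Clinical data and Age in
Bronchiolitis) combines those findings with the modified
Wood-Downes-Ferres (WDF) clinical score and age into one additive score
used to *rule out* the need for escalated respiratory support
(nCPAP/nBiPAP/invasive ventilation).  This package implements the score
calculators and the complete statistical validation of the 3.5-point
cutoff, together with a calibrated synthetic-cohort simulator so that the
whole pipeline is exercisable and testable without patient-level data
(which were never deposited for the motivating study).

## The scores

The WDF score sums six items: wheezing (0-3), retractions (0-3),
respiratory rate (0-3 points for <=30 / 31-45 / 46-60 / >60 breaths/min),
heart rate (0-1 for <=120 / >120 beats/min), inspiratory breath sounds
(0-3) and cyanosis (0-1), for a total of 0-14 banded as mild (<=3),
moderate (4-7) and severe (8-14).  Two gaps in the published bands (exactly
30 breaths/min and exactly 120 beats/min fall between bands) are closed
downward so a borderline measurement never inflates the score, and a total
of 0, below the printed "1-3 mild" band, is reported as mild because no
lower category exists.

The LUSCAB items and weights are: age under one month, 1.5 points; more
than three B-lines per intercostal space bilaterally in the anterior area,
1.5; confluent B-lines bilaterally anterior, 1; one or more posterior
subpleural consolidations under 1 cm, 1; of at least 1 cm, 3; WDF total of
6 or more, 2.5.  Points are carried internally as integer half-points, so
every total is an exact multiple of 0.5 and the 3.5-point cutoff is always
attainable and unambiguous (`classify_high_risk` is inclusive:
score >= 3.5 is high risk).

Two genuinely open choices are resolved as follows and are configurable
where it matters.  First, the published item table does not say whether the
two consolidation sizes are mutually exclusive; since the other paired
items (the two B-line rows) can clearly co-score, the default policy is
additive (range 0-10.5), with `consolidation_policy = "exclusive_max"`
(only the 3-point item counts when both sizes are present; range 0-9.5)
available throughout.  Second, a consolidation of exactly 1 cm sits between
the printed "<1 cm" and ">1 cm" rows; it is assigned to the 3-point item,
because for a rule-out score a borderline lesion should err toward higher
risk.  Lateral-wall findings, which the scanning protocol records but no
item scores, are ignored.

## Diagnostic accuracy

`confusion_at_cutoff` cross-tabulates test positivity (score at or above
the cutoff) against each outcome; `diagnostic_stats` computes sensitivity,
specificity, PPV and NPV, reporting a zero-denominator ratio as missing
rather than zero.  `roc_auc` returns the empirical ROC curve with
thresholds midway between consecutive distinct scores (plus sentinels), the
AUC — which equals the Mann-Whitney probability with ties counted one half
— and a DeLong 95% confidence interval truncated to [0, 1].  The published
accuracy table does not name its interval method; DeLong's nonparametric
variance is the standard choice paired with an empirical AUC, and the
package's interval is verified in the tests against a hand-coded DeLong
computation.

`reconstruct_confusion` inverts printed summary statistics
(tp = round(Se·n_pos), rounding half away from zero, etc.) back to the
integer 2x2 table.  This is how the package reproduces the published
predictive values exactly: for the top support tier, Se 87.5% and Sp 64.3%
with 8 events among 50 infants reconstruct to (tp, fn, fp, tn) =
(7, 1, 15, 27), whose NPV is 27/28 = 96.4%.  Every reconstructed row of the
published table yields 22 test-positive infants, although the running text
reports 19 infants at or above the cutoff; the package records the
discrepancy (it is in the source material) and takes the table as
canonical.

## Time to respiratory support

Time from emergency-department assessment to support initiation is
analysed with the Kaplan-Meier product-limit estimator and the two-sample
log-rank (Mantel-Cox) test, delegated to the `survival` package behind the
`km_fit` / `km_survival_at` / `logrank_test` interface and cross-checked in
the tests against an independent O/E/V tabulation.  Ties follow the
standard convention (events precede censorings), there is no continuity
correction, and curve evaluation is right-continuous.  The headline
comparison uses a 24-hour horizon (`horizon_h`, configurable): infants
event-free at `min(followup_h, 24 h)` are censored there, and an event
beyond the horizon counts as censored at the horizon.  An infant already on
support at assessment enters as an event at time 0, included in the first
risk set.  Which clock the time origin uses (arrival versus examination) is
the caller's choice; the packaged simulator clocks from the assessment.

## Descriptive statistics

Quantitative variables are summarized as median and interquartile range
(or mean and standard deviation) with quartiles by linear interpolation
between order statistics (type 7); at a cohort size of 50 the difference
between percentile conventions is below the resolution of the reported
values, but one convention has to be fixed and the simulator's calibration
targets use the same one.  Group comparisons use Kruskal-Wallis with tie
correction for quantitative variables and, for categorical ones, Pearson's
chi-square without continuity correction when every expected count is at
least 5, otherwise Fisher's exact test (two-sided p as the sum of
probabilities of tables as or more extreme).  Spearman's rho uses average
ranks and the t-approximation.  The motivating study prints a saturation
/ score correlation of rho = -0.89 with p = 0.5, which is internally
implausible at n = 50 (likely a typo for -0.089); the package simply
reports whatever the data give.

## The synthetic cohort model

No patient-level data were published, so the generator is the package's
own construction: the *simplest* latent-variable model able to match the
study's marginal and ordinal structure jointly.  One continuous severity
factor `z` drives everything:

* age is lognormal, calibrated analytically so the median is 2.18 months
  and 22% of infants are under one month;
* `z = -0.8 (log age - meanlog) + N(0, 1)`: younger infants are sicker;
* the three ordinal WDF items are ordered probits in `0.45 z`; respiratory
  and heart rate are linear in `z` with physiologic noise; cyanosis is a
  rare logistic item;
* each ultrasound finding is an independent logistic model in `z`, with
  the large-consolidation item rarest and most severity-loaded;
* the support tier thresholds a noisy copy `z + N(0, 0.5)`; because that
  index is exactly normal, the three tier thresholds are plain normal
  quantiles reproducing the study's tier fractions 58 / 6 / 20 / 16%
  (none / LFNC / HFNC / nCPAP-or-higher), and admission is the union of
  any support with a second threshold crossing tuned to an overall 66%;
* event times are exponential (default hazard 1/12 per hour, so about 86%
  of events fall inside the 24-hour horizon), truncated at the 96-hour
  follow-up; support-free infants carry no event time.

The calibration constants were fixed once with
`tools/calibrate-generator.R` and shipped as the defaults of
`cohort_config()`; re-running that script audits them.  At large n the
defaults reproduce: 66% admitted, 42% any oxygen, 36% HFNC or higher, 16%
top tier, 22% under one month, 60% male, WDF median straddling 4.5,
overall LUSCAB median 2.5, about 37% of infants at or above the 3.5-point
cutoff (the study observed 19/50), and an AUC near 0.85 for the top-tier
outcome with a lower AUC for the broader support outcome, matching the
ordering of the published discrimination estimates.

What the model does *not* emulate — deliberately, because nothing
published constrains it — includes: correlation between the two B-line
findings beyond their shared severity factor; admission criteria unrelated
to severity (feeding, social circumstances), which is why the simulated
score discriminates admission somewhat better than the study observed;
exact group medians of the middle support tier; and seasonal or viral
structure.  Passing calibration tests therefore shows the pipeline is
correct on data *like* the study's, not that it reproduces the study's
patients.

## Numerical and design notes

* Scores use integer half-point arithmetic internally; no floating-point
  drift can move a patient across the cutoff.
* Percent values are rounded half away from zero to one decimal **only at
  serialization**; all internal computation keeps full precision.
  (`round()`'s half-to-even rule would turn 31.85% into 31.8 or 31.9
  depending on binary representation; half-away matches how clinical
  tables are printed.)
* `reconstruct_confusion` warns, and never silently adjusts, if a printed
  statistic is inconsistent with every integer table.
* Cohorts live in a documented CSV schema; reading validates every
  invariant (support implies oxygen and an event time; event times within
  follow-up; item ranges) and reports offending row numbers.  A cohort may
  carry either raw WDF items or a precomputed total; if both are present
  and disagree, validation fails rather than preferring one.
* The generator draws variable-block by variable-block in a documented
  order from a single seeded stream, so identical configuration and seed
  give byte-identical CSVs, and the caller's RNG state is restored.
* Problem sizes in the test-suite: calibration checks simulate 5 000
  infants; null-distribution checks (log-rank and Kruskal-Wallis type-I
  error) use 2 000 replicates; convergence of empirical Se/Sp uses one
  draw of 100 000.  These sizes put Monte-Carlo error well inside the
  asserted tolerances while keeping the suite fast.

## A worked example

```{r}
report <- run_all(n = 50, seed = 1)
report
```

The printed block is the synthetic analogue of the study's results: the
accuracy rows correspond to the published AUC/Se/Sp/PPV/NPV table, and the
two survival lines to the published Kaplan-Meier comparisons at 24 hours.
`write_report()` serializes the same content as JSON
(`inst/schema/validation-report.schema.json` documents the layout), and
`check_report()` asserts the internal count and Bayes identities.

## Known limitations

* The validation is of the *pipeline*, not of the score's clinical value:
  only a real multi-centre cohort can do the latter.
* The log-rank test and KM estimator assume non-informative censoring;
  with a 24-hour horizon and administrative censoring this is reasonable,
  but the package does not model dependent censoring.
* Only two-group log-rank comparisons are provided (the cutoff defines two
  arms); no Cox regression, no interval censoring, no optimal-cutoff
  search — the 3.5-point threshold is taken as given from the score's
  derivation study.
```
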