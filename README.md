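# pacuseq

Predicting prolonged post-anesthesia care unit (PACU) stays before the day
of surgery, and resequencing operating-room (OR) days by predicted risk to
reduce after-hours PACU occupancy.

## The problem

In an ambulatory surgery center, a patient still recovering in the PACU
past the evening close (here, past 19:00) forces after-hours staffing.
Prolonged PACU length of stay (LOS ≥ 180 min, the cohort's 75th
percentile) is rare — about 5% of cases — but predictable from
preoperative features alone: age, sex, BMI, ASA Physical Status, procedure
category, scheduled case duration, and 16 comorbidity flags. If the
high-risk cases of an OR day are moved to the morning, their long PACU
tails run during staffed hours.

`pacuseq` implements that analysis end to end, for methodologists and
perioperative-informatics teams who want to reproduce, stress-test or
extend it:

1. **Synthetic cohort generator** — institutional PACU data is not
   distributable, so cohorts are generated with matched marginals
   (prevalence 5.31%, short/prolonged median LOS 81/210 min, median 4
   [3, 6] cases per OR day, etc.). PACU LOS follows a calibrated
   log-linear model
   `log(LOS) = b0 + bf·1(female) + bd·log(duration) + bb·z(BMI) + ba·z(age) + e`.
2. **Class imbalance handling** — SMOTE oversampling (k = 5 neighbors)
   combined with random under-sampling, with per-model-family target
   ratios (minority/majority after each step) shipped as defaults.
3. **Six classifier families** — penalized logistic regression, a
   single-hidden-layer ReLU network, hinge-objective gradient boosting,
   random forest, balanced random forest, balanced bagging — with
   cross-validated and held-out AUC / sensitivity / specificity (95%
   stratified-bootstrap CIs), decile calibration, and SHAP or permutation
   feature importance.
4. **Resequencing simulator** — rebuilds each full OR day (scheduled past
   15:00) sequentially, reorders cases by predicted risk descending, flags
   days with PACU exits past 19:00, and compares historic vs resequenced
   frequencies with a chi-square test. An exhaustive-permutation oracle
   verifies that longest-tail-first ordering is optimal.

## Worked example

```r
library(pacuseq)

cfg <- pipeline_config(cohort = cohort_config(n_cases = 10928),
                       model_family = "logistic", master_seed = 1)
res <- run_pipeline(cfg)
print(res$cohort)
print(res$evaluation)
print(res$resequencing)
```

```
Synthetic surgical cohort: 10928 cases in 2150 OR days; 582 (5.33%) prolonged PACU stays
Evaluation on 2185 cases (threshold 0.5 ):
  AUC          0.738 (0.689, 0.784)
  Sensitivity  0.595 (0.500, 0.681)
  Specificity  0.733 (0.713, 0.752)
Operating-room day resequencing summary
  Total number of OR days                        162
  Cases per OR day, median [quartile]            7 [6, 8]
  OR days resequenced                            156 (96.3%) (1088 cases)
  Days with PACU occupancy past 19:00            historic 74 (45.7%) vs resequenced 66 (40.7%)
  Chi-square = 0.80, p = 0.3696
```

Reading this: the generator hit its configured prevalence (5.33% vs the
5.31% target); the ridge-logistic model with its SMOTE(0.75) +
under-sampling(0.9) defaults reached held-out AUC 0.738 and, at the 0.5
threshold, caught 59.5% of prolonged stays at 73.3% specificity. Among the
162 full OR days rebuilt from the held-out cases, sorting each day's cases
by predicted risk (highest first) cut after-hours days from 74 to 66.
The reduction is real but far smaller than what slack-rich real schedules
allow — with back-to-back packing most after-hours days cannot be rescued
by *any* ordering; the methods vignette
(`vignettes/pacuseq-methods.Rmd`) quantifies that ceiling with the
perfect-foresight ordering.

`run_pipeline(cfg, out_dir = "...")` additionally writes every artifact:
cohort/OR-day/split/risk/schedule CSVs, evaluation and resequencing JSON,
and a provenance log with all seeds and package versions. Reruns with the
same config are byte-identical.

The `analysis/` directory holds the same workflow as narrative stages:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + summary table
Rscript analysis/02_evaluate_models.R   # all six families, raw vs balanced
Rscript analysis/03_resequence.R        # resequencing with the best model
```

each writing its tables under `results/`.

## Package layout

```
R/                      generator, cohort/encoding/split, balancing,
                        models, metrics, resequencing, pipeline
analysis/               numbered narrative drivers over the package
scripts/acceptance.R    headline-quantity recomputation (JSON out)
tests/testthat/         unit, property and acceptance suites
vignettes/              methods vignette (models, calibration, design
                        choices, limitations)
```
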