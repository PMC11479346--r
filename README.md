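# vimsdetect

Detection of visually induced motion sickness (VIMS) from low-burden
multimodal physiological recordings.

Operators driving machinery through displays — multi-monitor setups or
head-mounted displays — can develop VIMS: dizziness, nausea and discomfort
from wide-field moving imagery. Severity is reported verbally on a 1–5
scale at task-cycle boundaries and a report of 5 ends the session. This
package implements the full analysis chain that turns raw signals into a
per-second fit-to-work judgement:

1. **Feature extraction** — 23 features at 1-s resolution from a sliding
   30-s window: heart rate mean/sd and LF (0.04–0.15 Hz), HF
   (0.15–0.40 Hz), LF/HF spectral powers of heart-rate variability;
   respiratory period mean/sd; tonic skin conductance level mean/sd and the
   phasic response integral ∫|SCR| dt; saccade frequency and peak-speed
   mean/sd from the horizontal EOG; theta (4–8 Hz) and alpha (8–13 Hz) EEG
   power-ratio and peak-frequency means/sds; and the lambda response
   (amplitude, latency) of the eye-fixation-related potential.
2. **Preprocessing** — per-second labels from the stepwise reports (binary
   target: level ≥ 3), standardization as ratios to the mean of the 90
   feature rows in the first 120 s of each session, pooled 1/99-percentile
   clipping with previous-value repair.
3. **Classification** — gradient-boosted decision trees (logistic loss,
   class weights n/(2·n_class), seven tunable hyperparameters: `lambda_l1`,
   `lambda_l2`, `num_leaves`, `feature_fraction`, `bagging_fraction`,
   `bagging_freq`, `min_child_samples`) with stepwise tuning by stratified
   5-fold ROC-AUC and leave-one-participant-out validation.
4. **Trend analysis** — sessions resampled onto 1000 segments of
   normalized time; per-feature means with 95% bands and Pearson R/R²
   against the VIMS-level trend.

Because the human recordings behind the method are not public, the package
ships a seeded synthetic-signal generator (`simulate_session()`,
`simulate_cohort()`) producing all eight channels with ground truth and
sickness-coupled dynamics in the published trend directions; the entire
test suite runs against it. See the methods vignette
(`vignettes/vims-detection-methods.Rmd`) for the model, assumptions and
design choices.

## Worked example

```r
library(vimsdetect)

# simulate a 9-participant cohort (two sessions each; 7 develop severe VIMS)
cohort <- simulate_cohort(9, scenario_config(seed = 1), seed = 7)

# extract features + labels, standardize, assemble
sess <- lapply(cohort, function(s) {
  ft <- extract_features(s$recording)
  list(ft = ft, lb = build_label_series(s$recording$reports, ft$t_s))
})
std <- lapply(sess, function(s) standardize_features(s$ft))
thr <- fit_clip_thresholds(lapply(std, `[[`, "ratios"))
rep <- lapply(seq_along(std), function(i)
  list(features = repair_outliers(std[[i]]$ratios, thr)$features,
       labels = sess[[i]]$lb))
ds <- assemble_dataset(rep)$data

# leave-one-participant-out evaluation (tune = TRUE runs the stepwise search)
folds <- loocv(ds, seed = 11, tune = FALSE)
evaluate_folds(folds)
```

Output on this seed (untuned, desk-scale 600-s sessions):

```
  participant accuracy kappa roc_auc pr_auc
1         P01    0.993 0.968   1.000  0.998
2         P02    0.977 0.951   0.971  0.981
3         P03    0.961 0.905   0.997  0.993
4         P04    0.978 0.950   0.999  0.998
5         P05    0.989 0.950   1.000  1.000
6         P06    0.971 0.892   0.994  0.992
7         P07    0.997 0.986   1.000  1.000
8        Mean    0.981 0.943   0.995  0.994
```

One row per held-out participant: accuracy and Cohen's kappa at
threshold 0.5, ROC-AUC and PR-AUC of the per-second probability that the
operator is at VIMS level 3–4. The synthetic cohort's default effect sizes
are chosen to be clearly separable, so these numbers characterise the
pipeline, not human data.

## Command line

```sh
Rscript -e 'vimsdetect::vims_cli()' simulate --n 9 --out recs --seed 7
Rscript -e 'vimsdetect::vims_cli()' extract --in recs --out features.csv --labels labels.csv
Rscript -e 'vimsdetect::vims_cli()' standardize --features features.csv --labels labels.csv \
    --out dataset.csv --thresholds thresholds.csv
Rscript -e 'vimsdetect::vims_cli()' evaluate --dataset dataset.csv --report report.csv --seed 7
Rscript -e 'vimsdetect::vims_cli()' trends --dataset dataset.csv \
    --predictions predictions.csv --out trends.csv
```

Global options: `--config <file>` (key=value overrides of
`pipeline_config()` fields), `--seed`, `--log-level quiet`.

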