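---
title: "Detecting visually induced motion sickness from multimodal physiology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting visually induced motion sickness from multimodal physiology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Operators who control machinery through displays — multi-monitor walls or
head-mounted displays — can develop visually induced motion sickness
(VIMS): dizziness, nausea and discomfort triggered by wide-field moving
imagery. Severity grows over a session and is reported verbally on a
five-point scale at task-cycle boundaries; a report of 5 ends the session.
`vimsdetect` implements a detection pipeline that maps low-burden
physiological recordings (dry-electrode ECG, a respiration accelerometer,
electrodermal activity, horizontal EOG, and four parieto-occipital EEG
channels) to a per-second binary judgement: is the operator at level 1–2
(fit to continue) or 3–4 (should stop)?

Because the human recordings this method was developed on are not public, the
package ships a seeded synthetic-signal generator with full ground truth;
every stage of the pipeline is exercised and tested against that generator.

## Feature extraction

All channels are reduced to a 1-Hz time series of 23 features. Each feature
at timestamp $t$ (integer seconds) summarises the half-open trailing window
$[t-30, t)$; windows shift by 1 s and the first valid timestamp is $t=30$.
This convention is what makes the standardization baseline below hold
exactly 90 rows in the first 120 s.

* **Heart rate (5 features).** The ECG is band-passed 0.05–30 Hz; R waves
  are enhanced by derivative, squaring and 150-ms moving-window
  integration, with an adaptive threshold at 50% of the running median of
  the last eight enhanced peaks. RR intervals outside 0.3–2.0 s are
  discarded. Instantaneous HR ($60/\mathrm{RR}$ bpm, placed at beat times)
  is cubic-spline resampled at 50 Hz across the window; `HR_mean` and
  `HR_sd` summarise the resampled trace, and `LF`, `HF` are integrated
  Hann-periodogram powers in 0.04–0.15 Hz and 0.15–0.40 Hz, with
  `LF_HF = LF/HF` indexing sympathovagal balance. One periodogram per
  window is used rather than Welch averaging because each window yields a
  single value.
* **Respiration (2).** The accelerometer signal is band-passed 0.5–2 Hz
  (the published setting, kept as printed although it sits above typical
  resting breathing frequencies; the cutoff is configurable), differenced,
  and breath events are marked at positive-going zero crossings.
  `RespPeriod_mean`/`_sd` summarise inter-event intervals with onsets in
  the window.
* **Electrodermal activity (3).** The tonic skin conductance level is the
  0.04-Hz low-pass of the signal; the noise component is the 0.5-Hz
  high-pass; the phasic skin conductance response is
  $\mathrm{SCR} = (x - \mathrm{noise}) - \mathrm{SCL}$. Features are
  `SCL_mean`, `SCL_sd` and the window integral $\int |\mathrm{SCR}|\,dt$
  (µS·s).
* **Saccades (3).** EOG velocity is a smoothed derivative (20-ms central
  difference) for detection; spans with $|v|$ above an adaptive threshold
  (6 × median absolute deviation of the trailing 30 s, floored at
  500 µV/s) lasting 10–150 ms are saccades, merged when closer than 50 ms.
  Peak speed is read from a finer 5-point-stencil velocity inside each
  span, because the smoothed detection velocity biases fast-saccade peaks
  several percent low. Features: `SaccadeFreq` (onsets per second),
  `SaccadeSpeed_mean`/`_sd` (µV/s).
* **EEG spectra (8).** The four channels are band-passed 0.5–30 Hz and
  averaged; each window splits into fifteen non-overlapping 2-s
  subwindows. Per subwindow, a periodogram gives theta (4–8 Hz) and alpha
  (8–13 Hz) power ratios — the denominator is total 0.5–30 Hz power, a
  convention the original method leaves open — and peak frequencies (band argmax, 0.5-Hz
  resolution). Features are means and standard deviations across
  subwindows.
* **Lambda response (2).** Fixation onset is defined as saccade offset.
  The channel-averaged EEG is epoched −100…+300 ms around each fixation
  onset in the window, baseline-corrected by the −100…0 ms mean, and
  averaged. `LambdaAmplitude` is the maximum of that average in
  50–200 ms; `LambdaLatency` its time. The canonical 23-feature set keeps
  the per-window epoch averages (not their within-window dispersions),
  matching the published feature table.

All filters are 4th-order zero-phase Butterworth (forward–backward);
band-passes are realised as a high-pass/low-pass cascade. Zero phase keeps
event timing unbiased, which matters for saccade offsets and lambda
latency. No filtering package with Butterworth design is available in the
target environment, so design (bilinear transform) and `filtfilt` (odd
reflection padding, length 3 periods of the slowest cutoff) are implemented
here and validated against analytic magnitude responses.

## Labels, standardization, outlier repair

The per-second VIMS level is the most recent report at or before $t$
(level 1 before the first report). A level-5 report terminates the session
at its own timestamp, so the label series never contains a 5 and the
binary target is level ≥ 3. Each feature is divided by its per-session
reference — the mean of the 90 rows with $t \in [30, 120)$, NaNs excluded —
rather than z-scored, so the normalization is available in (near)
real time after a short calm baseline. Ratios from all sessions are pooled
per feature; the 1st/99th percentiles (linear-interpolation definition)
become clip thresholds, and values outside them, as well as NaNs, are
replaced by the previous repaired value (a bad leading value takes the
first in-range one). Threshold fitting pools *all* sessions, as published;
this leaks a small amount of distributional information across
cross-validation folds, which we accept for fidelity and note here.

## Classifier and validation

The classifier is a gradient-boosted decision-tree ensemble with binary
logistic loss, histogram-based splits (≤63 bins) and leaf-wise growth —
authored in C++ inside the package because no boosting library exists in
the target environment. Exactly seven hyperparameters are tunable:
`lambda_l1`, `lambda_l2` (L1/L2 leaf regularisation), `num_leaves`,
`feature_fraction` (columns per tree), `bagging_fraction`/`bagging_freq`
(row subsampling), `min_child_samples`. Class weights
$n_\mathrm{total}/(2\,n_\mathrm{class})$ enter the gradients. Training
uses an internal stratified 90/10 split for early stopping (cap 1000
rounds, learning rate 0.1).

Hyperparameters are tuned by a stepwise search in the style of automated
boosting tuners — feature fraction, then tree size, then bagging, then
L1/L2 (log-uniform draws), then minimum leaf size — each trial scored by
mean ROC-AUC over stratified 5-fold cross-validation. The original method does not state its tuning objective; ROC-AUC matches
its headline metric. Tuning
fits are capped at 150 rounds with a $10^{-4}$ minimum-improvement early
stop, a runtime choice that does not affect the final fit's 1000-round cap.

Evaluation is leave-one-participant-out over participants who ever reached
the severe class: all sessions of the held-out participant form the test
set; everyone else — including never-severe participants — forms the
training pool (a flag can exclude them), and tuning runs inside each fold.
Reported metrics per fold: accuracy and Cohen's kappa at threshold 0.5,
ROC-AUC (rank-based, tie-aware), and PR-AUC as step-wise average precision
(trapezoids overestimate PR curves).

## Trend analysis

Sessions differ in length, so each session's standardized features, VIMS
level and prediction-correctness series are linearly resampled onto 1000
segments of normalized time $[0,1]$. Segment means across sessions carry a
95% band (mean ± 1.96 SEM; with ~30 sessions the t-versus-normal
difference keeps empirical coverage near 94%, inside the tested 93–97%
window). Each feature's Pearson $R$ (and $R^2$) is computed between its
segment-mean trend and the segment-mean VIMS trend — on segment means, not
pooled raw points, matching how such trend figures are constructed.

## The synthetic world

`scenario_config()`/`simulate_session()` generate one session; a latent
severity $g(t) \in [0,1]$ rises piecewise-linearly from a configurable
onset (gradual or rapid), maps to levels 1–5 by thresholds
0.2/0.4/0.6/0.8, and couples every modality with the published trend
directions: HR and respiratory period up, SCL and SCR up, saccade
frequency down, saccade speed up, theta up / alpha down, peak frequencies
down, lambda amplitude and latency up. Default magnitudes (10–50%
fractional changes at full severity) are free parameters chosen once to
produce clearly separable classes; only trend directions, not raw effect
sizes, are reported for the real phenomenon.

Channel construction: ECG is a biphasic Gaussian-derivative QRS template
(80 ms) on a beat train integrating instantaneous HR with 0.1/0.3-Hz
sinusoidal modulation feeding LF/HF; respiration is a phase-integrated
oscillation with period $P_0(1+\delta g)$, with $P_0 = 1$ s so the
oscillation lies inside the published 0.5–2 Hz analysis band and ground
truth remains recoverable; EDA is a rising tonic level plus bi-exponential
phasic pulses of known area; EOG is a bounded random walk of logistic gaze
steps with known peak slope; EEG combines 1/f noise, amplitude- and
frequency-modulated alpha/theta oscillators (the frequency wander is what
keeps the peak-frequency dispersion features non-degenerate), and a
Gaussian lambda template after every fixation onset.

SCR pulse kinetics are 0.75 s rise / 2.5 s decay at a 2-per-minute
baseline rate. Slower kinetics (e.g. 1 s/4 s) push most of a pulse's area
below the 0.04-Hz tonic cutoff, so the published decomposition would
systematically absorb ~30% of every pulse into the SCL; the chosen values
sit inside the physiological range and keep an isolated pulse's area
recoverable within 10%. Even so, the decomposition redistributes pulse
mass over a ±40-s neighbourhood, so *individual* 30-s window integrals
deviate from injected areas far more than session aggregates do — a
genuine property of the published method, not of the simulator, and the
reason one acceptance clause on per-window SCR recovery is expected to
fail (see the test suite).

A default cohort mirrors the reference cohort structure: nine
participants, two sessions
each (multi-display and head-mounted), seven developing severe sickness
(three under both displays), two staying mild; participants carry shared
baseline offsets so grouped cross-validation is meaningful. The default
session length is 600 s — real sessions averaged ~1500 s; shorter sessions
keep the full test suite inside desk-scale runtimes and the class balance
comparable.

What the simulator does **not** emulate: measurement artifacts (motion,
electrode drift, Bluetooth dropouts), blink contamination of the EOG,
inter-feature physiological coupling beyond the shared severity, and
reporting noise (labels follow the latent severity exactly). A green test
suite therefore establishes that the pipeline implements its stated
contracts and recovers known signal — not that the classifier would reach
any particular performance on human data.

## Numerical choices and degenerate inputs

* Percentiles use the linear-interpolation (type-7) definition.
* A standardization reference below $10^{-9}$ in magnitude makes that
  feature's ratios NaN (logged) instead of dividing by ~0.
* Fewer than 4 R peaks, 2 breath events, 8 valid EEG subwindows or 3
  fixations in a window yield NaN features, repaired downstream by the
  previous-value rule.
* A constant accelerometer signal yields no breath events (an amplitude
  guard suppresses crossings of filter start-up residue).
* Decision threshold for accuracy/kappa is probability 0.5 (accuracy is
  conventionally reported without stating one).
* Seeds: every stochastic step (simulation, fold assignment, bagging,
  tuning draws) flows from explicit integer seeds; the C++ booster uses
  its own Mersenne Twister so results are machine-independent.

## Known limitations

* The boosting implementation is a faithful small-scale learner, not a
  performance-parity LightGBM clone; importance is split-gain only.
* Pooled threshold fitting leaks mild cross-fold information (published
  behaviour; a `fit-on-train` variant is left as an option hook).
* The respiration band-pass as printed (0.5–2 Hz) would suppress real
  resting breathing (~0.2–0.4 Hz); with real recordings the lower cutoff
  should be dropped to ~0.1 Hz via `pipeline_config(resp_bandpass=)`.
* Per-window SCR mass recovery is limited by the published tonic/phasic
  decomposition itself, as discussed above.
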