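---
title: "Maternal-fetal coupling and self-supervised ECG stress analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal-fetal coupling and self-supervised ECG stress analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fetalstress)
```

This vignette is the package's account of its science: the models it
implements, the knobs that matter, what the synthetic generator does and
does not emulate, and the design decisions taken where the underlying
analysis left choices open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The Fetal Stress Index

Bivariate phase-rectified signal averaging (BPRSA) extracts a coupling
signature between two synchronously recorded signals. Here the trigger is
maternal heart rate (mHR) and the target fetal heart rate (fHR), both
interpolated to a uniform 900 Hz grid (`interpolate_target()`, linear
through the beat values with each interval's rate placed at its
terminating beat). Anchor points are *decreases* of the trigger:
index `i` is an anchor when the mean of the `anchor_T` samples from `i`
onward is strictly below the mean of the `anchor_T` samples before it
(default `anchor_T = 1`, the classical single-sample criterion). Windows
of `2L` target samples centred on each anchor are averaged into the curve
`X`, and the index is

$$FSI = \frac{1}{S_2-S_1}\sum_{i=L+S_1}^{L+S_2} X(i)
      \;-\; \frac{1}{S_2-S_1}\sum_{i=L-S_2}^{L-S_1} X(i),$$

with defaults `L = 9000` (a 20-s window at 900 Hz), `S1 = 1350` (1.5 s)
and `S2 = 2250` (2.5 s). Three numerical points deserve note:

* **Indexing.** `X` is stored with the anchor at 0-based index `L`; the
  sums above are inclusive on both ends. The printed normalization is
  `1/(S2-S1)` although each inclusive sum has `S2-S1+1` terms, so a unit
  step at the anchor yields `901/900`, not 1. The package implements the
  definition literally; `bprsa_config(mean_normalization = TRUE)` divides
  by the point count instead when a conventional mean is wanted. The index
  is linear in `X` and offsets cancel, so the choice rescales but never
  reorders dyads.
* **Anchor granularity.** On a linearly interpolated 900 Hz heart-rate
  series, a single-sample decrease criterion marks every sample inside a
  decelerating beat interval, so anchors arrive in long consecutive runs
  (hundreds of thousands per 40-minute dyad). `bprsa_average()` therefore
  has two algebraically identical paths: direct window accumulation for
  small anchor sets, and a run-compressed cumulative-sum path whose cost
  scales with the number of runs rather than anchors. Their agreement is
  part of the test suite.
* **Sign convention.** FSI is *after minus before* on the fetal curve: a
  fetus that decelerates after maternal decelerations gives negative FSI,
  and stronger coupling gives larger magnitude. Only the magnitude
  ordering is identified by the generator's ground truth; the acceptance
  checks therefore rank `|FSI|` against the coupling gain.

## The synthetic cohort generator

The clinical recordings the analysis was developed on are private, so the
generator emulates the statistical structure the pipeline assumes; its
defaults are the study conditions (900 Hz, 46-minute recordings, SQI
artifact rate 4.1%, stress group defined by PSS-10 ≥ 19, maternal baseline
80 bpm, fetal baseline 140 bpm).

* **Beat process.** RR intervals are a base interval plus LF (~0.1 Hz) and
  HF (~0.25 Hz) sinusoidal modulations plus white jitter — the minimal
  structure under which maternal decelerations exist as anchors. Default
  amplitudes (0.03 s LF, 0.025 s HF, 0.01 s jitter) give a few bpm of
  heart-rate variability, a realistic magnitude for resting adults.
* **Coupling.** The fetal instantaneous rate is its own LF/HF baseline
  plus `coupling_gain` times the lagged maternal *deceleration component*,
  defined as the excursion of mHR below its 0.9 quantile (so sustained
  decelerations transfer fully; default lag 0.5 s). `coupling_gain = 0`
  produces a statistically independent fetal series; the gain is the
  ground truth that FSI must recover, and recovery is asserted as exact
  rank agreement across gains {0, 0.25, 0.5, 1, 2} on matched seeds.
* **Morphology.** Each beat is five Gaussian kernels (P, Q, R, S, T) at
  fixed fractions of the local RR interval. This gives analytic control
  (R-peak recovery, mixture linearity) at the price of realism: no
  baseline wander, no electrode artifacts beyond the SQI channel, no
  gestational-age or fetal-sleep-state structure, and the abdominal
  channel is a plain attenuated sum plus white noise rather than a
  deconvolution problem. Passing tests demonstrate that the pipeline
  recovers what the generator encodes; they say nothing about performance
  on clinical recordings.
* **Stress encoding.** A latent severity (control-centred at -1, stressed
  at +1) drives, continuously: maternal heart rate (+10 bpm span), HF
  amplitude (down to -60%), T-wave amplitude (down to -35%), the coupling
  gain (0.25 to 1.0), and the biomarkers. PSS-10 uses a sigmoid link
  clamped for consistency with the ≥ 19 rule; cortisol is log-linear in
  severity; PDQ linear, floored at 0. All link functions are generator
  conventions, not claims about the clinical distributions, which the
  source analysis does not publish.

## Preprocessing

Seconds with SQI < 0.5 are discarded — the rule is strict, so a second
scoring exactly 0.5 is kept — and survivors are concatenated; the splice
count is recorded because windows cut later may straddle splice points
(the alternative, splitting at every splice, would discard further data;
the affect model treats windows as morphology snapshots, so concatenation
was chosen and logged). Signals are resampled to 256 Hz by a zero-phase
97-tap FIR anti-alias filter (cutoff at 90% of the target Nyquist) plus
cubic-spline evaluation on the new grid — deterministic, and accurate to
correlation > 0.999 on band-limited content. Windows are 10 s,
non-overlapping, trailing remainder dropped, each z-scored; constant
windows are rejected.

## The representation-learning stage

The pretext task is transformation recognition: each window yields seven
rows — itself plus one transformation each of Gaussian noise (sd 0.05 of
a unit-variance window), scaling (factor drawn from {0.7, 1.3}), negation,
temporal inversion, permutation of 20 equal pieces, and time-warping
(alternate pieces stretched/squeezed by 1.05 and resampled back; the
alternating assignment keeps the cumulative time drift bounded by one
piece, so the transform approaches identity as the ratio approaches 1).
Rows are stacked in shuffled order with per-head 0/1 labels.

The trunk is fixed by the source description — three blocks of two
same-padded 1-D convolutions with leaky ReLU (slope 0.1) followed by max
pooling, then global max pooling — but widths, kernels and head structure
come from an unavailable supplementary and are reconstructed here at desk
scale. No deep-learning runtime is available in this stack, so forward
and backward passes are implemented in the package against BLAS matrix
products and verified against finite differences. Training uses Adam with
learning rate 0.001 and batch size 128.

Whether the pretext objective is per-head binary or joint multiclass was
left open by the source; both are implemented and the softmax multiclass
head is the default. The reason is calibration at desk scale: a
two-epoch run on 200 windows is only ~22 Adam steps, and with fixed-size
Adam updates the per-head sigmoids reliably learn to *rank* (head AUROC
near 1) long before their logits cross the fixed 0.5 threshold, so binary
heads can sit at the majority class. The softmax head needs only relative
logits — the predicted variant is the argmax — and converges dependably
in the same budget; `encoder_config(head_type = "binary")` restores the
parallel sigmoid heads (positive class weighted 6:1 for the 1-in-7
stacking imbalance).

Two initialization choices matter at short training lengths and are
deliberate: the output-layer weights start near zero (the max-pooled
features are unnormalized, and a generic init saturates the output
nonlinearity), and the convolution weights use a He init with a gain
above 1, which scales the pooled features and thereby the logit growth
per fixed-size Adam step. Both are documented knobs of
`encoder_config()`. Dropout on the pooled feature layer defaults to 0 in
the pretext stage — the two-epoch runs are far from overfitting, and
feature dropout adds gradient noise exactly where calibration must be
learned — while the affect heads keep dropout 0.5 on their hidden layer.

## The affect stage and evaluation protocol

The trunk is transferred frozen — bit-identical before and after head
training, asserted in the tests — and only a fully connected head (hidden
width 128, leaky ReLU, dropout 0.5, linear output) is trained per task:
sigmoid + binary cross-entropy for stress classification on segment-level
group labels; mean-absolute-error on the subject biomarker broadcast to
its windows for the four regressions, with targets z-scored on the
training rows and inverse-transformed for reporting (a conditioning
choice, stated since the source does not).

Evaluation follows the published protocol literally: each subject's
windows are split into five near-equal parts and fold *k* tests on part
*k* pooled over subjects. This *within-subject* split leaks subject
identity between training and test — it estimates within-subject
discrimination, not generalization to unseen mothers — and is implemented
as stated because it is the protocol behind the reported numbers;
`make_within_subject_folds(subject_wise = TRUE)` provides the leakage-free
alternative, clearly marked as not the published protocol. Whether
metrics are computed per window or per subject is unstated in the source;
the package computes the panel at window level (matching the split's
granularity) and reports subject-level aggregates (mean of window scores)
alongside. AUROC uses the rank statistic (tie-aware, equal to the
Mann-Whitney normalization, and checked against trapezoidal ROC
integration); fold-vector comparisons use the exact two-sided
Mann-Whitney U test — the normal approximation is poor at n = 5 — with
the Bonferroni-Holm first-step criterion at the stated family size
(p < 0.025 for two comparisons).

Two training approaches mirror the source: *from-scratch* pretext-trains
on the evaluation cohort's own windows; *transfer* pretext-trains on an
independent synthetic corpus (a second generator cohort with its own
seed, standing in for the public ECG corpora) and transfers the frozen
trunk. `run_experiment()` runs the full
{aECG, mECG} x {from-scratch, transfer} x {classification + 4 regressions}
grid and emits the metric-panel tables.

## Problem sizes and determinism

Desk-scale defaults were chosen so the full property suite runs on one
CPU: the pretext corpus is capped at 320 windows (2240 pretext rows), the
pretext stage runs 4 epochs and the affect heads 80 epochs by default, and
the end-to-end validation cohort is 40 subjects at 10 minutes each; the
coupling-recovery check uses 40-minute dyads because FSI averaging needs
the anchor mass of a full-length recording. Every stochastic step — the
generator, transformation draws, batch order, dropout, fold assignment —
derives from explicit seeds, and identical configurations reproduce
bit-identical cohorts, weights and reports; this is asserted in the test
suite.

## Known limitations

The generator's stress signature is intentionally strong and
low-dimensional; real cohorts are noisier in every direction the
out-of-scope list names (fetal extraction difficulty, electrode geometry,
demographic covariates). The published clinical metric values are not
reproducible without the private recordings, and the package makes no
attempt to imitate them: the acceptance machinery checks analytic
constants, oracle equivalences, and recovery of the generator's own
ground truth instead. The within-subject protocol's optimistic bias is
inherited deliberately; use the subject-wise split for honest
generalization estimates.
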