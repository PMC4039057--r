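---
title: "Robust oddball-ERP features and classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust oddball-ERP features and classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the data model and
its conventions, the rejection model, the feature definitions, the blink
machinery, the classification protocol, and — because everything here is
validated on simulated cohorts — an honest statement of what the
synthetic generator does and does not emulate.

## Data model and conventions

A subject is a data cube `X ∈ ℝ^{C×E×T}` (channels × epochs × time
samples, microvolts) with per-epoch stimulus labels (`standard` /
`deviant`), block indices, and a montage in which a subset of channels is
flagged *periocular*. Sample indices are 0-based and epoch windows are
half-open, `[onset − pre, onset + post)`, so `T = round((pre + post)·fs /
1000)`; with the default 200 ms baseline and 1000 ms post-stimulus window
at 1 kHz, `T = 1200`. The container stores `fs` explicitly: a 250 Hz
configuration (`T = 300`) is equally supported, and every operation that
needs absolute time (baseline length, interval sums, the mMSE working
rate) converts through `fs` rather than assuming a sample count. The
feature partitions, by contrast, are defined *by index* (`T/24` and
`T/12` samples), so their millisecond widths scale with the configuration.

Subjects are stored one per file in a self-describing container
(serialised list with named datasets and attributes) that round-trips
bit-exactly; continuous `C × N` arrays plus an event table can be epoched
with `epoch_continuous()`.

## Channel-by-epoch rejection

After subtracting each cell's pre-stimulus mean, a cell `(c, e)` is
discarded when either criterion fires:

* **Threshold**: some sample deviates from baseline by strictly more than
  `threshold_uv` (default 100 μV). The bound itself is kept — the strict
  inequality is a documented tie convention, exercised in the tests.
* **Trend line**: an ordinary least-squares fit of the cell against time
  (epoch duration normalised to 1, so the slope unit is "μV per epoch")
  has `|slope| > 50` **and** `R² ≥ 0.3`. Both slope signs are rejected;
  the sign convention is not observable from a magnitude bound.

The retained set `P = {(c, e)}` is not rectangular; that is the point.
The traditional comparator keeps an epoch only when *every*
(non-blacklisted) channel passes, i.e. when an entire mask column is
clean — so cellwise retention dominates traditional retention at every
threshold, a structural fact the tests assert rather than assume.
Kurtosis channel screening (excess kurtosis of a channel's pooled block
samples, z-scored *across the block's channels*, rejected at `|z| > 5`)
is exposed for the traditional comparator; z-scoring across channels was
chosen because a fixed "standard deviation of kurtosis" is otherwise
undefined for a single block, and the alternative readings (across
blocks, analytic SE) are not distinguishable from the method's
description.

## Features

All clean standard vectors are pooled across channels *and* epochs and
reduced by the elementwise median to `s̄` (deviants → `d̄`); the even-count
tie convention is the mean of the two middle values. Pooling before any
per-channel averaging means a noisy channel contributes few cells and is
implicitly down-weighted — rejection becomes suppression rather than a
hard gate.

From `δ = d̄ − s̄`:

* `SSD_i = Σ_{j=w(i−1)+1}^{wi} δ_j` with `w = T/24` (50 ms at 1 kHz) —
  the signed area of the difference waveform per partition;
* `v_i = var(δ_j : w(i−1)+1 ≤ j ≤ wi)` with `w = T/12`, unbiased
  (`n − 1`) divisor;
* the selected classification vector drops the four pre-stimulus SSD
  partitions (the baseline precedes the stimulus) and keeps variance
  partitions 4–6, giving 23 features. The variance is computed on `δ` per
  its printed definition; a `variance_source = "standard"` switch
  computes it on `s̄` instead, preserving an ambiguity in the method's
  prose as an explicit option rather than silently resolving it.
  Likewise, variance partitions 4–6 are kept *by index*: at 1 kHz they
  span 100–400 ms post-stimulus, which does not coincide with any round
  "200–400 ms" window; the indices, not a prose window, are what the
  selection implements.

Interval-level SSD sums (0–150, 150–250, 250–400, 400–1000 ms
post-stimulus, half-open) support group comparison by Welch's t-test,
with a `p = 1` convention for degenerate constant data.

**Modified multiscale entropy.** Sample entropy is
`−ln(A/B)`: `B` counts pairs of length-`m` templates (default `m = 2`,
self-matches excluded) within Chebyshev tolerance `r` (default
`0.15·SD`), `A` the pairs still matching at length `m + 1`. The
multiscale profile computes it at scales 1..20 on non-overlapping-mean
coarse-grainings (a moving-average mode is provided), with `r` fixed from
the scale-1 series so that the scale trend reflects structure, not
re-normalisation. Per channel, the earliest clean epochs are concatenated
and decimated to a 250 Hz working rate (order-8 IIR low-pass, integer
factor) until 5,000 contiguous samples (20 s) are available; every other
channel in montage order is used (64 of 128), giving 64 × 20 = 1,280
values. A channel with too little clean data uses what it has (with a
warning); a channel with none contributes zeros. Degenerate template
counts return 0 for constant series and a logged `NaN` sentinel
otherwise. The counting kernel is compiled (Rcpp) and is tested against a
brute-force R implementation for exact equality.

## Eye blinks

Each block is concatenated (time-contiguously), reduced by PCA to 10
components, and unmixed by symmetric fixed-point ICA with a tanh
contrast. The unmixing rotation is estimated on a deterministic subsample
of at most 50,000 columns — a `k × k` rotation needs far fewer samples
than a long block provides — and applied to the full block; runs are
deterministic given the seed, with component signs and ordering
canonicalised. Blink likeness is scored as mean |periocular mixing
weight| / mean |mixing weight|, tie-broken by the activation's < 5 Hz
power fraction. Identification is automatic (the score ranking) with a
`component` override to reproduce a manual choice.

* **Removal** subtracts up to `k_max = 2` top-scoring components, but
  only those scoring above 1.5 — on blink-free data no component
  concentrates frontally, and removal should be (and is tested to be) a
  near-identity.
* **Counting** zero-means the chosen component's activation, sets a
  subject-specific threshold of 3 SD (the multiplier is exposed as an
  option), and flags an epoch when the activation's **maximum** within it
  crosses the threshold. Max was chosen over mean or peak-to-peak because
  a blink is a brief unipolar lobe: an epoch mean dilutes it 10-fold, and
  peak-to-peak doubles sensitivity to noise; this choice is configurable
  in spirit via the multiplier and is invariant to activation offset.

## Classification

Labels are `ASD` (positive) and `TD`. All models are evaluated by
leave-one-out cross-validation with any data-dependent choice made
*inside* the training fold:

* linear SVM — penalty `C` chosen by nested stratified threefold
  cross-validation over powers of two in `[2⁻⁴, 2⁶]`, maximising weighted
  accuracy, ties to the smallest (most regularised) value;
* L2 logistic regression — same protocol over `[2⁻⁵, 2⁵]` (ridge path,
  `λ = 1/(nC)`);
* Gaussian naive Bayes — the posterior probability of the typical class
  is thresholded at a cut chosen by leave-one-out *within the training
  fold* over `{0.05, …, 0.95}`, ties resolved toward 0.5 then downward; a
  variance floor handles constant features.

Powers of two at unit steps are the natural resolution of a
"logarithmic interval" grid; inner folds are class-stratified and
assigned by subject identity (row names), which makes LOOCV predictions
equivariant to row permutation — a property the tests check. Class
weighting is inverse-frequency throughout. The mMSE block enters by
stacking: a linear SVM (`C = 0.1`, class-weighted) is evaluated on the
mMSE features by LOOCV and its out-of-fold hard prediction (ASD = 1) is
appended as feature 24; the hard label rather than the signed decision
value is the default encoding. Reported metrics are weighted accuracy
`(n₋₁c₁ + n₁c₋₁)/(2n₁n₋₁)` (the mean of per-class recalls), sensitivity
(ASD recall) and specificity (TD recall); significance comes from
permuting labels (default 100 times) and re-running the full pipeline,
with `p = (#{permuted ≥ observed} + 1)/(n_perm + 1)`. A males-only rerun
(refitting everything on the male subset) guards against the classifier
keying on a sex imbalance.

## The synthetic cohort generator

Real recordings for this paradigm are not distributable, so the generator
is a first-class module and every downstream claim is validated against
its ground truth. It emulates:

* the oddball schedule — blocks of 400 stimuli, 85/15 standard/deviant,
  every deviant flanked by at least four standards;
* ERP structure — Gaussian-bump components (defaults shaped like
  P1/N1/P2 plus a deviant-only novelty bump) on a frontality-graded
  montage, with per-subject lognormal amplitude jitter (SD 0.2) as
  between-subject variability;
* the ASD effect — an `asd_deviant_boost` (default 3 μV) added to the
  deviant template in the 0–200 and 400–1000 ms windows, the group
  contrast the features are designed to capture;
* noise — pink (1/f power) background at 10 μV RMS per channel with 30 %
  of variance shared across channels (ICA needs spatially correlated
  noise to be meaningful);
* artifacts with ground truth — frontally-weighted blink lobes
  (150 μV at the periocular sites, 200–400 ms), drifts and spikes; blink
  probability is group-dependent (defaults 0.30 ASD / 0.10 TD per
  standard epoch) and **three-fold higher after deviants**. The
  deviant-locking is the mechanism by which a pure blink-rate difference
  can reach deviant-minus-standard features at all — reflexive blinking
  to novel sounds — and is exactly the confound one must worry about when
  blinks are left in the data.

Where the emulated study pins a value (cohort 19/30, block structure,
oddball split, 128 channels, epoch window), the defaults are that value.
Where it does not (effect sizes, noise and artifact magnitudes), defaults
were chosen once as field-plausible values calibrated so that the
recovery properties are attainable, and are not revisited; they are
configuration, not fitted parameters.

What the generator does **not** emulate: real head geometry or volume
conduction (the montage is a frontality gradient, not electrode
positions), non-stationary noise, saccades and EMG, stimulus-response
latency jitter, or inter-channel differences in noise level. Passing
recovery tests therefore demonstrates that the pipeline's machinery is
correct and sensitive under its stated assumptions — not that any
particular accuracy will transfer to real recordings.

## Numerical choices and degenerate inputs

* Amplitude bound: strict inequality (a sample exactly at 100 μV is
  kept). Trend fit: closed-form normal equations, `R² = 0` for constant
  cells. Kurtosis z-scoring: zero cross-channel SD → warning, no
  rejections.
* Medians: even counts average the two middle values (compiled
  `nth_element` selection, tested against `apply(..., median)`).
* Sample entropy: `B = 0` or `A = 0` → `NaN` sentinel with a warning
  (0 for constant input); series shorter than `m + 2` are an error.
* Naive Bayes: variance floor `1e-9 · max(s2)` with a warning for
  constant features; single-member classes in very small inner folds fall
  back to the floor silently and degenerate one-class inner models
  produce the obvious posterior.
* Weighted accuracy requires both classes in the truth; single-class
  subgroups are skipped with a warning in reports.
* Determinism: one seed flows from the study config through per-subject
  substreams (hash of seed and subject index) to ICA initialisation and
  fold assignment; reruns are byte-identical.

## Problem sizes used in the shipped checks

The validation suite exercises full geometry where it is cheap (a
128-channel, 400-epoch block for the mask; 64 × 20 mMSE on 5,000 samples)
and a spatially reduced cohort — 19 ASD / 30 TD subjects, 32 channels,
one 150-epoch block each at 1 kHz — for the end-to-end recovery studies:
classification of the boosted cohort, label-permutation behaviour, ICA
blink-count recovery, and the blink-removal contrast. These sizes were
chosen as the smallest at which the cohort-level effects are comfortably
identifiable; nothing in the implementation depends on them.

## Known limitations

* The rejection thresholds are amplitude-domain only; frequency-domain
  artifact detection and channel interpolation are out of scope by
  design.
* The ICA stage assumes blink topography is the dominant frontal source;
  pathological montages with very few periocular channels weaken the
  score's contrast (the score is scale-free, so at very low channel
  counts a chance-frontal noise component can compete).
* `stack_mmse` encodes the inner prediction as a hard label; with very
  small cohorts this makes feature 24 coarse.
* The generator's blink waveform is a single positive lobe; real blinks
  vary in width and asymmetry, which mainly affects how much blink energy
  survives at mid-frontality channels.
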