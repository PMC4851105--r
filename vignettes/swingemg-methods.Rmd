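---
title: "Methods: EMG-based golf-swing profiling and shot-effectiveness prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMG-based golf-swing profiling and shot-effectiveness prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and algorithmic choices behind
`swingemg`: what each stage assumes, which parameters matter, how the
synthetic validation data are generated, and where genuinely open design
questions were settled by a package-level decision.

## 1. Signal model and study conditions

The package targets eight-channel surface EMG recorded during single golf
swings at 1000 Hz, one recording per shot, with the fixed channel map
1 right FCR, 2 right EDC, 3 left FCR, 4 left EDC, 5 right rhomboideus,
6 right trapezius, 7 left rhomboideus, 8 left trapezius (the reference
muscle for activation timing). The default validation scale is 15 players
(10 men, 5 women) with 5 swings each and total swing times of 1.5–2.2 s.
Shot metadata carry two target attributes, club head speed (km/h) and
ball carry distance (m); a shot is *effective* when its target value lies
strictly above the player's own average (ties are ineffective — the
literal reading of "above the personal average", and the only convention
under which the minimum shot can never be effective).

## 2. Onset detection and activation profiles

Each rectified channel `|s_i(t)|` is smoothed with four sliding Gaussian
filters of window lengths 256, 512, 1024 and 2048 samples. The kernels
are unit-area with `sigma = width/6`, so the nominal window covers about
±3 sigma; the width parameter is a window length, not a standard
deviation. Convolution is centered (zero lag) with reflective edge
padding.

The channel threshold is `T_i = alpha * mean(|s_i|)` over the window from
`delta` samples before to `2*delta` samples after the position of the
widest-scale maximum, with `alpha = 1.2` and `delta = 500` samples;
near record edges the window is clipped and the mean taken over the
samples actually present.

The onset rule combines the scales as follows: for each of the three
wider scales, take the **last upward crossing** of `T_i` before that
series' global maximum (skipping low pre-swing activity, which real
swings exhibit); the onset `ts_i` is the steepest rise of the finest
scale inside the window spanning all crossings **extended by 256 samples
on both sides**. The symmetric extension matters: the wide scales smear
the burst so much that their threshold crossings happen well before the
finest-scale rise, and a window truncated at the last crossing clips the
argmax at its right edge (measured on noiseless synthetic bursts, the
truncated rule recovers only ~37% of onsets within ±64 samples versus
~98% with the extension).

The activation profile is `x_i = ts_8 − ts_i` (ms), i = 1..7; positive
components mean the muscle fired before the left trapezius. A recording
is flagged for manual review when `lambda = max_i |ts_8 − ts_i|` falls
outside dataset-level bounds, by default the 2.5th/97.5th percentiles of
lambda over all processed recordings; flagged shots are reported, never
auto-corrected.

The ±64-sample tolerance used throughout validation is a quarter of the
smallest filter width: the finest scale cannot localize a rise more
sharply than its own support, and the steepest rise of a smoothed
Gaussian burst sits `~1.45 * sigma_burst` after the 5%-of-peak envelope
start that defines the ground-truth onset, which stays within 64 samples
for the generator's burst widths.

## 3. Preprocessing and swing segmentation

Feature extraction preprocesses each channel in the fixed order
**rectify → normalize to peak → band filter**: full-wave rectification,
division by the channel maximum (so amplitude units never propagate
downstream), then a second-order Butterworth high-pass at 20 Hz run
forward and backward (effective order 4, zero phase), demeaning of the
high-passed result, and a low-pass at 400 Hz likewise. Zero-phase passes
use odd-reflective padding whose length scales with the filter's
transient (`6 fs / cutoff` samples); a pad tied only to the filter order
lets the 20 Hz transient bleed visibly into short records. The filtered
trace may dip negative; peak logic consumes it as-is.

Peak detection mimics interactive biosignal peak pickers: smooth with a
moving Gaussian of window `w = max(3, round(T / (12 * PeakD)))` samples
(`PeakD = 2` dominant peaks expected, so about 1/24 of the record), take
local maxima above 5% of the global maximum as candidates, and refine
each by a parabola fit to the log of the samples above half height
(sub-sample position, height, FWHM width; area = `1.0646 * height *
width`, the Gaussian area identity; fitting error = RMS residual as % of
height). Candidates within half a smoothing window of either record edge
are dropped — without full convolution support the boundary itself
becomes a spurious local maximum. Degenerate fits (fewer than 3 points
above half height, non-concave log fit, vertex outside the fitted run)
fall back to discrete position/height and a half-max width count. The
auto-scale constant deserves a note: with a much shorter window (1/100 of
the record) the band-passed rectified signal retains several noise
excursions per burst, the "two highest peaks" frequently land inside one
burst, and the box-plot pruning then deletes exactly the channels that
found the impact burst; 1/24 makes each burst contribute essentially one
dominant smoothed peak.

Per channel the two highest peaks are retained and relabeled P1/P2 by
order of appearance. All P1/P2 positions are pooled; Tukey fences
(quartiles by linear interpolation, type 7 — shared with every quantile
in the package — ±1.5 IQR) remove channels from the P1 and/or P2
retention lists independently (the literal two-list reading). The swing
window is `t1 = pos − width/2` of the earliest retained P1 and
`t2 = pos + width/2` of the latest retained P2, floored at 0 and capped
at the record end; detection/pruning/window iterate until no new outliers
(at most 5 rounds). Peak positions are finally expressed relative to the
swing, clamped to [0, 1]. Channels pruned as outliers still contribute
their own (P1, P2) descriptors to the feature tables, because all 22
feature sets assume a fixed 8-channel, 28-pair layout.

## 4. Feature sets

Twelve summary statistics (min, max, mean, median, lower/upper quartile,
SD, IQR, lower/upper range, skewness, kurtosis — standardized central
moments, kurtosis not excess, both 0 for constant samples by convention)
enrich most sets. The registry defines 22 sets: side-channel statistics (49 = swing duration + 4 channels ×
12), correlation contrasts (Pearson − Spearman and Pearson/Spearman per
channel pair; 28, or 40 with the statistics block), peak-property sets
(5 properties × 8 channels = 40, for P1, P2, their difference and
ratio), peak-concurrency sets (28 signed or absolute pairwise
relative-position differences + 12 statistics = 40) and the eight
arithmetic combinations of P1- and P2-concurrency (subtract, add,
multiply, divide; signed and absolute variants).
Sex (0 woman, 1 man) is always the first feature. Ratio-style
features guard near-zero denominators (|d| < 1e−9 → feature 0): the
table sizes are fixed at 8 channels / 28 pairs, so dropping a degenerate
pair is not an option. Signed pair order is lower-index minus
higher-index channel. Correlations are computed on the filtered signals
restricted to the swing window.

## 5. Grouped random forests and OOB scoring

Because every player contributes several swings, bootstrap sampling is
grouped at the subject level: each tree's bag draws as many subjects as
exist, with replacement (sex-stratified for detection, so each bag keeps
the 10:5 sex ratio), and a subject drawn k times contributes all its
shots k times; subjects never drawn are that tree's OOB set. OOB
prediction is therefore leave-subjects-out validation. Tree growing is
delegated to `ranger` with per-tree in-bag counts supplied explicitly;
trees are unpruned (`min_leaf = 1`), with `q` random candidate features
per node. Detection trees are probability trees whose leaves hold
training class frequencies, so the OOB detection score — the mean over a
shot's OOB trees of (leaf frequency of *effective*) − (leaf frequency of
*ineffective*) — implements the class-posterior-difference score exactly;
the regression score is the mean of OOB tree predictions. The forest size
default is B = 500 (desk scale; B = 5000 reproduces full-scale runs and
only tightens the OOB averages). For individual feature sets the node
subspace size is grid-searched over `{⌈√p⌉, ⌈2√p⌉, ⌈p/3⌉}` — the usual √p-scaled
candidate range for random forests — keeping the best OOB criterion (Cllr for detection,
RMSE for regression). Permutation importance permutes one feature at a
time across shots and reports the mean OOB performance drop.

## 6. Decision-level fusion and AMDE

The meta learner is another grouped random forest whose inputs are sex
plus one meta-feature per feature set (that set's OOB score vector,
aligned by shot). Fusion evaluates every meta-q from 2 to the number of
selected meta-features + 1 and keeps the best criterion. Meta-feature
selection uses angle-modulated differential evolution: DE/rand/1/bin over
the four parameters (a, b, c, d) of
`g(x) = sin(2π(x−a) · b · cos(2πc(x−a))) + d`, decoded to a 22-bit mask
by the sign of g on the grid 0.1, 0.2, …, 2.2 (values within 1e−9 of
zero count as zero — the closed-form sign patterns at exact zeros would
otherwise flip on floating-point noise). Sex is never maskable. All-zero
masks are resampled rather than penalized. DE defaults — NP = 20,
F = 0.5, CR = 0.9, 30 generations with early stop after 10 stagnant
ones — are standard settings chosen for desk-scale runtime; the
evolution is elitist, so the best-so-far fitness is non-increasing. For
regression the fitness is RMSE (the selection criterion regression
reporting uses), computed alongside Cllr.

## 7. Evaluation

Detection scores are calibrated by pool-adjacent-violators along the
score order (tied scores pre-pooled so the isotonic fit cannot split a
tie group), which is equivalent to walking the ROC convex hull; the
log-likelihood ratio is the isotonic posterior log-odds minus the prior
log-odds, capped at ±15 nats so separable sets stay finite. Cllr is the
usual two-class cost in bits on those LLRs — i.e. min-Cllr, the
convex-hull-calibrated value — the calibration-free summary of the
scores' discrimination. EER is the miss = false-alarm crossing of
the hull, linearly interpolated between vertices (endpoints (0,0) and
(1,1) are re-anchored because convex-hull routines drop collinear
vertices). AUC is the tie-corrected Mann–Whitney statistic. Regression
reports RMSE (the model-selection criterion), MAPE and Pearson
correlation, next to the naive reference that predicts every shot as the
full-sample mean of its sex.

## 8. The synthetic generator

`simulate_shots()` emulates the recording conditions: each channel is a
zero-mean 20–400 Hz band-limited Gaussian carrier — matching the
preprocessing band, so filtering does not distort planted structure —
multiplied by an envelope of baseline tone (0.02 of burst scale),
optional low pre-swing bumps (probability 0.3, amplitude 0.12), a
backswing burst starting at the channel's onset, and an impact burst near
78% of the swing duration. Ground truth records every onset (the time
the envelope first exceeds 5% of the burst peak), burst center, window
and generative quantity.

Burst morphology was chosen so each detector stage has a well-posed
target: the backswing burst is the broader one (sigma 30–42 ms, amplitude
0.95–1.2) and the impact burst the sharper one (sigma 22–32 ms, amplitude
0.8–1.05). The larger first-burst *area* pins the widest smoothing
scale's maximum to the swing initiation (the onset anchor), while the
comparable *amplitudes* keep the two filtered-domain peaks of similar
height so P1/P2 pairing is reliable; burst widths are short enough that
the steepest-rise onset estimate stays within the ±64-sample tolerance of
the 5%-envelope ground truth.

Onset structure: per-subject offsets around the defaults (150, 200, 380,
400, 50, 100, 250, 450 ms after swing start — channels 5→6→7→8 forming
the avalanche motif, channel 8 last), per-subject channel noise 40 ms,
per-shot jitter 10 ms, so orderings are a stable personal trait.

Targets follow a linear model: sex base (speed 132/116 km/h,
distance 155/124 m for men/women), a subject skill trait `w ~ N(0,1)`
that both shifts the targets (6 km/h, 10 m per unit) and scales the
activation lead of the non-reference muscles by `1 + 0.35 w` (effective
players activate earlier relative to the reference), a residual subject
effect (SD 4 / 8), shot-level couplings to swing duration (10 / 15 per s
below 1.85 s) and to the impact concurrency spread (250 / 350 per s below
0.018 s), and shot noise (SD 1 / 2). The couplings were calibrated once,
during generator design, to two anchors: the naive sex-average reference
lands near the reference values reported for this kind of data (speed
RMSE ≈ 7 km/h with correlation ≈ 0.75–0.85), and an oracle
leave-one-subject-out linear model on the generative quantities clearly
beats that reference (speed RMSE ≈ 4 vs ≈ 7) — so the planted effect is
unambiguously recoverable in principle, leaving honest margin for
estimation loss in the forest chain. They were then frozen.

What the generator does **not** emulate: motor-unit physiology,
electrode cross-talk and motion artifacts, nonstationary carrier spectra,
fatigue across shots, multi-swing records, or nonlinear EMG–outcome
relations. Passing the synthetic validation therefore shows the
*machinery* is correct (onsets, windows, features, grouped OOB contracts,
calibration), not that real swings are predictable to any particular
accuracy.

A noteworthy repeated-measures artifact the synthetic studies expose:
leave-subjects-out OOB scores carry a small *negative* within-sex
correlation with the target (removing a strong subject lowers the
remaining pool's mean), so base-learner meta-features can rank below the
naive baseline individually while the meta forest — indifferent to sign —
still extracts their information; decision-level fusion plus optimization
is what lifts regression above the sex-average reference.

## 9. Validation problem sizes

The test suite exercises: 18–75-shot simulated studies for the signal
chain (onset recovery ≥ 95% of 600 channels within ±64 samples;
swing-window coverage of the one-sigma core of all 16 planted bursts in
≥ 95% of 75 shots); 500-tree group-purity checks; hand-computable
leaf-frequency and tree-mean score contracts; calibration anchors at
n = 1000 (noise: Cllr ≈ 1, EER ≈ 50%, AUC ≈ 0.5; separable: Cllr < 0.05,
EER = 0, AUC = 1); a 10-seed end-to-end power study at B = 500 (fused
detection mean EER ≤ 35% and AUC ≥ 0.65; fused regression mean RMSE below
the naive baseline, with q-searched base learners); AMDE closed-form mask
patterns, elitist trajectories and planted-relevance recovery over 10
seeds; and the 1/√n shrinkage of repeated-fusion confidence intervals at
5 vs 20 repeats. `scripts/acceptance.R` reruns the full chain at the
75-shot study scale.

## 10. Known limitations

* EDF hardware exports are not read directly; convert to the csv-wide
  layout first.
* The onset estimator assumes one swing per record; multi-swing records
  will anchor on the dominant burst group.
* Box-plot pruning only removes channels whose peaks are gross outliers
  relative to the pooled position spread (about 1.5× the inter-burst
  IQR); subtler channel corruption passes through by design.
* With 15 subjects the sex-stratified bootstrap leaves on average ~36% of
  subjects OOB per tree; forests below ~100 trees can leave a shot with
  too few OOB trees for a stable score (an explicit error suggests a
  larger B).
* All validation evidence is synthetic; see Section 8 for what that does and
  does not establish.
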