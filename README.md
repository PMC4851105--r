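# swingemg

Surface EMG analysis of the golf swing: muscle activation-sequence
profiling and prediction of shot effectiveness from an eight-channel EMG
stream.

## The problem

During a golf swing, eight arm and shoulder muscles (left/right *flexor
carpi radialis*, *extensor digitorum communis*, *rhomboideus*,
*trapezius*) produce a characteristic EMG pattern: a backswing burst and
an impact burst per channel, with a player-specific ordering of
activation onsets. `swingemg` implements a complete chain for analyzing
such recordings and relating them to shot outcome (club head speed, ball
carry distance), for sports scientists and biosignal engineers working
with repeated-measures EMG:

1. **Onset profiling.** Each rectified channel is smoothed by four
   sliding Gaussian filters (widths 256/512/1024/2048 samples at
   1000 Hz). A data-driven threshold
   `T_i = α · mean(|s_i|)` over a window around the widest-scale maximum
   (α = 1.2, δ = 500 samples) anchors the swing-related activation onset
   `ts_i`; the **activation profile** is the vector
   `x_i = ts_8 − ts_i` (i = 1..7) of onset leads relative to the left
   trapezius reference.
2. **Swing segmentation.** After rectification, peak normalization and
   zero-phase 20–400 Hz Butterworth filtering (order 2 per pass, run
   forward and backward), all envelope peaks are detected per channel and
   the two highest retained (P1, P2, by order of appearance). Tukey
   fences (1.5 IQR) on the pooled positions prune outlier channels; the
   swing window is `t1 = pos(P1_k) − width(P1_k)/2` at the earliest P1
   and `t2 = pos(P2_k) + width(P2_k)/2` at the latest P2.
3. **22 feature sets** (channel statistics, Pearson-vs-Spearman
   correlation contrasts, peak properties, peak-position concurrency and
   their arithmetic combinations), each prefixed with sex.
4. **Grouped random forests.** Detection (shot above the personal average
   = effective) and regression (target value) with subject-grouped,
   sex-stratified bootstrap sampling: all of a player's swings are jointly
   in-bag or out-of-bag (OOB), so OOB scores are leave-subjects-out
   estimates. Detection scores are leaf class-frequency differences in
   [−1, 1].
5. **Decision-level fusion.** A meta random forest over the per-set OOB
   scores (sex always included), with brute-force meta-q search and
   angle-modulated differential evolution (AMDE) selecting the
   meta-feature subset via the mask
   `g(x) = sin(2π(x−a)·b·cos(2πc(x−a))) + d`, `g_k = 1 ⇔ g(0.1k) > 0`.
6. **Evaluation.** Cllr (ROC-convex-hull / PAV min-Cllr, in bits),
   DET/EER, ROC/AUC for detection; RMSE, MAPE and Pearson correlation
   against a naive sex-average reference for regression.

Because suitable public golf-swing EMG recordings are scarce, the package
ships a synthetic multichannel EMG generator (`simulate_shots()`) with
known ground truth — onset times, burst centers, planted couplings
between swing characteristics and shot outcome — and every stage is
validated against it.

## Worked example

```r
library(swingemg)

sim <- simulate_shots(default_study_config(seed = 42))
ds  <- sim$dataset
ds
#> <shot_dataset> 75 shots, 15 subjects (10 men, 5 women)

rec <- ds$recordings[["G01_S1"]]
rec
#> <emg_recording> shot G01_S1 (subject G01, man), 8 x 3633 @ 1000 Hz

# muscle activation profile: onset lead of each muscle vs left trapezius (ms)
ap <- activation_profile(rec)
round(ap$profile$x)
#>  x1  x2  x3  x4  x5  x6  x7
#> 435 342  93  59 431 422 295

# swing segment from the two dominant envelope peaks per channel
extract_segment(rec)
#> <swing_segment> [1.074, 2.696] s (1.621 s), 1 iteration(s)

# personal-effectiveness labels (above the player's own average)
lab <- effectiveness_labels(ds, "speed")
sum(lab)
#> [1] 40
```

The profile reads: right rhomboideus (x5 = 431 ms) and right trapezius
(x6 = 422 ms) activate far ahead of the reference, left FCR/EDC (x3, x4)
nearly together with it — the sequential "avalanche" onset motif the
generator plants for channels 5 → 6 → 7 → 8. 40 of 75 shots are faster
than their player's own average.

The full chain — base forests per feature set, meta table, fusion — is one
call:

```r
res <- run_pipeline(list(task = "detect", target = "speed",
                         forest = list(B = 500)), seed = 42)
res$report   # list(cllr = ..., eer = ..., auc = ...)
```

A thin command-line wrapper with `simulate`, `validate`, `profile` and
`run` subcommands is installed at `inst/cli/swingemg.R`.

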