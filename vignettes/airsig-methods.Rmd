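---
title: "Channel attribution for in-air signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel attribution for in-air signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An in-air signature is a signature written in the air while holding a phone
or wearing a smartwatch. The capture is not a pen trace but a multivariate
inertial time series with nine channels: accelerometer x/y/z (m/s²),
gyroscope x/y/z, and attitude pitch/roll/yaw (`att_x`, `att_y`, `att_z`).
Closed-set identification asks which of a fixed set of enrolled signers
produced a signal. The question this package is built around is one level
deeper: *which of the nine channels carry the identifying information, and
how much does each contribute?*

The answer is framed as a coalitional game. The nine channels are players;
a coalition S is a channel subset; its value v(S) is the validation accuracy
of a classifier trained on exactly the channels in S. With the game defined,
each channel's contribution is its Shapley value,

$$\varphi_i \;=\; \sum_{S \subseteq P \setminus \{i\}}
  \frac{|S|!\,(p-|S|-1)!}{p!}\,\bigl[v(S \cup \{i\}) - v(S)\bigr],$$

the coalition-weighted average of its marginal accuracy contributions. The
four classical axioms (dummy player, symmetry, additivity, efficiency) are
not just theory here — they double as executable correctness tests on every
computed map, with efficiency
$\sum_i \varphi_i = v(P) - v(\varnothing)$ the primary gate.

Computing v exactly means training one classifier per non-empty coalition:
$2^9 = 512$ coalitions per device, 1024 cells across a phone and a
smartwatch corpus. This is exhaustive ablation, not a sampling
approximation.

## The synthetic corpus generator

The reference corpora (a 427-subject phone corpus and a 22-subject
smartwatch corpus, 10 repetitions each) are not redistributable, so the
package ships a seeded generator whose defaults emulate their documented
structure; every downstream stage is testable against corpora with known
ground truth. The generative model per record:

* **Subject latent.** Each subject owns one smooth "motor program" per
  channel: a sum of `n_harmonics = 6` sinusoids with random frequencies
  below the Nyquist limit of the configured sampling interval, random
  phases and Gaussian amplitudes, rescaled to unit variance. This yields
  smooth, subject-stable, repetition-variable trajectories without claiming
  a biomechanical model.
* **Informativeness mixing.** Channel c of a record is
  $\sqrt{\rho_c}\,\text{latent}_c + \sqrt{1-\rho_c}\,\text{noise}_c$ where
  the noise trajectory is an independent band-limited process drawn per
  record and $\rho_c$ is `channel_informativeness[c]` — the fraction of the
  channel's variance carried by the subject identity. This is the ground
  truth that attribution methods must recover
  (`informativeness_oracle()` ranks it).
* **Repetition noise** (white, sd 0.1 by default) on every sample.
* **Session effect.** Rounds 1–5 belong to capture session 1, rounds 6–10 to
  session 2 (the pattern implied by the reference corpus's missing-record
  index, where every lost round ≤ 5 sits in section 1). Session-2 records
  receive a per-subject, per-channel constant offset with sd
  `session_shift_sd = 0.2`, emulating sessions held days apart.
* **Dwell segments.** Signers hold the device still for a moment after
  pressing start and before pressing finish; the first and last
  `dwell_steps = 5` samples are replaced by low-amplitude white noise. The
  segments are kept, not filtered — they sometimes carry identifying
  information, which the class activation maps can reveal.
* **Timing.** Sampling intervals are drawn uniformly from 215–230 ms (the
  normal-rate sampling mode); record lengths are jittered ±10% around
  `duration_steps = 1000` to force downstream length standardization.

Each record draws from its own RNG stream keyed by
`(seed, subject, round, session)`, so corpora are bit-reproducible and
removing one record never shifts any other — corpora also nest across
subject counts, which the tests exploit.

Defaults that the available documentation does not pin down — noise sds,
harmonic count, the uniform informativeness default of 0.7 — were chosen
once as plausible for wrist/hand gesture signals and are configuration, not
claims about the real corpora. The generator does not emulate real per-channel
amplitude scales or spectral content, cross-channel physical coupling
(gravity in the accelerometer, attitude/gyroscope kinematics), or forgery
attempts; passing tests demonstrate pipeline correctness and recovery of
*constructed* ground truth, not field accuracy on real signatures.

## Preprocessing

* **Length standardization** is linear interpolation on a uniform grid over
  the record's time span; the default target of 1000 samples matches the
  horizon of the corpus heatmap statistic (`subject_mean_series()`, which
  averages the 9 channels and all repetitions per subject). The target is a
  config knob surfaced in provenance, since no single standard length is
  canonical.
* **Splitting** is subject-stratified 80/20 by default: each subject
  contributes `floor(n_i · 0.2)` records (minimum 1 when `n_i ≥ 5`) to the
  test partition, so every subject stays in training — a requirement for
  closed-set identification. A plain random split is available for
  ablation.
* **Missing-data re-weighting.** Subjects with lost records get sampling
  weight `expected/actual` per record rather than record duplication,
  keeping dataset counts truthful; the weights enter the training loss.
* **Coalition slicing** projects records onto a channel subset in canonical
  order; the empty coalition is an explicit error at this layer, because
  its value belongs to the attribution baseline, not to training.

## DTW profiling and descriptors

The DTW accumulated-cost matrix follows the classic three-predecessor
recurrence: origin 0, first row and column +∞, each interior cell adds the
local cost |aᵢ − bⱼ| to the minimum of the diagonal, left and lower
neighbours, each scaled by a tuning coefficient (all 1 by default; a
squared-cost mode is a flag). The distance is the last cell; the warping
path is recovered by traceback with a deterministic tie-break — diagonal,
then vertical, then horizontal. For sequences small enough to enumerate
every admissible warping path, the dynamic program is tested to agree with
the exhaustive minimum exactly. The per-subject *relative average DTW*
statistic reduces each record to its channel mean (the same merge the
heatmap uses) and reports, per subject, the mean distance from that
subject's signatures to all other subjects' signatures, with above/below
global-mean flags.

The descriptor set covers the three domains usually quoted for ensemble
time-series classifiers with one representative each: time (mean, sd, RMS),
frequency (dominant frequency and spectral centroid of the magnitude
spectrum, DC excluded), and complexity (permutation entropy of order 3,
normalized so a constant sequence scores 0 and white noise approaches 1;
ordinal ties break by order of occurrence). The exact descriptor formulas
behind the corresponding corpus figures are not published, so this set is a
documented stand-in with the stated conventions.

## The model zoo

Seven time-series classifiers are implemented on a small matrix-based
neural-network engine written for this package (im2col convolutions backed
by BLAS, manual backpropagation, deterministic seeding). The layer plans:

| Architecture | Plan |
|---|---|
| FCN | 3 × [conv(k 8/5/3, f 128/256/128) + batch norm + ReLU], GAP, softmax |
| MLP | flatten, 3 × dense(732) + ReLU, softmax |
| ResNet | 3 residual blocks × 3 convs (k 8/5/3), filters 64→128→256, GAP, softmax |
| Encoder | 3 × [conv(k 5/11/21, f 128/256/512, valid) + instance norm + PReLU + dropout], max-pool(2,2) after stages 1–2, split-softmax attention, softmax |
| MC-DCNN | per-channel branch: 2 × [conv(k5, 8f) + ReLU + max-pool(2,2)], concat, dense(732), softmax |
| Time-CNN | 2 × [conv(k7, 6/12f) + ReLU + avg-pool(3,3)], flatten, softmax |
| InceptionTime | 2 blocks × 3 inception modules (1×1 bottleneck 32, parallel convs k 3/5/8/11/17 + max-pool branch), residuals input→block1→block2, GAP, softmax |

Choices the layer descriptions leave open, resolved as follows:

* **Padding** is "same" for stride-1 convolutions except the Encoder, whose
  plan specifies padding 0; with a GAP head "same" vs "valid" is immaterial
  to the classifier output, and "same" keeps pooling arithmetic simple.
* **Encoder attention**: after the last convolution the channels are split
  in half, the second half is softmaxed over time and contracted against
  the first half (a dot product along time) — attention pooling rather than
  transformer self-attention.
* **Encoder dropout** is unstated; 0.2, configurable.
* **Time-CNN head** uses softmax (its original formulation used sigmoid).
* **InceptionTime** runs a single network per cell, not the original
  five-network ensemble, matching single-result reporting.
* **Input normalization** (per-channel z-scoring from training statistics)
  and batch size (16) are not specified anywhere; both are config with
  logged defaults.

Training is deterministic given the seed: initialization, shuffling and
dropout draw from one stream, and all computation is single-threaded BLAS.
Sample weights from the missing-data compensation enter the cross-entropy.
The reference hyper-parameters — learning rate 1e-5 and 1500 epochs for all
seven architectures, Adam except Adadelta (MLP) and SGD (MC-DCNN) — sit
behind `paper_defaults = TRUE`. Desk defaults keep the per-architecture
optimizer mapping but use practical rates (Adam 1e-3, Adadelta 1.0, SGD
0.01 with momentum 0.9) and a 150-epoch budget; 150 rather than a rounder
100 because Adadelta, which ramps its effective step size up slowly,
needs ~110–130 epochs to drive the 3×732-unit MLP to criterion on the desk
fixtures, and keeping the reference optimizer mapping was judged more
faithful than swapping the MLP to Adam. `stop_at_train_acc` truncates the
curves once the training accuracy reaches a threshold, which the scaled
experiments use liberally.

## Coalition experiments and attribution

`compute_characteristic()` shares one subject-stratified split and one
training seed across all coalitions of a run, so that differences in v(S)
reflect the channels, not resampling noise (per-coalition reseeding is a
flag). The empty coalition never trains; its value is chance accuracy
1/n_classes by default (a `zero` baseline is available), and efficiency is
reported as $\sum\varphi = v(P) - v(\varnothing)$ accordingly. Per-coalition
results can be cached as JSON keyed by a configuration hash, so interrupted
512-cell grids resume.

`shapley_values()` evaluates the subset-sum formula directly with exact
factorial weights accumulated in double precision — at p = 9 this is 256
subsets per channel, trivially fast next to the training grid. Percentage
shares are `100 · φᵢ / Σφ`; negative raw values (possible with noisy
accuracies) are reported as-is in φ but clipped at zero with a warning for
the percentage view, whose published analogues are all positive.
`compatibility_curves()` reports, per coalition size, the mean accuracy
with and without each channel, plus the global mean-by-size curve.

## Class activation maps

For the three GAP-headed architectures (FCN, ResNet, InceptionTime) the CAM
at time t is the class-weighted sum of the final convolutional feature
maps, $\mathrm{CAM}(t) = \sum_k w^c_k f_k(t)$, linearly upsampled from the
feature-map time axis to the record length and min–max normalized for
display (signed values are kept before normalization; a constant map
normalizes to all zeros). The explained class defaults to the prediction
and can be forced to the true label. Architectures without a GAP head are
refused with an explicit error.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own test-design sizes: corpora of 3–427 subjects with 24–1000
sample records for structural checks; the architecture overfit fixture at 5
subjects × 4 records, length 128, 3 channels; importance recovery on a
10-subject, 4-channel corpus (channel 1 informativeness 0.9 vs 0.05
elsewhere) over the full 16-coalition grid with an 8/16/8-filter FCN at up
to 100 epochs, repeated over 3 seeds; Shapley oracles at p ≤ 6 over ≥ 50
random games; DTW oracles over ≥ 100 random pairs with nm ≤ 36. The full
512-coalition, 1500-epoch reference profile remains available
(`inst/profiles/paper.yaml`) but is a long-running batch job.

## Known limitations

* The engine is CPU-only and sized for the scaled experiments; the full
  reference grid is supported but slow.
* Synthetic corpora carry no cross-channel physical coupling and no
  forgeries; verification (impostor/EER analysis) is out of scope.
* Attitude and gyroscope units are pass-through labels; no unit
  harmonization between devices is attempted.
* Whether published percentage shares derive from raw or baseline-adjusted
  Shapley values is not documented; both are available (`phi`, `shares`).
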