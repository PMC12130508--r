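# airsig

Dimension-wise Shapley-value feature selection for in-air signature
identification.

An in-air signature is a signature written in the air while holding a phone
or wearing a smartwatch, captured as a multivariate inertial time series
with nine channels: accelerometer x/y/z (m/s²), gyroscope x/y/z, and
attitude pitch/roll/yaw. `airsig` is for researchers in movement biometrics
who want to know not just *whether* a classifier can identify the signer
(closed-set identification), but *which sensor channels carry the
identifying information and how much each contributes*.

The core idea treats the nine channels as players in a coalitional game.
A coalition S ⊆ {1, …, 9} has value v(S) = the validation accuracy of a
time-series classifier trained on exactly those channels. Training all
2⁹ = 512 coalitions (an exhaustive ablation) defines the characteristic
function, and each channel's contribution is its exact Shapley value

    φ_i = Σ_{S ⊆ P\{i}}  |S|! (p−|S|−1)! / p!  · [v(S ∪ {i}) − v(S)],

normalized to percentage shares. The four Shapley axioms — dummy player,
symmetry, additivity, efficiency (Σφ = v(P) − v(∅)) — run as executable
tests on every computed map.

The package provides:

* a **seeded synthetic corpus generator** with controllable per-channel
  informativeness (the real reference corpora are not redistributable), so
  attribution can be validated against constructed ground truth;
* per-signature **CSV I/O** and corpus management;
* **preprocessing**: linear length standardization, subject-stratified
  80/20 splits, missing-record re-weighting, coalition slicing, a
  per-subject corpus heatmap statistic;
* **DTW** with accumulated cost matrix and warping path, per-subject
  relative average DTW, and time/frequency/complexity descriptors;
* a **model zoo** of seven 1-D time-series classifiers — FCN, MLP, ResNet,
  Encoder (CNN + attention), MC-DCNN, Time-CNN, InceptionTime — on a small
  deterministic neural-network engine written in R (BLAS-backed im2col
  convolutions, manual backpropagation);
* **exhaustive coalition experiments**, exact Shapley attribution,
  percentage shares and dimension-compatibility curves;
* **class activation maps** for the GAP-headed architectures (FCN, ResNet,
  InceptionTime);
* a thin **command-line interface** (`inst/cli/airsig`) with
  `generate | preprocess | dtw | descriptors | train | select | shapley |
  cam | report` subcommands, YAML configs and run manifests.

## Worked example

Generate a 10-subject corpus in which channel 1 (`acc_x`) carries 90% of
the subject-specific variance and the other channels 5%, restrict it to 4
channels, train one small FCN per coalition (16 coalitions), and attribute
accuracy to channels:

```r
library(airsig)

cfg <- generator_config(
  n_subjects = 10, duration_steps = 64, dwell_steps = 3, seed = 11,
  channel_informativeness = c(0.9, rep(0.05, 8))
)
ds  <- extract_coalition(generate_dataset(cfg, "phone"), coalition(1:4))

char <- compute_characteristic(
  ds,
  spec_for = function(nc, k) model_spec("fcn", 64, nc, k, filters = c(8, 16, 8)),
  config   = train_config("fcn", epochs = 100, seed = 1, stop_at_train_acc = 1),
  split    = split_spec(seed = 1)
)
shapley_values(char)
```

```
<shapley_report> p=4, sum(phi)=0.7 = v(P) - v(0) = 0.7
          phi share_pct
ch1  0.658333   91.8605
ch2  0.033333    4.6512
ch3  0.025000    3.4884
ch4 -0.016667    0.0000
```

Reading the output: `phi` are raw Shapley values on the accuracy scale —
channel 1 contributes ~0.66 of the 0.70 accuracy gain of the full coalition
over the chance baseline (1/10), and the percentage shares assign it ~92%,
matching the configured ground truth (`informativeness_oracle(cfg)` ranks
channel 1 first). The small negative φ for channel 4 is training noise; it
is reported as-is in `phi` and clipped to 0 in the percentage view.

The same machinery scales to the full 9-channel, 512-coalition grid
(`inst/profiles/paper.yaml`), which is a long-running batch job.

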