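---
title: "Detecting catches and drops from wrist-worn sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting catches and drops from wrist-worn sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(catchsense)
```

## The problem

A receiver wears one multisensor wearable on each wrist. Each wearable
samples tri-axial acceleration (1 kHz, ±16 g = ±156.96 m/s², with
g = 9.81 m/s²), tri-axial spin rate (1 kHz, ±1000 °/s), tri-axial magnetic
flux density (100 Hz, ±5 mT), audio (8 kHz) and absolute pressure (100 Hz,
260–1260 hPa), all at 16-bit resolution. The firmware keeps a one-second
ring buffer; when the absolute acceleration — the Euclidean norm of the
accelerometer vector, gravity included — exceeds 14 g on either wrist, both
wearables synchronously record one second before and two seconds after the
trigger. The task is to classify each recorded attempt as a *catch* or a
*drop* from the raw signals alone.

`catchsense` implements that system end to end in software: an attempt
simulator, the trigger/segmentation firmware logic, the preparation of the
fixed-shape network input, a one-dimensional convolutional classifier, and
the cross-validation and channel-ablation evaluation harness.

## The attempt simulator

Real two-wrist recordings of labeled catch attempts are not publicly
available, so the package ships a generative model that emulates the
qualitative phase structure of a catching motion. Every attempt runs through
four contiguous phases:

1. **Starting pose** — near-quiet signals; gravity plus a slowly drifting
   orientation and a small motion floor (acceleration noise SD 0.5 m/s²).
2. **Positioning** (0.6 s before impact) — band-limited movement noise
   (Gaussian noise low-passed at 30 Hz; acceleration SD 6 m/s², spin rate SD
   60 °/s). Novice athletes position more sharply: their noise is scaled by
   1.4, experts by 0.8.
3. **Catching** — a short Gaussian impulse (4 ms width) when the ball hits
   the hands. Its norm peak is drawn from 18–45 g, so every attempt is
   triggerable by construction and hard impacts visibly saturate the
   accelerometer at ±156.96 m/s², as a real ±16 g sensor does. The impulse
   is accompanied by a 60 Hz damped ring, a spin-rate transient of
   300–800 °/s, an orientation jump in the magnetometer and a broadband
   audio burst. For one-handed and body catches the off hand receives a
   reduced impact (35–75 %); both wrists always share the impact timing,
   which is what makes paired triggering meaningful.
4. **Post-impact** — both outcomes share a damped 10 Hz oscillation that
   settles into the carry pose. A *drop* additionally shows a secondary
   impact (6–14 g, 0.25–0.55 s after the first), sustained movement noise
   (extra acceleration SD 5 m/s², spin rate SD 120 °/s), a second audio
   burst, and a diverging orientation trajectory in the flux density
   (0.5–1.5 rad/s yaw drift).

Every drop-specific term scales linearly with a single `class_effect`
parameter (default 1). `class_effect = 0` therefore produces an exact null
simulator in which the two classes are statistically identical — used to
verify that classifiers and the energy baseline fall back to chance — and
the per-sensor-group multipliers (`effect_accelerometer`, …) let tests plant
the class signal into chosen channel groups only, which is how the ablation
harness is validated.

All samples are clipped to the sensor ranges and quantized to the 16-bit
grid before anything downstream sees them. The default dataset composition
is 759 attempts — 541 catches and 218 drops — with the categorical
conditions (pass source, movement, positioning, pass style, catch style,
athlete level, environment) drawn uniformly from the documented grid.
A dataset is represented by its *manifest* (scenario, label and a derived
seed per attempt); recordings are re-materialized from the seeds on demand,
so a manifest of any size is cheap to store and bit-reproducible.

What the simulator does **not** attempt: biomechanically plausible arm
trajectories, athlete-specific signatures, ball spin aerodynamics, realistic
acoustics, or any quantitative match to real signal amplitude distributions
(no public reference exists to calibrate against). Consequently, passing
tests demonstrate that the *pipeline* is correct and that the *protocol*
behaves as specified on data with a known planted effect — they do not
demonstrate field accuracy on real recordings.

## Acquisition and preparation

`detect_trigger()` scans both wrists' accelerometer norms on the shared time
base and returns the earliest sample strictly above the threshold (default
14 g = 137.34 m/s²). "Absolute acceleration" is interpreted as the vector
norm rather than a per-axis comparison, the more physical reading. The
comparison is strict (`> 14 g`), so in the calibrated impulse sweep the
16-bit quantization of the peak decides whether a nominal 14 g impulse
fires; the sweep recovers the threshold to within one 0.25 g step.

`segment_attempt()` cuts the half-open window `[trigger − 1 s, trigger + 2 s)`
from every channel, so a channel at `fs` contributes exactly `3·fs` samples
(3000 at 1 kHz, 300 at 100 Hz, 24,000 at 8 kHz); the trigger sample belongs
to the post-trigger part. The pre-buffer is exactly 1.000 s — exactness is
what makes the fixed input shape below come out.

`build_input_matrix()` upsamples every channel to 8 kHz by exact linear
interpolation (audio passes through), cuts the first 0.7 s (5600 samples) to
remove segment-head artefacts, drops the pressure channel (its outfall in
real recordings makes it unreliable; it is simulated and then excluded so
the rule is exercised), and merges both wrists into an 18,400 × 20 matrix.
The column order — left wrist acceleration x/y/z, spin rate x/y/z, flux
density x/y/z, audio, then the same ten for the right wrist — is not imposed
by any data format, so it is fixed and versioned in
`input_channel_names()`; ablation masks and every stored matrix refer to it.
No amplitude normalization happens in preprocessing: scaling is a model-side
decision (below).

## The classifier

The network is a sequential one-dimensional CNN over the 18,400 × 20 input:
three blocks of convolution → PReLU → squeeze-and-excitation → max pooling,
then global average pooling over time, one dense hidden layer with PReLU and
dropout (rate 0.3), and a single sigmoid unit emitting P(catch). The
squeeze-and-excitation stage computes per-channel means over time, passes
them through a small bottleneck (reduction ratio 4) and rescales the feature
maps with sigmoid gates — channel attention over sensor-derived features.
All activations except the output are PReLU with a learned per-channel
negative slope (initialized at 0.25). The loss is binary cross entropy; the
classification threshold is 0.5 with ties going to catch (both
configurable).

The exact per-block hyperparameters of the original architecture are not
published, so the defaults here are deliberately modest and fully recorded
in `model_config()`: filters (24, 32, 48), kernels (16, 9, 9) with stride 8
in the first block, pools (4, 4, 2), dense width 32. The default
configuration has on the order of 10⁴ trainable parameters — far fewer than
the ~2.2 × 10⁶ of the original network, a choice made for single-CPU
tractability; the builder reports its exact count, and a test checks that
count against independent layer-by-layer arithmetic.

Training uses a Ranger-style optimizer — RAdam (variance-rectified Adam)
with Lookahead (slow weights updated every 6 steps with interpolation 0.5) —
implemented in the package, with plain Adam as a configurable fallback;
reports record the optimizer name. Early stopping is epoch-level: training
stops once the validation loss has failed to improve on the running best by
at least 10⁻³ for 20 consecutive epochs (patience), up to 1000 epochs, and
the best-validation-epoch weights are restored. The bookkeeping is factored
into `early_stop_epoch()` so it can be verified against stubbed loss
sequences. "Optimization cycles" are read as epochs, the standard usage for
a patience of 20.

Two engineering choices matter for speed on one CPU and are recorded here as
design decisions: minibatch membership is fixed after one seeded shuffle and
only the batch *order* is reshuffled per epoch (this lets the first
convolution's im2col workspace be precomputed once per batch and reused
across epochs; with 10–20 samples per batch the gradient noise is ample),
and the convolutions run as single BLAS matrix products over a stacked
batch workspace written in RcppArmadillo. Backpropagation through every
layer — including the squeeze-and-excitation gates and the PReLU slopes — is
verified against central finite differences in the test suite.

### The scaled-down configuration

`scaled_model_config()` is the documented reduced preset used for
desk-scale simulation studies: filters (8, 12, 16), dense width 16, a
non-overlapping first convolution (kernel = stride = 8, i.e. a learned 1 ms
frame projection), at most 100 epochs, and per-channel standardization of
the inputs using training-fold means and standard deviations (stored with
the model and applied at prediction). Standardization is off by default in
the full configuration — preprocessing prescribes none — but the reduced
network benefits from it because the raw channel units span five orders of
magnitude (±0.05 mT flux density next to ±1000 °/s spin rates); a
reduced-capacity network should not spend its epoch budget learning that
rescaling. Early-stopping patience (20) and minimum improvement (10⁻³) keep
their defaults. Learning rate is 2 × 10⁻³ everywhere, chosen so training
loss converges within the 100-epoch cap at these problem sizes.

## Evaluation protocol

`stratified_kfold()` deals each class evenly across k = 5 folds and sends
per-class remainders to the currently smallest folds, so fold sizes differ
by at most one and per-fold class counts are within one of proportional
(759 sequences give fold sizes 152, 152, 152, 152, 151).

`run_iterations()` repeats: draw a fresh stratified split, hold fold 1 out
as the *test* fold, and perform four trainings in which the *validation*
fold (used only for early stopping) rotates through the four remaining
folds while the other three train the network. The phrase "four trainings
per iteration" admits another reading — four reseeded repeats against a
fixed split — which is available via `trainings = "reseed"`; rotation is the
default because early stopping needs a validation set distinct from the
test fold, and rotation uses each training fold once per iteration. The
test fold is never seen by training or early stopping. Per training, the
report logs test accuracy and the mispredicted sequence ids; across
iterations it accumulates per-sequence misprediction counts and their
recurrence histogram, plus three row-normalized confusion matrices: pooled
test-fold predictions (the honest one), the last model on the whole dataset
(which includes its own training folds and therefore reads optimistic — it
is reported separately and labeled as such), and the last model on its
validation fold.

`ablate()` retrains the network once per input setting with whole sensor
groups (accelerometer 6 columns, audio 2, gyroscope 6, magnetometer 6,
across both wrists) replaced by zeros in training *and* test inputs —
zeroing after preprocessing, since each setting retrains. The default grid
is the ten-row on/zero table (all on; each group zeroed alone; each group
alone; accelerometer + magnetometer). With every group zeroed the input is
constant, the network's output collapses to a constant, and accuracy equals
the majority-class share of the test fold — a degenerate-input check the
suite asserts exactly. On simulator data with the class effect planted in a
single group, zeroing that group collapses accuracy toward chance while
zeroing others does not, which validates the harness's direction.

## Numerical and degenerate-input choices

* Quantization rounds to the nearest point of the 2¹⁶-level grid spanning
  each channel's range; clipping precedes quantization.
* `resample_linear()` holds the last sample value for output points beyond
  the final input sample (constant extrapolation over at most one input
  sample period); linearity and exactness on affine signals are asserted in
  the tests.
* Standardization guards zero-variance columns (e.g. ablated groups) by
  forcing their scale to 1.
* The energy baseline `oracle_classify()` measures the RMS of the dynamic
  acceleration norm 0.5–2 s after the trigger; segments with no measurable
  impact default to "drop" (no damped-settling signature can be present).
  It is a fixed statistic, not a trained model, and exists to certify class
  separability independently of the CNN.
* Seeds: every stochastic step (scenario draws, signal noise, fold shuffles,
  weight initialization, minibatch order, dropout) flows from explicit
  integer seeds; per-attempt and per-training seeds are derived from the
  master seed, and callers' RNG state is always restored.

## Problem sizes used in the shipped studies

The packaged tests and the reproduction script run entirely on synthetic
data at sizes chosen for a single CPU: the design-goal accuracy check uses a
150-attempt dataset (107 catches, 43 drops) and the reproduction script a
300-attempt dataset (214/86, the study's 541:218 proportion), both with one
stratified 5-fold iteration (4 trainings) under the scaled-down
configuration. Ablation validations use 25–50 attempts with the tiny test
network. At these sizes the full suite and the script each finish in
minutes; the same functions scale unchanged to the full 759-attempt
composition via `default_run_config()`.

## Known limitations

* Synthetic-only validation: no claim is made about accuracy on real
  recordings; the planted class effect is almost certainly easier than the
  real catch/drop distinction, in which thresholding and classical signal
  analysis are reported not to suffice.
* The simulator's condition labels (movement, pass style, environment, …)
  modulate only a few signal parameters; they mainly exercise bookkeeping,
  not hard covariate shift.
* The CNN is much smaller than the original ~2.2 M-parameter network, and
  block hyperparameters are package defaults, not a reconstruction.
* Re-triggering within an attempt is not modeled: the first crossing wins,
  once per attempt, as in the firmware.
* Mistriggering (claps, tackles) and the three-class extension
  (catch/drop/no-attempt) are out of scope.
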