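---
title: "Identifying people from PPG waveforms: models and methods in ppgid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from PPG waveforms: models and methods in ppgid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ppgid` implements a complete identification pipeline for
photoplethysmography (PPG) waveforms: synthetic signal generation,
preprocessing, conversion of 1-D signals to 2-D Gram-matrix images,
training-set augmentation, a CNN–LSTM classifier with hand-written
backpropagation, evaluation reporting, and a streaming identification
loop. This vignette explains the models behind each stage, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the package's tests do and do not demonstrate.

## 1. The generative signal model

A PPG beat has three landmarks: the systolic peak (peak blood flow in
the cardiac cycle), the dicrotic notch (a small dip at end-systole when
the aortic valve closes), and the diastolic peak (a secondary wave).
`ppgid` models one cycle as a sum of three Gaussian bumps on the beat
interval $[0, 1)$:

$$b(t) = \sum_{j \in \{sys, dic, dia\}} a_j \exp\!\left(-\frac{(t - p_j)^2}{2 w_j^2}\right)$$

This is the simplest parametric family that reproduces the three
landmarks; each subject's identity is the parameter vector
(positions $p_j$, amplitudes $a_j$, widths, heart period, baseline,
pulse amplitude, timing jitter), held in a `subject_profile`. Profiles
are drawn from uniform ranges chosen so that (a) the landmark ordering
systolic < dicrotic < diastolic always holds, (b) the systolic peak is
always the global maximum, and (c) subjects remain distinguishable under
the default measurement noise. The dicrotic and diastolic bump widths
are tied to the systolic width (0.6x and 1.1x) so a single width
parameter controls sharpness.

A recording (`synth_signal`) concatenates beats whose periods are
jittered i.i.d. $N(0, \sigma_{jitter})$, scales to ADC counts as
`baseline + pulse_amplitude * b(t)`, adds i.i.d. Gaussian measurement
noise in counts, clips to the 18-bit range $[0, 262143]$ and rounds.
Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| subjects x recordings x samples | 40 x 80 x 300 | the acquisition-campaign shape the generator emulates |
| `sampling_rate` | 50 Hz | 300 samples then cover ~6 s, i.e. 5–8 beats; the sensor's 1 kHz ADC ceiling is a capability, not a logging rate |
| `noise_sd` | 800 counts | ~1–2% of a typical 30k–70k-count pulse excursion: visible roughness without drowning morphology |
| `adc_bits` | 18 | the sensor family's converter resolution |
| `jitter_sd` | 5–20 ms per beat | resting heart-rate variability at short range |
| `random_phase` | `FALSE` | see "capture phase" below |

One RNG stream is derived per subject from the master seed, so
`build_dataset` is bit-reproducible and adding subjects never perturbs
existing ones.

**What the generator does not emulate.** Motion artifacts, baseline
wander, skin-tone/perfusion optics, sensor contact changes, and the red
vs infrared channel structure are all absent. Consequently a perfect
test score on synthetic data shows that the pipeline machinery is
correct and that the classifier can exploit morphological differences of
the modelled kind — it does not predict accuracy on signals from real
subjects, where within-subject variability is far richer.

**Capture phase.** By default every recording starts at a beat onset.
A `random_phase = TRUE` knob starts each recording at a uniformly random
point of the cycle instead. Beat alignment is the default because the
within-subject/between-subject distance ordering — the property that
makes the subjects identifiable at all — collapses when recordings of
the same subject are mutually phase-shifted (measured within/between
mean-squared-distance ratios fall to ~1). The classifier inherits this:
it is *not* phase-invariant, and streamed captures are only reliable
when they begin near a beat onset (section 7).

## 2. Preprocessing

Two operations, in a fixed order:

* **Savitzky–Golay smoothing** (`savgol_smooth`): sliding least-squares
  polynomial fits, evaluated at each window centre; for evenly spaced
  samples this is a fixed convolution. Defaults window 11, order 3 — a
  common choice for pulse waveforms sampled at tens of Hz: wide enough
  to suppress sample-level noise, narrow enough to preserve the dicrotic
  notch. Edges are handled by evaluating the first/last window's
  polynomial at the edge offsets, preserving length. The filter
  reproduces any polynomial up to the fitted degree exactly; the test
  suite checks interior samples against an explicit per-window
  normal-equations oracle at 1e-8.
* **Min–max normalization** (`minmax_normalize`):
  $x' = (x - \min x)/(\max x - \min x)$, giving every signal the range
  $[0, 1]$. A constant signal raises an explicit degenerate-input error:
  silently mapping it to zeros would fabricate a fake identity image
  downstream. Near-constant inputs (range below ~1e-9 relative) are
  treated as constant, since a smoothed constant signal is constant only
  up to floating-point noise.

Filtering precedes normalization so the $[0,1]$ contract holds at the
boundary feeding the image conversion. Three dataset variants mirror the
evaluation protocol: `raw` (normalized only), `filtered` (smoothed then
normalized), and `mixed` — the union of both, doubling the record count,
with per-record provenance tags.

## 3. Gram-matrix images

The pipeline's 2-D representation of a normalized signal $s$ of length
$N$ is its Gramian — the outer product

$$G_{mn} = s_m s_n,$$

an $N \times N$ symmetric positive-semidefinite matrix of rank at most
1 whose diagonal is $s^2$ and whose bright off-diagonal cells mark pairs
of jointly large samples; the beat structure appears as a periodic
lattice. The pairwise-dot-product form between whole signals,
$G_{ij} = \sum_k s_{i,k} s_{j,k}$, is kept as `cross_gram` for
similarity analysis across recordings. The per-signal outer product is
the operational choice because the classifier needs one image per
recording; whether the original system used exactly this form, a
Gramian angular field, or dot products over sliding segments is not
recoverable, so the chosen form is stated here and implemented
literally. Angular-field and Markov-transition variants are deliberate
non-goals.

`render_gram` min–max rescales the matrix to $[0,1]$ intensity and
bilinearly resamples to a fixed side (default 64 for desk-scale
training; 224 is the conventional side for the full-scale model
family). A constant matrix renders as all-zero intensity by convention.
Rendering is invariant to positive scaling of the matrix, so the
classifier sees shape, not amplitude.

## 4. Augmentation

Training-set-only, by construction: `augment_dataset` refuses records
not tagged `train` (leakage guard). Three composable operators:

* `hflip` — column reversal (an involution);
* `sv_perturb` — SVD $U\,\mathrm{diag}(\sigma)\,V^\top$ with each
  singular value scaled by $1 + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma_{sv})$, negatives clipped; exact
  round-trip at $\sigma_{sv}=0$, rank-1 inputs stay rank 1, and the
  Frobenius distortion equals $\|\sigma \odot \varepsilon\|_2$ by
  unitary invariance;
* `pca_perturb` — scores of the top-$k$ row-space principal components
  scaled by $1 + \varepsilon$, reconstructed with the
  discarded-component residual re-added (lossless at $\sigma = 0$ for
  any $k$);
* `rotate_raster` — rotation about the centre bounded by 90 degrees,
  bilinear with zero fill (zero Gram intensity means "no similarity",
  so background is neutral; reflection fill would fabricate structure);
  right angles are exact index permutations.

The default per-copy operator draws between the flip+SV chain and a
uniform random rotation in $[-90°, +90°]$. The expansion contract is
exact: `copies_per_image = 10` turns 2560 training images into 28,160
records (originals plus ten copies each) — an ~11x expansion. Each
augmented record carries its source id and operator chain in a
provenance sidecar.

## 5. The classifier

`ppgnet` trains a compact CNN–LSTM implemented entirely in base R,
including the backward pass (no external deep-learning runtime):

* **Stem**: 3x3 convolution, stride 2 —
  $y(i,j,k) = \sum_{m,n,c} x(i{+}m, j{+}n, c)\, Q(m,n,c,k) + B(k)$ with
  same padding — then batch normalization and activation.
* **Inverted-residual blocks**: pointwise expansion (factor $t$),
  depthwise 3x3 (stride 1 or 2), squeeze-and-excitation, pointwise
  projection; batch normalization after each convolution; the input is
  added back when stride is 1 and channel counts match. The published
  formula for this block is internally inconsistent (it never uses the
  pointwise weights it defines), so the standard composition the
  surrounding prose describes is implemented.
* **Squeeze-and-excitation**: global average pooling per channel, a
  two-layer bottleneck (reduction ratio 4), sigmoid gate in $(0,1)$
  multiplying each channel.
* **Swish** ($v\,\sigma(v)$) hidden activations by default; ReLU and
  leaky ReLU selectable.
* **Sequence head**: the final $H' \times W' \times C'$ feature map is
  read as a sequence of $H'$ time steps (one per row, each the
  concatenation of that row across columns and channels), consumed by an
  LSTM whose final hidden state feeds a dense softmax layer. Rows were
  chosen as time steps because a single image has no intrinsic frame
  axis; the mapping is deterministic and shape-preserving.

Two presets: `tiny` (input 64, stem 8 channels, 3 blocks, 32 LSTM
units, ~25k parameters at 8 classes — the configuration all tests
train) and `paper` (input 224, the full B0-family block layout, 21
blocks, 256 LSTM units, ~66 weighted layers, millions of parameters —
buildable and inspectable, never trained here). Training from random
initialization only; pretrained-weight transfer is out of scope, which
is the main reason desk-scale results are not comparable to a
transfer-learned full-scale system.

Correctness of the network rests on two oracle families in the test
suite: brute-force loop evaluation of the convolution equation (1e-10)
and central-difference gradient checks through the entire network
(relative error below 1e-4; measured ~1e-7).

## 6. Training protocol and evaluation

* **Split**: stratified per subject (so all classes appear on both
  sides), 80/20 by default, seeded shuffle.
* **Settings**: three presets for the ablation grid — batch 16 / SGD /
  lr 0.01, batch 32 / Adam / lr 0.001, batch 64 / RMSprop / lr 0.0001 —
  with hidden activation Swish / ReLU / leaky ReLU respectively. The
  first setting's activation is listed as "Softmax" in the source
  protocol; softmax is always the output layer, so it is read as "the
  default hidden activation", i.e. Swish.
* **Loss**: categorical cross-entropy (implied by the softmax head).
* **Early stopping**: up to 25 epochs, patience 10 on validation loss,
  best-epoch weights restored. The validation set is carved (10%) from
  the training data after augmentation, since the protocol names a
  validation set but specifies only a train/test split. With a
  never-improving validation loss the rule halts at epoch 11 exactly;
  reproducing that boundary case requires freezing the
  batch-normalization running statistics (`bn_momentum = 1`) as well as
  the weights, because running-statistic drift alone moves the
  validation loss.
* **Evaluation**: confusion matrix (rows = truth), per-class precision
  / recall / F1 with the zero-denominator convention (score 0, with a
  warning), macro and support-weighted averages, accuracy. Metrics are
  cross-checked against an independent implementation (`caret`) in the
  tests.
* **Ablation harness**: `ablation()` trains one model per
  (setting x dataset-variant) cell and emits a tidy accuracy table.

**Problem sizes.** The test suite and the acceptance script train the
tiny preset on 8 subjects x 40 recordings (256 training images at side
64) for up to 25 epochs, three seeds — a deliberately small
configuration that a single CPU handles in a few minutes while still
exercising every stage at the study's record length and ADC scale. The
structural counts (3200 / 2560 / 640 / 300 / 262143) are checked at the
full 40 x 80 scale, where no training is involved.

## 7. Streaming identification

`stream_from_vector` / `stream_from_file` replay stored counts;
`stream_from_generator` synthesizes a beat-continuous stream (no phase
resets between beats, as a live sensor would deliver).
`stabilize_and_capture` discards exactly
`round(stabilization x sampling_rate)` samples — the settling period
after a sensor is applied, 25 s in the deployed workflow — then captures
a single window (default 300 samples). `identify` runs the identical
preprocess → Gram → render → predict chain as the offline pipeline, so
offline and streaming probability vectors agree exactly on the same
window; `run_session` loops capture/identify, prints label and
confidence, and writes a session CSV with per-stage timings. Timings
are reported, not claimed: they are properties of this implementation
on the host machine.

How a deployed system should map tens of seconds of stream onto one
300-sample model input is genuinely open (decimation, multiple windows
with voting, beat-onset triggering); the package implements
single-window capture and leaves voting as an extension point.

## 8. Numerical choices and degenerate inputs

* Constant (or numerically constant) signals: explicit error at
  normalization, surfaced to the streaming user.
* Degenerate raster rescale (max = min): all-zero intensity.
* Negative singular values after perturbation: clipped to 0.
* Rotation at exact right angles: index permutation, no interpolation.
* F1 with zero support or zero predictions: 0 with a warning.
* Batch normalization: epsilon 1e-5, running-statistic momentum 0.9
  (configurable), biased batch variance.
* Beat period jitter draws are clamped so a beat never falls below the
  10-sample resolvability floor.
* All stochastic stages (profile draws, noise, splits, shuffles,
  augmentation, initialization) run on seeds derived deterministically
  from a single master seed via a fixed integer recurrence kept below
  2^31.

## 9. Known limitations

* The generator's realism gap (section 1): results on synthetic cohorts
  bound nothing about real-subject accuracy.
* Phase sensitivity: identification assumes capture near a beat onset;
  arbitrary-phase deployment would need onset triggering or
  phase-randomized training, which trades away the clean within-subject
  geometry.
* The tiny preset's capacity is matched to the synthetic task; at 40
  classes with realistic noise it would need scaling up.
* Pure-R training is practical only at desk scale; the `paper` preset
  exists for structural inspection, not training.
* `sv_perturb` returns both the matrix and the applied singular-value
  changes; pipelines use `$out`, and the extra bookkeeping exists so
  distortion accounting stays testable.
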