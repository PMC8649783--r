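---
title: "Task-weight classification from fused EEG-EMG images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-weight classification from fused EEG-EMG images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During dynamic elbow flexion-extension, the external weight a person holds
(here 0, 3 or 5 lbs) modulates both muscle activation (surface EMG over
biceps and triceps) and sensorimotor cortical rhythms (EEG over C3, C4 and
Cz). `neurofuse` implements an input-level fusion approach to decoding the
task weight: instead of extracting hand-crafted features from each
modality and fusing decisions, both signals are rendered into a single
image per 250 ms window and a convolutional neural network (CNN) learns
the discriminative structure directly. Three weight classes give a chance
level of 33.33%.

The pipeline is subject-specific end to end: models, hyperparameters and
normalization statistics are all fitted per subject.

## The synthetic session generator

Laboratory EEG/EMG sessions of this kind cannot be redistributed, so the
package ships a seeded generator (`generate_recording()`) that reproduces
the *structure* of such a session: 6 trials (2 speeds x 3 weights), 3
repetitions per trial, 5 channels at 4,000 Hz, with movement start/end
markers. Slow repetitions default to 30 s of movement and fast repetitions
to 2 s, with a 3 s inter-repetition pause split around each repetition.

The generative model encodes the two physiological effects the classifier
is supposed to exploit, each behind an explicit dial (`effect_model()`):

* **EMG amplitude scaling.** Each EMG channel is a Gaussian carrier
  band-limited to 20-500 Hz, multiplied by a raised-cosine activation
  envelope: the biceps envelope peaks in the first (flexion) half of the
  movement, the triceps envelope in the second (extension) half, on top of
  a 5% resting tone. The envelope amplitude is
  `(1 + emg_gain_per_lb * weight)`, with an extra `speed_gain` factor
  (default 1.3) for fast repetitions. The default gain, 0.15/lb, makes the
  5 lbs class 1.75x the amplitude of 0 lbs -- a strong but not trivial
  effect, chosen once as a plausible activation scaling over this load
  range.
* **Event-related desynchronization (ERD).** EEG channels are 1/f
  background noise plus mu (8-12 Hz) and beta (13-30 Hz) band-limited
  oscillations; during the marked movement portion the oscillation power
  is reduced by `eeg_erd_depth_per_lb * weight` (default 0.05/lb, i.e. a
  25% mu/beta power reduction at 5 lbs). This is deliberately a much
  weaker class signal than the EMG gain, mirroring the usual finding that
  EEG alone decodes load far worse than EMG.

Band-limited carriers are synthesized by zeroing FFT bins outside the
band. This is a deliberate numerical choice: at a 4,000 Hz sampling rate
the mu band is 0.2-0.3% of Nyquist, where cascaded IIR (Butterworth)
designs in transfer-function form are numerically unstable under
forward-backward filtering. Frequency-domain truncation is exact, stable
at any band width, and deterministic.

Amplitudes are calibrated so EMG ~ 1 mV and EEG ~ 0.01 mV (a realistic
~100:1 ratio); this forces the per-modality normalization described below
to matter. Motion artifacts -- low-frequency (<5 Hz) raised-cosine
transients at 10x channel scale on all channels -- occur at
`artifact_rate` events/s (default 0.1) to exercise the band-pass filters.
Each recording derives a single RNG stream from `(seed, subject_id)`, so
subjects are independent but every array is bit-reproducible.

What the generator does *not* emulate: volume conduction and cross-channel
covariance, non-stationary fatigue (beyond an optional spectral-shift
hook), eye/cardiac artifacts, or inter-subject variability in effect
sizes. Passing the end-to-end tests therefore shows the pipeline can
recover a weight signal *of the kind and relative strength injected*, not
that real-data accuracies are reproduced.

## Preprocessing

Software filtering follows standard practice for these modalities: EEG
0.5-40 Hz (3rd-order Butterworth), EMG mean-subtraction then 20-500 Hz
(4th-order Butterworth). Filters are applied zero-phase
(forward-backward, `signal::filtfilt`), a choice the offline setting
permits; the realized magnitude response is then the square of the
single-pass response (e.g. ~92% amplitude rejection of 60 Hz mains on the
EEG band rather than the single-pass 72%), and tests assert against this
realized response.

Repetitions are truncated to the half-open marker range
`[start_marker, end_marker)`. Indices are 1-based half-open throughout --
the half-open convention keeps every window/segment length a plain
difference, and 1-based is the native R idiom. Windowing then cuts
250 ms windows (1,000 samples) with 50% overlap (step 500); a repetition
of `N >= 1000` samples yields `floor((N - 1000)/500) + 1` windows
(a 30 s slow repetition gives 239, a 2 s fast repetition 15) and trailing
partial windows are discarded rather than padded. Weight classes are
encoded by rank: 0 lbs -> 0, 3 lbs -> 1, 5 lbs -> 2.

## Images

**Spectrograms.** Each channel window is transformed with an STFT: Hann
window of 56 samples, 75% overlap (hop 14), frames starting at sample 1
with no centering or padding -- the unique alignment that yields exactly
68 frames from 1,000 samples. FFT length is 3,200 for EEG and 256 for
EMG; after dropping the DC bin and keeping bins `1..floor(f_high/df)`,
both modalities produce 32 frequency bins (EEG: df = 1.25 Hz, 40/1.25 =
32; EMG: df = 15.625 Hz, 500/15.625 = 32). The magnitude is plain
one-sided linear `|STFT|` (no dB scaling, no window-power correction);
a `log_magnitude` flag exists but defaults off.

One physical consequence worth stating: a 56-sample window at 4,000 Hz
spans 14 ms, so the Hann main lobe is roughly +/-143 Hz wide. Within the
0.5-40 Hz EEG crop this means individual rhythms are *not* resolved --
EEG spectrogram rows carry broadband band-energy rather than localized
peaks, and a low-frequency test tone does not localize to "its" bin. The
EMG crop (15.625 Hz bins over 20-500 Hz) does localize tones to the
nearest bin, and the test suite pins both behaviours against a
brute-force DFT oracle.

**Normalization.** For each subject and each modality separately, the
global min/max over all of that subject's spectrogram magnitudes (or raw
amplitudes, for signal images) maps values affinely onto [0, 1]; a
degenerate max = min maps to 0. Fitting over *all* of a subject's windows
(training, validation and test) is the default because it matches the
subject-wise procedure this protocol is built around; it does leak test
extrema into training inputs, so a `norm_scope = "train"` mode is
provided for leakage-free experiments. The default stays
protocol-faithful.

**Fusion layouts.** Normalized per-channel images combine into

| layout | shape (H x W [x C]) | arrangement |
|---|---|---|
| `grouped` | 160 x 68 | rows C3, C4, Cz, biceps, triceps |
| `mixed` | 160 x 68 | rows C3, biceps, C4, triceps, Cz |
| `stacked` | 32 x 68 x 5 | depth-wise channel stack |
| `eeg_stack` / `emg_stack` | 96 x 68 / 64 x 68 | single-modality baselines |
| `eeg_multi` / `emg_multi` | 32 x 68 x 3 / x 2 | multi-channel baselines |
| `signal_full` / `signal_eeg` / `signal_emg` | 5/3/2 x 1000 | time-domain signal images |

Signal images are the filtered time series themselves, channels stacked
vertically, EEG rows normalized with the EEG amplitude extrema and EMG
rows with the EMG extrema.

## Models

Three CNN families (all hidden activations ReLU, softmax output over 3
classes, valid padding, stride 1):

* `spectro2d`: 3 x [conv2d -> maxpool 2x2 -> dropout] followed by
  2 x [dense -> dropout] and the output layer; consumes any spectrogram
  layout (vertical layouts as H x W x 1 tensors, depth layouts as
  32 x 68 x C).
* `split_conv`: a temporal 1 x k convolution, then a spatial
  (height x 1) convolution collapsing the channel axis, maxpool 1x2,
  dropout, then the dense head; consumes signal images as
  channels x 1000 x 1.
* `conv1d`: 3 x [1-D conv -> maxpool 2 -> dropout] plus the dense head;
  consumes signal images as 1 x 1000 x channels sequences.

Because no deep-learning framework is available to R in this environment,
the engine is implemented in the package: im2col + BLAS GEMM convolution
with the exact scatter-add adjoint (compiled via Rcpp/RcppArmadillo),
max-pooling with argmax routing, inverted dropout, dense layers,
categorical cross-entropy and Adam (beta1 0.9, beta2 0.999, eps 1e-7 --
only the learning rate is tuned). The test suite verifies backpropagated
gradients against central finite differences, and shape propagation
(`out = in - k + 1`; `floor(in/p)`) is asserted against realized tensor
shapes for randomly sampled architectures.

**Hyperparameter search.** `tune_model()` runs pure random search over
the space in `search_space()`: 2-D kernels {3x3, 5x5} (layer 3 may also
draw 7x7; multi-channel inputs fix all kernels at 3x3), 1-D kernel widths
3-55 step 2, filters {8, ..., 1024} (<=512 for `split_conv`), dropout
0-0.5 step 0.05, dense units 20-500 step 20, and a log-uniform Adam
learning rate on [1e-5, 1e-2]. Design points the source protocol leaves
open were fixed as follows: every tunable slot is drawn independently per
layer; each sampled configuration is trained twice and scored by the
*minimum* validation loss of its repeats (an optimistic pick, recorded
alongside both scores in the search log); infeasible shape chains are
resampled rather than raised. Training uses batch size 32, an epoch limit
of 50 and early stopping with patience 5 on validation loss, restoring
the best-epoch weights (standard practice; recorded in the history). A
fit whose loss becomes non-finite is scored infinitely bad and abandoned.

## Evaluation protocol

Per subject: repetitions 1-2 of every trial are training data; repetition
3 is shuffled (seeded) and split 50/50 into validation and test with
stratification by class, so per-class counts differ by at most one.
Reports contain overall accuracy, accuracy separated by movement speed
(the overall accuracy is exactly the size-weighted mean of the two),
the 3x3 confusion matrix, class-wise precision and recall (0/0 reported
as 0 with a flag), and a macro F-score. Across subjects, accuracies
aggregate as unweighted mean +/- sample (n-1) SD; confusion matrices sum
into a pooled matrix from which pooled precision/recall/F derive. Both
the pooled F and the mean of per-subject macro F are emitted, labelled,
since the two conventions differ. Argmax ties break toward the lowest
class index.

`compare_models()` provides the one-way within-subjects ANOVA (F tested
against the model x subject stratum via `stats::aov`) with Bonferroni-
corrected pairwise paired t-tests, at the conventional 0.05 threshold.
Zero-variance pairs are flagged and reported as p = 0 (nonzero offset) or
p = 1 (identical); sphericity corrections are out of scope. The full
speed x model two-way ANOVA is reduced to reporting per-speed accuracies
plus this one-way utility.

## Problem sizes for the reduced runs

The full protocol (32 subjects, 30 s slow repetitions, 50-trial search
trained twice) is a cluster-scale computation. The package's test suite
and acceptance script run a *reduced protocol*, chosen once as the
smallest configuration that still exercises every stage meaningfully: one
synthetic subject with 6 s slow and 2 s fast repetitions (558 windows:
372 train, 93 validation, 93 test), a 5-configuration random search with
one fit each, a 15-epoch limit, and a reduced space
(`quick_search_space()`: filters {8, 16}, dense 20-100, dropout 0-0.3,
learning rate [1e-4, 3e-3]) that keeps single fits in the tens of
seconds on one CPU. Under these conditions the grouped-fusion model is
expected to clear 45% test accuracy (chance 33.33%) and the EMG-only
baseline to beat the EEG-only baseline -- the qualitative ordering the
generator's effect sizes encode. The EEG/EMG-only baselines use one fixed
mid-sized configuration rather than their own search, since only their
ordering, not their optimum, is under test.

## Known limitations

* The CNN engine is single-threaded per GEMM call and trades generality
  for auditability: no GPU, no batch normalization (rejected in the
  source protocol anyway), no data augmentation.
* The generator's effect sizes are free parameters of the synthetic
  model, not measured physiology; absolute accuracies on synthetic data
  do not transfer to real recordings.
* Normalization's default all-windows scope leaks test statistics by
  construction (see above); use `norm_scope = "train"` when that matters.
* The EDF import hinted at by the recording container is not provided;
  recordings interchange via the package's CSV + JSON directory format.
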