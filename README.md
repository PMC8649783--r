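# neurofuse

Input-level EEG–EMG fusion with convolutional neural networks, for
classifying the external **task weight** (0, 3 or 5 lbs) held during
dynamic elbow flexion–extension.

Wearable-exoskeleton control systems benefit from knowing what load the
user is holding. Both bioelectrical signals available at the interface
carry weight information: surface EMG amplitude over the prime movers
(biceps, triceps) grows with load, and sensorimotor EEG rhythms over
C3/C4/Cz show load-dependent event-related desynchronization (ERD) of the
mu (8–12 Hz) and beta (13–30 Hz) bands. `neurofuse` fuses the two
modalities *at the input level*: each 250 ms window of the 5-channel
recording is rendered as one image — either a short-time Fourier
transform (STFT) spectrogram stack or a raw time-domain signal image —
and a CNN classifies the window into one of the three weight classes
(chance level 1/3).

The package implements the full experimental pipeline:

* **Synthetic sessions** — `session_spec()`, `effect_model()`,
  `generate_recording()`: seeded 2-speed × 3-weight factorial sessions
  (5 channels at 4,000 Hz, movement markers) with controllable EMG gain
  per lb, ERD depth per lb, noise and motion artifacts. Recordings
  round-trip to a CSV + JSON directory (`write_recording()` /
  `read_recording()`).
* **Preprocessing** — `filter_recording()` (zero-phase Butterworth,
  EEG 0.5–40 Hz order 3, EMG DC-removal + 20–500 Hz order 4),
  `segment_movement()` (marker-based truncation), `make_windows()`
  (250 ms windows, 50% overlap).
* **Imaging** — `spectrogram()` (Hann 56, 75% overlap, FFT 3,200/256 →
  68 × 32 images per channel), per-subject per-modality min–max
  normalization, and the fusion layouts: `grouped` (160 × 68), `mixed`,
  `stacked` (32 × 68 × 5), EEG/EMG-only baselines, and 1,000 × 5 signal
  images (`build_image_dataset()`).
* **Models** — three CNN families (`spectro2d`, `split_conv`, `conv1d`)
  with a compiled im2col convolution engine, Adam, early stopping
  (patience 5, epoch limit 50, batch 32), shape-chain validation
  (`propagate_shapes()`), and random-search tuning over the published
  hyperparameter space (`search_space()`, `tune_model()`).
* **Evaluation** — subject-specific splits (reps 1–2 train, rep 3
  stratified 50/50 validation/test), accuracy, per-speed accuracy,
  confusion matrices, precision/recall/F (`evaluate_model()`,
  `aggregate_reports()`) and within-subjects ANOVA with Bonferroni
  pairwise comparisons (`compare_models()`).
* **Orchestration** — `run_pipeline()` and a thin CLI
  (`inst/cli/neurofuse.R`) drive the whole chain from a YAML config.

## Worked example

One synthetic subject under the reduced protocol (6 s slow repetitions),
grouped-fusion spectrogram model with a 5-configuration random search:

```r
library(neurofuse)

spec <- session_spec(subject_id = "S01", slow_duration = 6,
                     fast_duration = 2, seed = 11)
rec  <- generate_recording(spec)
rec
#> <nf_recording> subject S01: 6 trials, 18 repetitions, 5 channels @ 4000 Hz

ws <- make_windows(segment_movement(filter_recording(rec)))
ws
#> <nf_window_set> 558 windows of 1000 samples x 5 channels @ 4000 Hz
#>       speed
#> weight fast slow
#>      0   45  141
#>      3   45  141
#>      5   45  141

split <- split_windows(ws, split_spec(seed = 11))
data  <- model_data(build_image_dataset(ws, "grouped"), split)
tuned <- tune_model(data, "spectro2d", quick_search_space(),
                    train_spec(max_epochs = 15, search_trials = 5,
                               trainings_per_trial = 1, seed = 11),
                    layout = "grouped")
evaluate_model(tuned$best_model, data$test, "S01")
#> <nf_eval_report> S01: accuracy 53.76% (n = 93), macro F 51.62%
#>   per-speed accuracy: fast 61.90%, slow 51.39%
#>     predicted
#> true  0  1 2
#>    0 24  7 0
#>    1 12 18 1
#>    2  7 16 8
```

Reading the report: 53.8% test accuracy against a 33.3% chance level —
the network recovered weight information from the fused image. The
confusion matrix shows the typical pattern: the unloaded class (0 lbs) is
recognized best, while 3 lbs and 5 lbs are mostly confused *with each
other*, not with 0 lbs. (The search here is deliberately small; this is
a demonstration run, not a tuned model.)

The same protocol with single-modality baselines (`emg_multi`,
`eeg_multi` layouts) reproduces the expected ordering: EMG-only beats
EEG-only, and fusion sits at or above EMG-only.

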