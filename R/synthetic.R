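#' Session specification for a synthetic recording
#'
#' Describes one subject's recording session: a 2 speed x 3 weight full
#' factorial of trials, each trial containing `reps_per_trial` repetitions of
#' elbow flexion-extension. Slow repetitions last `slow_duration` seconds and
#' fast repetitions `fast_duration` seconds; repetitions are padded on both
#' sides with half the inter-repetition pause so that movement markers fall
#' strictly inside each repetition's sample array.
#'
#' @param subject_id Subject identifier (string); combined with `seed` to
#'   derive the per-subject random stream, so different subjects generated
#'   from the same seed are independent but reproducible.
#' @param sampling_rate Sampling rate in Hz. Must exceed twice the upper EMG
#'   band edge (500 Hz).
#' @param slow_duration,fast_duration Target movement duration in seconds for
#'   slow (~10 deg/s) and fast (~150 deg/s) repetitions.
#' @param weights Ordered vector of task-weight levels in lbs (strictly
#'   increasing); these are the class labels.
#' @param reps_per_trial Repetitions per speed-weight trial.
#' @param inter_rep_pause Pause between repetitions in seconds; half of it is
#'   kept as idle signal on each side of a repetition.
#' @param seed Integer seed for the session's random stream.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(subject_id = "S01",
                         sampling_rate = 4000,
                         slow_duration = 30,
                         fast_duration = 2,
                         weights = c(0, 3, 5),
                         reps_per_trial = 3,
                         inter_rep_pause = 3,
                         seed = 1L) {
  if (slow_duration <= 0 || fast_duration <= 0)
    stop("repetition durations must be positive")
  if (sampling_rate <= 2 * 500)
    stop("sampling_rate must exceed twice the upper EMG band edge (500 Hz)")
  if (reps_per_trial < 1)
    stop("reps_per_trial must be >= 1")
  if (length(weights) < 2 || any(diff(weights) <= 0))
    stop("weights must be strictly increasing")
  structure(list(subject_id = as.character(subject_id),
                 sampling_rate = sampling_rate,
                 slow_duration = slow_duration,
                 fast_duration = fast_duration,
                 weights = weights,
                 reps_per_trial = as.integer(reps_per_trial),
                 inter_rep_pause = inter_rep_pause,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Effect model for the synthetic generator
#'
#' Encodes how task weight and movement speed shape the generated signals:
#' active-muscle EMG amplitude grows multiplicatively with weight and with
#' fast movement, while EEG mu (8-12 Hz) and beta (13-30 Hz) band power over
#' the motor cortex is reduced during movement (event-related
#' desynchronization, ERD) in proportion to weight.
#'
#' @param emg_gain_per_lb Multiplicative EMG amplitude gain per lb of task
#'   weight (active muscle).
#' @param emg_fatigue_spectral_shift Optional downward shift of the EMG
#'   carrier band per repetition, in Hz (fatigue hook; default off).
#' @param eeg_erd_depth_per_lb Fractional reduction of mu/beta band power per
#'   lb during movement. `eeg_erd_depth_per_lb * max(weights)` must stay
#'   below 1 so band power remains positive.
#' @param speed_gain Extra EMG amplitude factor applied to fast repetitions.
#' @param noise_sd Additive white-noise level, relative to each channel's
#'   base amplitude.
#' @param artifact_rate Expected number of low-frequency (<5 Hz)
#'   high-amplitude motion-artifact transients per second, shared across all
#'   channels.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(emg_gain_per_lb = 0.15,
                         emg_fatigue_spectral_shift = 0,
                         eeg_erd_depth_per_lb = 0.05,
                         speed_gain = 1.3,
                         noise_sd = 0.05,
                         artifact_rate = 0.1) {
  if (emg_gain_per_lb < 0 || eeg_erd_depth_per_lb < 0 || speed_gain < 0 ||
      noise_sd < 0 || artifact_rate < 0)
    stop("all effect-model gains and rates must be >= 0")
  structure(list(emg_gain_per_lb = emg_gain_per_lb,
                 emg_fatigue_spectral_shift = emg_fatigue_spectral_shift,
                 eeg_erd_depth_per_lb = eeg_erd_depth_per_lb,
                 speed_gain = speed_gain,
                 noise_sd = noise_sd,
                 artifact_rate = artifact_rate),
            class = "effect_model")
}

# Channel layout shared by the whole package.
nf_channels <- function() c("C3", "C4", "Cz", "biceps", "triceps")
nf_modality <- function() c("EEG", "EEG", "EEG", "EMG", "EMG")
eeg_rows <- function() 1:3
emg_rows <- function() 4:5

# EMG/EEG base amplitudes in mV; the ~1:100 EEG:EMG ratio forces the
# per-modality normalization downstream to matter.
EMG_BASE_MV <- 1.0
EEG_BASE_MV <- 0.01

# Evaluate a function under a temporary RNG state, restoring the caller's.
with_local_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# Derive an integer stream seed from (seed, subject_id), kept below 2^31.
subject_seed <- function(seed, subject_id) {
  codes <- utf8ToInt(subject_id)
  h <- sum(codes * seq_along(codes)) %% 100000L
  as.integer((abs(seed) %% 20000L) * 100000L + h)
}

# Band-limited Gaussian noise normalized to unit RMS. Band-limiting is done
# in the frequency domain (zeroing FFT bins outside the band), which stays
# exact and stable for arbitrarily narrow bands relative to the sampling
# rate -- the regime of the mu and beta carriers at 4,000 Hz.
band_noise <- function(n, band, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)              # two-sided spectrum
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# 1/f-amplitude background noise via FFT spectral shaping, unit RMS.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # mirror for the negative-frequency half
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Raised-cosine activation envelope over a fraction of the movement.
# tau in [0,1] across the movement; the bump occupies [lo, hi].
phase_envelope <- function(tau, lo, hi) {
  env <- numeric(length(tau))
  inside <- tau >= lo & tau <= hi
  env[inside] <- sin(pi * (tau[inside] - lo) / (hi - lo))^2
  env
}

#' Generate a synthetic EEG-EMG recording session
#'
#' Builds one subject's session: 6 trials (slow/fast x each weight level),
#' each with `reps_per_trial` repetitions of 5-channel signal (C3, C4, Cz,
#' biceps, triceps) at the session sampling rate. EMG channels are a
#' band-limited (20-500 Hz) stochastic carrier shaped by phase-locked
#' raised-cosine envelopes (biceps peaks during the flexion half of the
#' movement, triceps during the extension half) and scaled by
#' `(1 + emg_gain_per_lb * weight)` and, for fast repetitions, `speed_gain`.
#' EEG channels are 1/f background plus mu- and beta-band oscillations whose
#' power during the marked movement portion is reduced by
#' `eeg_erd_depth_per_lb * weight`. Occasional low-frequency high-amplitude
#' transients are added to all channels at `artifact_rate` events/s.
#' Output is bit-identical for identical `(spec, effects)`.
#'
#' @param spec A [session_spec()].
#' @param effects An [effect_model()].
#' @return An object of class `nf_recording`: list with `subject_id`,
#'   `sampling_rate`, `channel_names`, and `trials`; each trial carries
#'   `speed_label`, `weight_label` and a list of repetitions with a
#'   channels-by-time `samples` matrix (mV) plus `start_marker`/`end_marker`
#'   (1-based, half-open) bracketing the movement.
#' @export
generate_recording <- function(spec, effects = effect_model()) {
  stopifnot(inherits(spec, "session_spec"), inherits(effects, "effect_model"))
  if (effects$eeg_erd_depth_per_lb * max(spec$weights) >= 1)
    stop("eeg_erd_depth_per_lb too deep: mu/beta band power would become non-positive")
  fs <- spec$sampling_rate
  with_local_seed(subject_seed(spec$seed, spec$subject_id), function() {
    trials <- list()
    for (speed in c("slow", "fast")) {
      dur <- if (speed == "slow") spec$slow_duration else spec$fast_duration
      for (w in spec$weights) {
        reps <- lapply(seq_len(spec$reps_per_trial), function(r)
          generate_repetition(fs, dur, spec$inter_rep_pause, speed, w, r, effects))
        trials[[length(trials) + 1L]] <-
          list(speed_label = speed, weight_label = w, reps = reps)
      }
    }
    structure(list(subject_id = spec$subject_id,
                   sampling_rate = fs,
                   channel_names = nf_channels(),
                   trials = trials),
              class = "nf_recording")
  })
}

generate_repetition <- function(fs, dur, pause, speed, weight, rep_index, effects) {
  pad <- as.integer(round(pause / 2 * fs))
  n_move <- as.integer(round(dur * fs))
  n <- n_move + 2L * pad
  start <- pad + 1L                 # 1-based, half-open [start, end)
  end <- start + n_move
  tau <- rep(NA_real_, n)
  tau[start:(end - 1L)] <- seq(0, 1, length.out = n_move)
  tau_all <- ifelse(is.na(tau), -1, tau)

  amp <- EMG_BASE_MV * (1 + effects$emg_gain_per_lb * weight) *
    (if (speed == "fast") effects$speed_gain else 1)
  band <- c(20, 500) - effects$emg_fatigue_spectral_shift * (rep_index - 1)
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("fatigue-shifted EMG band fell outside (0, Nyquist)")

  samples <- matrix(0, nrow = 5L, ncol = n,
                    dimnames = list(nf_channels(), NULL))
  env_b <- phase_envelope(tau_all, 0, 0.5)   # flexion half
  env_t <- phase_envelope(tau_all, 0.5, 1)   # extension half
  tone <- 0.05
  samples[4L, ] <- amp * (tone + env_b) * band_noise(n, band, fs)
  samples[5L, ] <- amp * (tone + env_t) * band_noise(n, band, fs)

  erd <- sqrt(1 - effects$eeg_erd_depth_per_lb * weight)
  moving <- !is.na(tau)
  for (ch in eeg_rows()) {
    mu <- band_noise(n, c(8, 12), fs)
    beta <- band_noise(n, c(13, 30), fs)
    scale <- ifelse(moving, erd, 1)
    samples[ch, ] <- EEG_BASE_MV *
      (pink_noise(n) + 0.5 * scale * mu + 0.3 * scale * beta)
  }

  base_amp <- c(rep(EEG_BASE_MV, 3), rep(EMG_BASE_MV, 2))
  samples <- samples + effects$noise_sd * base_amp *
    matrix(stats::rnorm(5L * n), nrow = 5L)

  n_art <- stats::rpois(1, effects$artifact_rate * n / fs)
  if (n_art > 0) {
    width <- round(0.5 * fs)
    for (k in seq_len(n_art)) {
      at <- sample.int(n - width, 1L)
      f_art <- stats::runif(1, 0.5, 4.5)
      tt <- seq_len(width) / fs
      bump <- sin(pi * seq_len(width) / width)^2 * sin(2 * pi * f_art * tt)
      idx <- at:(at + width - 1L)
      samples[, idx] <- samples[, idx] +
        outer(10 * base_amp, bump)
    }
  }

  list(samples = samples, start_marker = start, end_marker = end)
}

#' @export
print.nf_recording <- function(x, ...) {
  n_reps <- sum(vapply(x$trials, function(tr) length(tr$reps), integer(1)))
  cat(sprintf("<nf_recording> subject %s: %d trials, %d repetitions, %d channels @ %g Hz\n",
              x$subject_id, length(x$trials), n_reps,
              length(x$channel_names), x$sampling_rate))
  invisible(x)
}

#' Write / read a recording as a CSV + JSON directory
#'
#' Persists a recording as one directory: `metadata.json` at the root
#' (subject, sampling rate, channel names) and, per repetition, a CSV of
#' samples (one column per channel, header row = channel names) plus a JSON
#' sidecar holding `speed_label`, `weight_label`, `start_marker` and
#' `end_marker`. The round trip is lossless for markers and labels and
#' preserves samples to full double precision.
#'
#' @param rec An `nf_recording`.
#' @param path Directory to create/write into.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the reconstructed `nf_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nf_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(subject_id = rec$subject_id,
               sampling_rate = rec$sampling_rate,
               channel_names = rec$channel_names,
               n_trials = length(rec$trials))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (t in seq_along(rec$trials)) {
    tr <- rec$trials[[t]]
    for (r in seq_along(tr$reps)) {
      rep <- tr$reps[[r]]
      stem <- sprintf("trial%02d_rep%02d", t, r)
      dt <- data.table::as.data.table(t(rep$samples))
      data.table::setnames(dt, rec$channel_names)
      data.table::fwrite(dt, file.path(path, paste0(stem, ".csv")))
      side <- list(speed_label = tr$speed_label,
                   weight_label = tr$weight_label,
                   start_marker = rep$start_marker,
                   end_marker = rep$end_marker,
                   rep_index = r, trial_index = t)
      jsonlite::write_json(side, file.path(path, paste0(stem, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}

require_keys <- function(x, keys, where) {
  missing <- setdiff(keys, names(x))
  if (length(missing))
    stop(sprintf("%s: missing required metadata key(s): %s",
                 where, paste(missing, collapse = ", ")))
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("metadata.json not found in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  require_keys(meta, c("subject_id", "sampling_rate", "channel_names"),
               "metadata.json")
  sidecars <- sort(list.files(path, pattern = "^trial\\d+_rep\\d+\\.json$"))
  trials <- list()
  for (sc in sidecars) {
    side <- jsonlite::read_json(file.path(path, sc), simplifyVector = TRUE)
    require_keys(side, c("speed_label", "weight_label", "start_marker",
                         "end_marker", "trial_index", "rep_index"), sc)
    dt <- data.table::fread(file.path(path, sub("\\.json$", ".csv", sc)))
    t <- side$trial_index
    if (length(trials) < t || is.null(trials[t][[1]]))
      trials[[t]] <- list(speed_label = side$speed_label,
                          weight_label = as.numeric(side$weight_label),
                          reps = list())
    trials[[t]]$reps[[side$rep_index]] <-
      list(samples = t(as.matrix(dt)),
           start_marker = as.integer(side$start_marker),
           end_marker = as.integer(side$end_marker))
  }
  structure(list(subject_id = meta$subject_id,
                 sampling_rate = as.numeric(meta$sampling_rate),
                 channel_names = meta$channel_names,
                 trials = trials),
            class = "nf_recording")
}
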