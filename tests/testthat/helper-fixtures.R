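# Shared fixtures, generated once per test run and cached.
fixture_env <- new.env()

tiny_spec <- function(seed = 5L, subject = "S01") {
  session_spec(subject_id = subject, slow_duration = 3, fast_duration = 1.5,
               inter_rep_pause = 1, seed = seed)
}

tiny_recording <- function() {
  if (is.null(fixture_env$rec))
    fixture_env$rec <- generate_recording(tiny_spec())
  fixture_env$rec
}

tiny_windows <- function() {
  if (is.null(fixture_env$ws)) {
    rec <- segment_movement(filter_recording(tiny_recording()))
    fixture_env$ws <- make_windows(rec)
  }
  fixture_env$ws
}

# Subset a window set by window indices.
subset_windows <- function(ws, idx) {
  ws$windows <- ws$windows[, , idx, drop = FALSE]
  ws$meta <- ws$meta[idx, , drop = FALSE]
  rownames(ws$meta) <- NULL
  ws
}

# Hand-built recording: one trial, one repetition, given channel matrix.
manual_recording <- function(samples, start = 1L, end = ncol(samples) + 1L,
                             speed = "slow", weight = 0, fs = 4000) {
  structure(list(subject_id = "M01", sampling_rate = fs,
                 channel_names = c("C3", "C4", "Cz", "biceps", "triceps"),
                 trials = list(list(speed_label = speed, weight_label = weight,
                                    reps = list(list(samples = samples,
                                                     start_marker = start,
                                                     end_marker = end))))),
            class = "nf_recording")
}

# Three visually separable 24x24 image classes for training sanity checks:
# a bright patch top-left, a bright patch bottom-right, or background only.
toy_image_data <- function(n = 240, seed = 7) {
  set.seed(seed)
  y <- rep(0:2, length.out = n)
  x <- array(stats::rnorm(24 * 24 * n, sd = 0.1), dim = c(24, 24, n))
  for (i in seq_len(n)) {
    if (y[i] == 0) x[3:8, 3:8, i] <- x[3:8, 3:8, i] + 1
    if (y[i] == 1) x[16:21, 16:21, i] <- x[16:21, 16:21, i] + 1
  }
  n_tr <- round(0.75 * n)
  list(train = list(x = x[, , seq_len(n_tr)], y = y[seq_len(n_tr)]),
       val = list(x = x[, , (n_tr + 1):n], y = y[(n_tr + 1):n]))
}

toy_hp <- function(lr = 1e-3) {
  list(kernels = c(3, 3, 3), filters = c(4, 4, 4), conv_dropout = c(0, 0, 0),
       dense_units = c(16, 16), dense_dropout = c(0, 0), lr = lr)
}

# Naive DFT of one Hann-tapered frame: the independent oracle for the STFT.
brute_frame <- function(x, start, fft_len, n_bins, win_len = 56) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(win_len - 1)) / (win_len - 1)))
  seg <- x[start:(start + win_len - 1)] * w
  vapply(seq_len(n_bins), function(k)
    Mod(sum(seg * exp(-2i * pi * k * (0:(win_len - 1)) / fft_len))),
    numeric(1))
}

# Single-pass Butterworth magnitude response at frequency f (Hz); the
# zero-phase (filtfilt) response is its square.
butter_gain <- function(filt, f, fs) {
  w <- 2 * pi * f / fs
  zb <- exp(-1i * w * (seq_along(filt$b) - 1))
  za <- exp(-1i * w * (seq_along(filt$a) - 1))
  Mod(sum(filt$b * zb) / sum(filt$a * za))
}
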