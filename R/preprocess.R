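#' Software filter specification
#'
#' EEG channels are band-passed 0.5-40 Hz with a 3rd-order Butterworth
#' design; EMG channels have their DC offset removed and are band-passed
#' 20-500 Hz with a 4th-order Butterworth. Filters are applied zero-phase
#' (forward-backward), so the realized magnitude response is the square of
#' the single-pass response and the effective order doubles.
#'
#' @param eeg_band,emg_band Pass bands in Hz, `c(low, high)`.
#' @param eeg_order,emg_order Butterworth orders of the single-pass designs.
#' @param emg_dc_removal Subtract the channel mean from EMG before filtering.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(eeg_band = c(0.5, 40), eeg_order = 3,
                        emg_band = c(20, 500), emg_order = 4,
                        emg_dc_removal = TRUE) {
  for (b in list(eeg_band, emg_band))
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stop("filter bands must satisfy 0 < low < high")
  structure(list(eeg_band = eeg_band, eeg_order = eeg_order,
                 emg_band = emg_band, emg_order = emg_order,
                 emg_dc_removal = isTRUE(emg_dc_removal)),
            class = "filter_spec")
}

#' Apply the software filters to a recording
#'
#' @param rec An `nf_recording`.
#' @param fspec A [filter_spec()].
#' @return The recording with filtered samples; markers and labels unchanged.
#' @export
filter_recording <- function(rec, fspec = filter_spec()) {
  stopifnot(inherits(rec, "nf_recording"))
  fs <- rec$sampling_rate
  if (fspec$eeg_band[2] >= fs / 2 || fspec$emg_band[2] >= fs / 2)
    stop("filter band edge at or above the Nyquist frequency (", fs / 2, " Hz)")
  bf_eeg <- signal::butter(fspec$eeg_order, fspec$eeg_band / (fs / 2), type = "pass")
  bf_emg <- signal::butter(fspec$emg_order, fspec$emg_band / (fs / 2), type = "pass")
  for (t in seq_along(rec$trials)) {
    for (r in seq_along(rec$trials[[t]]$reps)) {
      s <- rec$trials[[t]]$reps[[r]]$samples
      for (ch in eeg_rows())
        s[ch, ] <- signal::filtfilt(bf_eeg, s[ch, ])
      for (ch in emg_rows()) {
        x <- s[ch, ]
        if (fspec$emg_dc_removal) x <- x - mean(x)
        s[ch, ] <- signal::filtfilt(bf_emg, x)
      }
      rec$trials[[t]]$reps[[r]]$samples <- s
    }
  }
  rec
}

#' Truncate repetitions to the marked movement portion
#'
#' Keeps, for every repetition, the half-open sample range
#' `[start_marker, end_marker)` and resets the markers to span the truncated
#' array, discarding the idle signal before and after movement.
#'
#' @param rec An `nf_recording` with markers set.
#' @return The segmented recording.
#' @export
segment_movement <- function(rec) {
  stopifnot(inherits(rec, "nf_recording"))
  for (t in seq_along(rec$trials)) {
    for (r in seq_along(rec$trials[[t]]$reps)) {
      rep <- rec$trials[[t]]$reps[[r]]
      n <- ncol(rep$samples)
      if (rep$start_marker >= rep$end_marker)
        stop(sprintf("inverted markers in trial %d, repetition %d (%d >= %d)",
                     t, r, rep$start_marker, rep$end_marker))
      if (rep$start_marker < 1 || rep$end_marker > n + 1L)
        stop(sprintf("markers out of range in trial %d, repetition %d", t, r))
      rep$samples <- rep$samples[, rep$start_marker:(rep$end_marker - 1L),
                                 drop = FALSE]
      rep$start_marker <- 1L
      rep$end_marker <- ncol(rep$samples) + 1L
      rec$trials[[t]]$reps[[r]] <- rep
    }
  }
  rec
}

#' Sliding-window specification
#'
#' @param length_ms Window length in milliseconds (default 250 ms, i.e.
#'   1,000 samples at 4,000 Hz).
#' @param overlap Fractional overlap between consecutive windows in `[0, 1)`
#'   (default 50%).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_ms = 250, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (length_ms <= 0) stop("window length must be positive")
  structure(list(length_ms = length_ms, overlap = overlap),
            class = "window_spec")
}

window_samples <- function(wspec, fs) {
  len <- round(wspec$length_ms / 1000 * fs)
  step <- round(len * (1 - wspec$overlap))
  list(len = as.integer(len), step = as.integer(step))
}

#' Cut labeled sliding windows from a segmented recording
#'
#' Windows start at samples 1, 1+step, 1+2*step, ... as long as a full
#' window fits, giving `floor((N - len) / step) + 1` windows for a
#' repetition of `N >= len` samples and none otherwise (trailing partial
#' windows are discarded, never padded). Weight classes are encoded by rank
#' of the weight label: lightest weight -> class 0.
#'
#' @param rec A segmented `nf_recording`.
#' @param wspec A [window_spec()].
#' @return An object of class `nf_window_set`: list with `windows` (array
#'   channels x samples x n), `meta` (data.frame with subject_id, trial,
#'   speed_label, weight_label, weight_class, rep_index, window_index),
#'   `channel_names` and `sampling_rate`.
#' @export
make_windows <- function(rec, wspec = window_spec()) {
  stopifnot(inherits(rec, "nf_recording"))
  ws <- window_samples(wspec, rec$sampling_rate)
  weights <- sort(unique(vapply(rec$trials, `[[`, numeric(1), "weight_label")))
  chunks <- list(); meta <- list()
  for (t in seq_along(rec$trials)) {
    tr <- rec$trials[[t]]
    for (r in seq_along(tr$reps)) {
      s <- tr$reps[[r]]$samples
      n <- ncol(s)
      k <- if (n >= ws$len) (n - ws$len) %/% ws$step + 1L else 0L
      if (k == 0L) next
      starts <- 1L + (seq_len(k) - 1L) * ws$step
      arr <- array(0, dim = c(nrow(s), ws$len, k))
      for (i in seq_len(k))
        arr[, , i] <- s[, starts[i]:(starts[i] + ws$len - 1L)]
      chunks[[length(chunks) + 1L]] <- arr
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rec$subject_id, trial = t,
        speed_label = tr$speed_label, weight_label = tr$weight_label,
        weight_class = match(tr$weight_label, weights) - 1L,
        rep_index = r, window_index = seq_len(k),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(chunks))
    windows <- array(0, dim = c(length(rec$channel_names), ws$len, 0))
  else {
    n_tot <- sum(vapply(chunks, function(a) dim(a)[3], integer(1)))
    windows <- array(0, dim = c(dim(chunks[[1]])[1], ws$len, n_tot))
    at <- 0L
    for (a in chunks) {
      k <- dim(a)[3]
      windows[, , at + seq_len(k)] <- a
      at <- at + k
    }
  }
  structure(list(windows = windows,
                 meta = if (length(meta)) do.call(rbind, meta) else
                   data.frame(),
                 channel_names = rec$channel_names,
                 sampling_rate = rec$sampling_rate,
                 window_samples = ws$len, step_samples = ws$step),
            class = "nf_window_set")
}

#' @export
print.nf_window_set <- function(x, ...) {
  cat(sprintf("<nf_window_set> %d windows of %d samples x %d channels @ %g Hz\n",
              dim(x$windows)[3], dim(x$windows)[2], dim(x$windows)[1],
              x$sampling_rate))
  if (nrow(x$meta))
    print(table(weight = x$meta$weight_label, speed = x$meta$speed_label))
  invisible(x)
}
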