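#' STFT specification for spectrogram images
#'
#' A Hann window of 56 samples with 75% overlap (hop 14) gives 68 frames per
#' 1,000-sample window. Frequency resolution differs by modality: the FFT
#' length is 3,200 for EEG and 256 for EMG so that, after band cropping,
#' both modalities yield 32 frequency bins.
#'
#' @param win_len STFT window length in samples.
#' @param overlap Fractional overlap between STFT frames.
#' @param fft_len_eeg,fft_len_emg FFT lengths per modality.
#' @param log_magnitude Use `log1p` of the magnitude instead of the linear
#'   magnitude (default off: plain one-sided `|STFT|`).
#' @return An object of class `stft_spec`.
#' @export
stft_spec <- function(win_len = 56, overlap = 0.75,
                      fft_len_eeg = 3200, fft_len_emg = 256,
                      log_magnitude = FALSE) {
  hop <- win_len * (1 - overlap)
  if (hop != round(hop) || hop < 1)
    stop("win_len * (1 - overlap) must be a positive integer hop")
  if (fft_len_eeg < win_len || fft_len_emg < win_len)
    stop("FFT length must be >= win_len")
  structure(list(win_len = as.integer(win_len), overlap = overlap,
                 hop = as.integer(hop),
                 fft_len_eeg = as.integer(fft_len_eeg),
                 fft_len_emg = as.integer(fft_len_emg),
                 log_magnitude = isTRUE(log_magnitude)),
            class = "stft_spec")
}

#' Frequency-crop specification
#'
#' After the STFT, images keep bins `1 .. floor(f_high / df)` where
#' `df = fs / fft_len` (the DC bin is dropped). At 4,000 Hz this yields 32
#' bins for both the EEG band (df = 1.25 Hz, 40/1.25) and the EMG band
#' (df = 15.625 Hz, 500/15.625). The lower band edges are honoured by the
#' band-pass pre-filtering rather than the crop.
#'
#' @param eeg_band,emg_band Frequency bands of interest in Hz.
#' @return An object of class `crop_spec`.
#' @export
crop_spec <- function(eeg_band = c(0.5, 40), emg_band = c(20, 500)) {
  structure(list(eeg_band = eeg_band, emg_band = emg_band),
            class = "crop_spec")
}

# Hann window, symmetric (0.5 * (1 - cos)).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Compute a cropped STFT magnitude image for one channel window
#'
#' Frames start at sample 1 and advance by the hop with no centering or
#' padding; each frame is Hann-tapered, zero-padded to the modality's FFT
#' length and transformed. Rows are the cropped frequency bins ordered low
#' to high, columns are frames ordered in time, so a 1,000-sample window
#' yields a 32 x 68 matrix (height x width).
#'
#' @param x Numeric vector, one channel of one window (1,000 samples at the
#'   default specs).
#' @param modality `"EEG"` or `"EMG"`; selects FFT length and crop band.
#' @param sspec A [stft_spec()].
#' @param cspec A [crop_spec()].
#' @param fs Sampling rate in Hz.
#' @return Numeric matrix, frequency bins x time frames.
#' @export
spectrogram <- function(x, modality = c("EEG", "EMG"), sspec = stft_spec(),
                        cspec = crop_spec(), fs = 4000) {
  modality <- match.arg(modality)
  n <- length(x)
  if (n < sspec$win_len)
    stop("window shorter than the STFT window length (", sspec$win_len, ")")
  fft_len <- if (modality == "EEG") sspec$fft_len_eeg else sspec$fft_len_emg
  band <- if (modality == "EEG") cspec$eeg_band else cspec$emg_band
  df <- fs / fft_len
  n_bins <- floor(band[2] / df)
  n_frames <- (n - sspec$win_len) %/% sspec$hop + 1L
  starts <- 1L + (seq_len(n_frames) - 1L) * sspec$hop
  idx <- outer(0:(sspec$win_len - 1L), starts, `+`)   # win_len x frames
  frames <- matrix(x[idx], nrow = sspec$win_len) * hann_window(sspec$win_len)
  padded <- matrix(0, nrow = fft_len, ncol = n_frames)
  padded[seq_len(sspec$win_len), ] <- frames
  mag <- Mod(stats::mvfft(padded))[2:(n_bins + 1L), , drop = FALSE]
  if (sspec$log_magnitude) mag <- log1p(mag)
  dimnames(mag) <- NULL
  mag
}

#' Per-subject per-modality min-max normalization
#'
#' `fit_normalization()` records the global minimum and maximum over all
#' supplied values (spectrogram magnitudes, or raw amplitudes for signal
#' images) of one subject and modality; `apply_normalization()` maps values
#' affinely so that the recorded extrema become exactly 0 and 1. A
#' degenerate fit (max equal to min) maps everything to 0.
#'
#' @param x For fitting: numeric vector, matrix or array, or a list of
#'   them, pooled before taking extrema. For applying: the values to
#'   transform.
#' @param modality `"EEG"` or `"EMG"` (bookkeeping, checked on application).
#' @param subject_id Subject the statistics belong to.
#' @return `fit_normalization` returns a `norm_stats` object with fields
#'   `min`, `max`, `modality`, `subject_id`; `apply_normalization` returns
#'   `x` rescaled into `[0, 1]`.
#' @export
fit_normalization <- function(x, modality = c("EEG", "EMG"),
                              subject_id = NA_character_) {
  modality <- match.arg(modality)
  vals <- if (is.list(x)) unlist(lapply(x, as.numeric), use.names = FALSE)
          else as.numeric(x)
  if (!length(vals)) stop("cannot fit normalization on zero values")
  structure(list(min = min(vals), max = max(vals),
                 modality = modality, subject_id = subject_id),
            class = "norm_stats")
}

#' @param stats A `norm_stats` object from [fit_normalization()].
#' @rdname fit_normalization
#' @export
apply_normalization <- function(x, stats, subject_id = NULL) {
  stopifnot(inherits(stats, "norm_stats"))
  if (!is.null(subject_id) && !is.na(stats$subject_id) &&
      !identical(subject_id, stats$subject_id))
    warning(sprintf("normalization stats fitted on subject %s applied to %s",
                    stats$subject_id, subject_id))
  rng <- stats$max - stats$min
  if (rng == 0) return(x * 0)
  (x - stats$min) / rng
}

layout_names <- function() c("grouped", "mixed", "stacked",
                             "eeg_stack", "emg_stack",
                             "eeg_multi", "emg_multi",
                             "signal_full", "signal_eeg", "signal_emg")

layout_row_order <- function(layout) {
  switch(layout,
         grouped = c("C3", "C4", "Cz", "biceps", "triceps"),
         mixed = c("C3", "biceps", "C4", "triceps", "Cz"),
         stacked = c("C3", "C4", "Cz", "biceps", "triceps"),
         eeg_stack = , eeg_multi = c("C3", "C4", "Cz"),
         emg_stack = , emg_multi = c("biceps", "triceps"),
         signal_full = c("C3", "C4", "Cz", "biceps", "triceps"),
         signal_eeg = c("C3", "C4", "Cz"),
         signal_emg = c("biceps", "triceps"),
         stop("unknown layout: ", layout))
}

#' Combine per-channel spectrogram images into a fusion layout
#'
#' Vertical layouts concatenate the channel images top to bottom in the
#' layout's row order (grouped: C3, C4, Cz, biceps, triceps; mixed: C3,
#' biceps, C4, triceps, Cz; plus EEG-only and EMG-only stacks); depth
#' layouts (`stacked`, `eeg_multi`, `emg_multi`) stack the images along a
#' third channel axis. Pixel values are passed through unchanged.
#'
#' @param channel_images Named list of equal-sized bins x frames matrices;
#'   names must cover the layout's channels.
#' @param layout One of `"grouped"`, `"mixed"`, `"stacked"`, `"eeg_stack"`,
#'   `"emg_stack"`, `"eeg_multi"`, `"emg_multi"`.
#' @return For vertical layouts a matrix (height x width); for depth layouts
#'   a 3-d array (height x width x channels). The row/channel order is
#'   attached as attribute `row_order`.
#' @export
assemble_layout <- function(channel_images, layout) {
  order <- layout_row_order(layout)
  if (layout %in% c("signal_full", "signal_eeg", "signal_emg"))
    stop("signal layouts are built with signal_image(), not assemble_layout()")
  missing <- setdiff(order, names(channel_images))
  if (length(missing))
    stop("missing channel image(s) for layout ", layout, ": ",
         paste(missing, collapse = ", "))
  imgs <- lapply(channel_images[order], unname)
  dims <- unname(vapply(imgs, dim, integer(2)))
  if (any(dims != dims[, 1]))
    stop("all channel images must share the same dimensions")
  out <- if (layout %in% c("stacked", "eeg_multi", "emg_multi")) {
    array(unlist(imgs, use.names = FALSE),
          dim = c(dims[1, 1], dims[2, 1], length(imgs)))
  } else {
    unname(do.call(rbind, imgs))
  }
  attr(out, "row_order") <- order
  out
}

#' Build a time-domain signal image from one window
#'
#' Stacks the channel time series of a filtered window vertically into a
#' channels x samples image (5 x 1,000 at the default specs), normalizing
#' EEG rows with the subject's EEG amplitude extrema and EMG rows with the
#' EMG extrema so that the two modalities occupy comparable `[0, 1]` ranges
#' despite their ~100-fold amplitude difference.
#'
#' @param window Channels x samples matrix with rows in the order C3, C4,
#'   Cz, biceps, triceps (or the modality subset for the EEG-/EMG-only
#'   variants).
#' @param stats_eeg,stats_emg `norm_stats` fitted on this subject's raw
#'   amplitudes per modality; either may be omitted when the corresponding
#'   modality is absent from `window`.
#' @param channels Channel names corresponding to the rows of `window`.
#' @return Channels x samples matrix with values in `[0, 1]`.
#' @export
signal_image <- function(window, stats_eeg = NULL, stats_emg = NULL,
                         channels = nf_channels()) {
  stopifnot(is.matrix(window), nrow(window) == length(channels))
  modality <- nf_modality()[match(channels, nf_channels())]
  out <- window
  for (i in seq_along(channels)) {
    stats <- if (modality[i] == "EEG") stats_eeg else stats_emg
    if (is.null(stats))
      stop("normalization stats missing for modality ", modality[i])
    out[i, ] <- apply_normalization(window[i, ], stats)
  }
  rownames(out) <- channels
  out
}

#' Build a CNN-ready image dataset from a window set
#'
#' Computes per-channel spectrograms (for spectrogram layouts) or uses the
#' filtered time series directly (signal layouts), fits the subject's
#' per-modality min/max normalization over the requested scope, and
#' assembles every window into the chosen fusion layout.
#'
#' The default normalization scope `"all"` pools every window of the
#' subject, matching the subject-wise procedure the evaluation protocol is
#' built around; scope `"train"` restricts the fit to a supplied index set
#' (e.g. training windows only) to avoid leaking test statistics, and is
#' provided as an explicitly non-default alternative.
#'
#' @param ws An `nf_window_set`.
#' @param layout One of [layout_names()].
#' @param sspec,cspec STFT and crop specifications (spectrogram layouts).
#' @param norm_scope `"all"` (default) or `"train"`.
#' @param norm_indices Window indices used to fit normalization when
#'   `norm_scope = "train"`.
#' @return An object of class `nf_image_dataset`: list with `layout`,
#'   `images` (array height x width x n, or height x width x channels x n
#'   for depth layouts), `labels` (integer classes 0..2), `meta`,
#'   `row_order`, and the fitted `norm_eeg` / `norm_emg` stats.
#' @export
build_image_dataset <- function(ws, layout, sspec = stft_spec(),
                                cspec = crop_spec(),
                                norm_scope = c("all", "train"),
                                norm_indices = NULL) {
  stopifnot(inherits(ws, "nf_window_set"))
  layout <- match.arg(layout, layout_names())
  norm_scope <- match.arg(norm_scope)
  n <- dim(ws$windows)[3]
  if (n == 0) stop("empty window set")
  fit_idx <- if (norm_scope == "train") {
    if (is.null(norm_indices)) stop("norm_scope = 'train' needs norm_indices")
    sort(unique(norm_indices))
  } else seq_len(n)
  subject <- ws$meta$subject_id[1]
  chans <- layout_row_order(layout)
  ch_idx <- match(chans, ws$channel_names)
  modality <- nf_modality()[match(chans, nf_channels())]

  if (layout %in% c("signal_full", "signal_eeg", "signal_emg")) {
    fit_vals <- function(rows) ws$windows[rows, , fit_idx, drop = FALSE]
    stats_eeg <- if (any(modality == "EEG"))
      fit_normalization(fit_vals(eeg_rows()), "EEG", subject) else NULL
    stats_emg <- if (any(modality == "EMG"))
      fit_normalization(fit_vals(emg_rows()), "EMG", subject) else NULL
    images <- array(0, dim = c(length(chans), dim(ws$windows)[2], n))
    for (i in seq_len(n))
      images[, , i] <- signal_image(
        matrix(ws$windows[ch_idx, , i], nrow = length(chans)),
        stats_eeg, stats_emg, channels = chans)
    norm_eeg <- stats_eeg; norm_emg <- stats_emg
  } else {
    # one spectrogram per channel per window, computed once
    specs <- vector("list", length(chans))
    for (j in seq_along(chans)) {
      specs[[j]] <- lapply(seq_len(n), function(i)
        spectrogram(ws$windows[ch_idx[j], , i], modality[j], sspec, cspec,
                    fs = ws$sampling_rate))
    }
    pool <- function(mod) {
      vals <- unlist(lapply(which(modality == mod), function(j)
        specs[[j]][fit_idx]), use.names = FALSE)
      fit_normalization(vals, mod, subject)
    }
    norm_eeg <- if (any(modality == "EEG")) pool("EEG") else NULL
    norm_emg <- if (any(modality == "EMG")) pool("EMG") else NULL
    norm_of <- function(j)
      if (modality[j] == "EEG") norm_eeg else norm_emg
    one <- function(i) {
      imgs <- stats::setNames(lapply(seq_along(chans), function(j)
        apply_normalization(specs[[j]][[i]], norm_of(j))), chans)
      assemble_layout(imgs, layout)
    }
    first <- one(1)
    images <- array(0, dim = c(dim(first), n))
    nd <- length(dim(first))
    if (nd == 2) images[, , 1] <- first else images[, , , 1] <- first
    for (i in seq_len(n)[-1]) {
      if (nd == 2) images[, , i] <- one(i) else images[, , , i] <- one(i)
    }
  }
  structure(list(layout = layout, images = images,
                 labels = ws$meta$weight_class,
                 meta = ws$meta, row_order = chans,
                 norm_eeg = norm_eeg, norm_emg = norm_emg),
            class = "nf_image_dataset")
}

#' @export
print.nf_image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<nf_image_dataset> layout %s: %d images of %s\n",
              x$layout, d[length(d)],
              paste(d[-length(d)], collapse = " x ")))
  invisible(x)
}
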