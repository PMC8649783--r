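test_that("spectrograms have 68 frames x 32 bins and match a naive DFT", {
  set.seed(3)
  x <- rnorm(1000)
  for (mod in c("EEG", "EMG")) {
    sp <- spectrogram(x, mod)
    expect_identical(dim(sp), c(32L, 68L))
    fft_len <- if (mod == "EEG") 3200 else 256
    for (frame in 1:3) {
      start <- 1 + (frame - 1) * 14
      expect_equal(sp[, frame], brute_frame(x, start, fft_len, 32),
                   tolerance = 1e-10)
    }
  }
  expect_error(spectrogram(rnorm(40), "EEG"), "shorter")
  expect_true(all(spectrogram(numeric(1000), "EMG") == 0))
})

test_that("EMG tones localize to the nearest cropped frequency bin", {
  t <- (0:999) / 4000
  for (f in c(100, 250, 400)) {
    sp <- spectrogram(sin(2 * pi * f * t), "EMG")
    nearest_bin <- round(f / (4000 / 256))
    expect_identical(which.max(rowMeans(sp)), as.integer(nearest_bin),
                     info = paste(f, "Hz"))
  }
  # EEG settings: the 14 ms Hann main lobe spans the whole 0.5-40 Hz band,
  # so a low tone is NOT localizable; implementation and oracle agree on
  # wherever the leakage-dominated peak lands.
  x <- sin(2 * pi * 10 * t)
  sp <- spectrogram(x, "EEG")
  oracle <- brute_frame(x, 1, 3200, 32)
  expect_identical(which.max(sp[, 1]), which.max(oracle))
})

test_that("min-max normalization maps extrema to exactly 0 and 1", {
  st <- fit_normalization(c(2, 4, 10), "EEG", "S01")
  expect_equal(apply_normalization(c(2, 4, 10), st), c(0, 0.25, 1))
  const <- fit_normalization(matrix(5, 2, 2), "EMG")
  expect_true(all(apply_normalization(matrix(5, 2, 2), const) == 0))
  # order independence of the fit
  imgs <- lapply(1:5, function(i) matrix(rnorm(12), 3))
  s1 <- fit_normalization(imgs, "EEG")
  s2 <- fit_normalization(rev(imgs), "EEG")
  expect_identical(s1$min, s2$min)
  expect_identical(s1$max, s2$max)
  expect_warning(apply_normalization(1:3, st, subject_id = "S99"), "S99")
})

test_that("fusion layouts produce the documented shapes", {
  set.seed(4)
  imgs <- setNames(lapply(1:5, function(i) matrix(runif(32 * 68), 32, 68)),
                   c("C3", "C4", "Cz", "biceps", "triceps"))
  expect_identical(dim(assemble_layout(imgs, "grouped")), c(160L, 68L))
  expect_identical(dim(assemble_layout(imgs, "mixed")), c(160L, 68L))
  expect_identical(dim(assemble_layout(imgs[1:3], "eeg_stack")), c(96L, 68L))
  expect_identical(dim(assemble_layout(imgs[4:5], "emg_stack")), c(64L, 68L))
  expect_identical(dim(assemble_layout(imgs, "stacked")), c(32L, 68L, 5L))
  expect_identical(dim(assemble_layout(imgs[1:3], "eeg_multi")), c(32L, 68L, 3L))
  expect_identical(dim(assemble_layout(imgs[4:5], "emg_multi")), c(32L, 68L, 2L))
  expect_error(assemble_layout(imgs[1:3], "grouped"), "missing channel")
})

test_that("mixed equals grouped after the fixed row-block permutation", {
  set.seed(5)
  imgs <- setNames(lapply(1:5, function(i) matrix(runif(32 * 68), 32, 68)),
                   c("C3", "C4", "Cz", "biceps", "triceps"))
  grouped <- assemble_layout(imgs, "grouped")
  mixed <- assemble_layout(imgs, "mixed")
  # grouped blocks: C3, C4, Cz, biceps, triceps; mixed: C3, bi, C4, tri, Cz
  block <- function(m, i) m[(32 * (i - 1) + 1):(32 * i), ]
  perm <- c(1, 4, 2, 5, 3)
  for (i in 1:5) expect_identical(block(mixed, i), block(grouped, perm[i]))
  # equal pixel multisets
  expect_identical(sort(as.vector(mixed)), sort(as.vector(grouped)))
  # stacked depth identity: the 5-vector at (f, t) equals the sources
  stacked <- assemble_layout(imgs, "stacked")
  for (k in 1:5) expect_identical(stacked[, , k], unname(imgs[[k]]))
})

test_that("signal images are channels x samples in [0, 1] per modality", {
  set.seed(6)
  w <- rbind(matrix(rnorm(3 * 1000, sd = 0.01), 3),    # EEG, ~100x smaller
             matrix(rnorm(2 * 1000, sd = 1), 2))       # EMG
  st_eeg <- fit_normalization(w[1:3, ], "EEG")
  st_emg <- fit_normalization(w[4:5, ], "EMG")
  img <- signal_image(w, st_eeg, st_emg)
  expect_identical(dim(img), c(5L, 1000L))
  expect_true(all(img >= 0 & img <= 1))
  # both modalities span comparable ranges after normalization
  expect_gt(diff(range(img[1:3, ])), 0.5)
  expect_gt(diff(range(img[4:5, ])), 0.5)
  # modality subsets
  eeg_only <- signal_image(w[1:3, ], st_eeg, NULL, channels = c("C3", "C4", "Cz"))
  expect_identical(dim(eeg_only), c(3L, 1000L))
  emg_only <- signal_image(w[4:5, ], NULL, st_emg,
                           channels = c("biceps", "triceps"))
  expect_identical(dim(emg_only), c(2L, 1000L))
  expect_error(signal_image(w, NULL, st_emg), "missing")
})

test_that("image datasets honour the per-layout dimension table", {
  ws <- subset_windows(tiny_windows(), c(1:6, 101:106, 201:206))
  dims <- list(grouped = c(160, 68), mixed = c(160, 68),
               eeg_stack = c(96, 68), emg_stack = c(64, 68),
               stacked = c(32, 68, 5), eeg_multi = c(32, 68, 3),
               emg_multi = c(32, 68, 2), signal_full = c(5, 1000),
               signal_eeg = c(3, 1000), signal_emg = c(2, 1000))
  for (layout in names(dims)) {
    ds <- build_image_dataset(ws, layout)
    d <- dim(ds$images)
    expect_identical(d[-length(d)], as.integer(dims[[layout]]),
                     info = layout)
    expect_identical(d[length(d)], 18L, info = layout)
    expect_true(all(ds$images >= 0 & ds$images <= 1), info = layout)
  }
})

test_that("subject-modality extrema hit exactly 0 and 1 across a dataset", {
  ws <- subset_windows(tiny_windows(), seq(1, 300, by = 20))
  ds <- build_image_dataset(ws, "grouped")
  expect_identical(range(ds$images), c(0, 1))
  # grouped/mixed/stacked carry identical pixel multisets per window
  dm <- build_image_dataset(ws, "mixed")
  dstk <- build_image_dataset(ws, "stacked")
  i <- 3
  expect_identical(sort(as.vector(ds$images[, , i])),
                   sort(as.vector(dm$images[, , i])))
  expect_identical(sort(as.vector(ds$images[, , i])),
                   sort(as.vector(dstk$images[, , , i])))
})
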