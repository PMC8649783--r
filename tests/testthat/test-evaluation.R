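# Minimal window-set stub with a chosen meta table.
stub_ws <- function(meta) {
  structure(list(windows = array(0, dim = c(5, 10, nrow(meta))),
                 meta = meta, channel_names = c("C3", "C4", "Cz",
                                                "biceps", "triceps"),
                 sampling_rate = 4000),
            class = "nf_window_set")
}

balanced_meta <- function(per_rep = 10) {
  grid <- expand.grid(rep_index = 1:3, trial = 1:6)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tr <- grid$trial[i]
    data.frame(subject_id = "S01", trial = tr,
               speed_label = if (tr <= 3) "slow" else "fast",
               weight_label = c(0, 3, 5)[(tr - 1) %% 3 + 1],
               weight_class = (tr - 1) %% 3,
               rep_index = grid$rep_index[i],
               window_index = seq_len(per_rep))
  }))
}

test_that("the subject split is stratified, disjoint and seeded", {
  ws <- stub_ws(balanced_meta(per_rep = 5))
  sp <- split_windows(ws, split_spec(seed = 3))
  meta <- ws$meta
  expect_true(all(meta$rep_index[sp$train] %in% 1:2))
  expect_true(all(meta$rep_index[c(sp$val, sp$test)] == 3))
  expect_length(intersect(sp$val, sp$test), 0)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_len(nrow(meta)))
  # 10 holdout windows per class -> 5 + 5
  expect_equal(as.vector(table(meta$weight_class[sp$val])), c(5, 5, 5))
  expect_equal(as.vector(table(meta$weight_class[sp$test])), c(5, 5, 5))
  expect_identical(split_windows(ws, split_spec(seed = 3)), sp)
  expect_false(identical(split_windows(ws, split_spec(seed = 4))$val, sp$val))
})

test_that("odd holdout classes split with a difference of exactly one", {
  meta <- balanced_meta(per_rep = 5)
  # an 11th holdout window for weight_class 0 (trials 1 and 4 carry it)
  extra <- meta[meta$trial == 1 & meta$rep_index == 3 & meta$window_index == 1, ]
  extra$window_index <- 6
  ws <- stub_ws(rbind(meta, extra))
  sp <- split_windows(ws, split_spec(seed = 8))
  n_val <- sum(ws$meta$weight_class[sp$val] == 0)
  n_test <- sum(ws$meta$weight_class[sp$test] == 0)
  expect_identical(n_val + n_test, 11L)
  expect_identical(abs(n_val - n_test), 1L)
})

test_that("a missing repetition is reported with its trial", {
  meta <- balanced_meta(per_rep = 4)
  meta <- meta[!(meta$trial == 4 & meta$rep_index == 3), ]
  expect_error(split_windows(stub_ws(meta)), "trial 4")
})

test_that("evaluation reports match hand-computed confusion arithmetic", {
  # toy matrix [[5,0,0],[0,3,2],[0,2,3]]
  truth <- rep(c(0, 1, 1, 2, 2), times = c(5, 3, 2, 2, 3))
  pred  <- rep(c(0, 1, 2, 1, 2), times = c(5, 3, 2, 2, 3))
  r <- classification_report(truth, pred)
  expect_equal(unname(as.vector(t(r$confusion))),
               c(5, 0, 0, 0, 3, 2, 0, 2, 3))
  expect_equal(r$accuracy, 100 * 11 / 15)
  expect_equal(unname(r$precision[3]), 3 / 5)
  expect_equal(unname(r$recall[3]), 3 / 5)

  perfect <- classification_report(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$precision == 1) && all(perfect$recall == 1))

  # 0/0 precision is 0 with a flag (class 2 never predicted)
  r0 <- classification_report(c(0, 1, 2), c(0, 1, 1))
  expect_equal(unname(r0$precision[3]), 0)
  expect_true(r0$prf_undefined[3])
})

test_that("overall accuracy is the size-weighted mean of per-speed accuracy", {
  set.seed(12)
  n <- 200
  truth <- sample(0:2, n, replace = TRUE)
  pred <- sample(0:2, n, replace = TRUE)
  speed <- sample(c("slow", "fast"), n, replace = TRUE, prob = c(0.8, 0.2))
  r <- classification_report(truth, pred, speed = speed)
  w <- table(speed)[names(r$speed_accuracy)]
  expect_equal(r$accuracy,
               sum(r$speed_accuracy * as.vector(w)) / sum(w))
})

test_that("aggregation uses sample SD and pooled confusion matrices", {
  r1 <- classification_report(c(0, 0, 1, 1, 2), c(0, 0, 1, 1, 2))  # 100%
  r1$accuracy <- 80  # keep the matrix, force the accuracy values
  r2 <- classification_report(c(0, 0, 1, 1, 2), c(0, 0, 1, 1, 2))
  r2$accuracy <- 90
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$mean_accuracy, 85)
  expect_equal(agg$sd_accuracy, sd(c(80, 90)))
  expect_equal(agg$sd_accuracy, 7.0711, tolerance = 1e-4)
  expect_equal(sum(agg$pooled_confusion), r1$n + r2$n)

  solo <- aggregate_reports(list(r1))
  expect_identical(solo$sd_accuracy, 0)
  expect_true(solo$sd_undefined)
})

test_that("pooled and subject-mean F-scores are distinct conventions", {
  # subject A: strong on few windows; subject B: weak on many windows
  ra <- classification_report(rep(0:2, each = 2), rep(0:2, each = 2))
  rb <- classification_report(rep(0:2, each = 20),
                              c(rep(0, 20), rep(0, 20), rep(2, 20)))
  agg <- aggregate_reports(list(ra, rb))
  expect_false(isTRUE(all.equal(agg$pooled_f, agg$mean_macro_f)))
  manual_pooled <- ra$confusion + rb$confusion
  expect_equal(unname(agg$pooled_confusion), unname(manual_pooled))
})

test_that("the repeated-measures ANOVA matches textbook sums of squares", {
  acc <- matrix(c(78, 81, 74, 70, 83, 77,
                  80, 84, 75, 73, 85, 80,
                  71, 76, 68, 66, 75, 72), nrow = 6,
                dimnames = list(NULL, c("grouped", "stacked", "eeg")))
  res <- compare_models(acc)
  n <- nrow(acc); k <- ncol(acc)
  grand <- mean(acc)
  ss_model <- n * sum((colMeans(acc) - grand)^2)
  ss_subj <- k * sum((rowMeans(acc) - grand)^2)
  ss_tot <- sum((acc - grand)^2)
  ss_err <- ss_tot - ss_model - ss_subj
  f_expected <- (ss_model / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  expect_equal(res$F, f_expected, tolerance = 1e-10)
  expect_equal(res$p, stats::pf(f_expected, k - 1, (k - 1) * (n - 1),
                                lower.tail = FALSE), tolerance = 1e-10)
  expect_identical(res$df, c(k - 1, (k - 1) * (n - 1)))
  expect_true(all(res$pairwise_p <= 1, na.rm = TRUE))
})

test_that("degenerate comparison tables are handled explicitly", {
  same <- matrix(rep(c(70, 75, 80, 85), 3), ncol = 3)
  res <- compare_models(same)
  expect_identical(res$F, 0)
  expect_identical(res$p, 1)
  expect_true(all(res$pairwise_p[upper.tri(res$pairwise_p)] == 1))

  # constant offset, zero within-pair variance -> p = 0, flagged
  off <- cbind(a = c(70, 75, 80), b = c(72, 77, 82))
  res2 <- compare_models(off)
  expect_identical(res2$pairwise_p["a", "b"], 0)
  expect_true(res2$degenerate_pairs["a", "b"])

  expect_error(compare_models(matrix(c(1, NA, 2, 3), 2)), "missing cells")
})
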