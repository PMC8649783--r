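#' Subject-specific split specification
#'
#' Repetitions 1 and 2 of every trial form the training set; repetition 3
#' is the holdout, shuffled (seeded) and divided 50/50 into validation and
#' test with stratification by weight class, so per-class counts in the two
#' halves differ by at most one and no window appears twice.
#'
#' @param train_reps Repetition indices assigned to training.
#' @param holdout_rep Repetition index held out for validation/test.
#' @param val_fraction Fraction of the holdout assigned to validation.
#' @param seed Shuffle seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_reps = c(1, 2), holdout_rep = 3,
                       val_fraction = 0.5, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (holdout_rep %in% train_reps)
    stop("holdout repetition cannot also be a training repetition")
  structure(list(train_reps = as.integer(train_reps),
                 holdout_rep = as.integer(holdout_rep),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a window set into train / validation / test indices
#'
#' @param ws An `nf_window_set`.
#' @param sspec A [split_spec()].
#' @return List of integer index vectors `train`, `val`, `test` into the
#'   window set; pairwise disjoint.
#' @export
split_windows <- function(ws, sspec = split_spec()) {
  stopifnot(inherits(ws, "nf_window_set"))
  meta <- ws$meta
  need <- c(sspec$train_reps, sspec$holdout_rep)
  for (t in unique(meta$trial)) {
    have <- unique(meta$rep_index[meta$trial == t])
    missing <- setdiff(need, have)
    if (length(missing))
      stop(sprintf("trial %d is missing repetition(s) %s", t,
                   paste(missing, collapse = ", ")))
  }
  train <- which(meta$rep_index %in% sspec$train_reps)
  holdout <- which(meta$rep_index == sspec$holdout_rep)
  val <- integer(0); test <- integer(0)
  with_local_seed(sspec$seed, function() {
    shuffled <- holdout[sample.int(length(holdout))]
    for (cl in sort(unique(meta$weight_class[shuffled]))) {
      h <- shuffled[meta$weight_class[shuffled] == cl]
      n_val <- floor(length(h) * sspec$val_fraction)
      val <<- c(val, h[seq_len(n_val)])
      test <<- c(test, h[setdiff(seq_along(h), seq_len(n_val))])
    }
  })
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Assemble train/validation data for model fitting
#'
#' @param dataset An `nf_image_dataset`.
#' @param split Index list from [split_windows()].
#' @return List with `train` and `val` components consumable by
#'   [train_model()] and a `test` component for [evaluate_model()].
#' @export
model_data <- function(dataset, split) {
  stopifnot(inherits(dataset, "nf_image_dataset"))
  take <- function(idx) {
    d <- dim(dataset$images)
    x <- if (length(d) == 3) dataset$images[, , idx, drop = FALSE]
         else dataset$images[, , , idx, drop = FALSE]
    list(x = x, y = dataset$labels[idx],
         speed = dataset$meta$speed_label[idx])
  }
  list(train = take(split$train), val = take(split$val),
       test = take(split$test))
}

#' Confusion matrix for a 3-class prediction
#'
#' @param truth,pred Integer class vectors (0-based).
#' @param n_class Number of classes.
#' @return `n_class` x `n_class` matrix, rows = true class, columns =
#'   predicted class.
#' @export
confusion_matrix <- function(truth, pred, n_class = 3L) {
  m <- matrix(0L, n_class, n_class,
              dimnames = list(true = 0:(n_class - 1),
                              predicted = 0:(n_class - 1)))
  for (i in seq_along(truth))
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  m
}

# precision/recall per class from a confusion matrix; 0/0 is reported as 0
# and flagged.
prf_from_confusion <- function(m) {
  diagm <- diag(m)
  col_tot <- colSums(m)
  row_tot <- rowSums(m)
  precision <- ifelse(col_tot > 0, diagm / col_tot, 0)
  recall <- ifelse(row_tot > 0, diagm / row_tot, 0)
  undefined <- col_tot == 0 | row_tot == 0
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  list(precision = precision, recall = recall, f1 = f1,
       undefined = undefined)
}

#' Evaluate a trained model on a test set
#'
#' Predicts by argmax probability (ties broken toward the lowest class
#' index) and reports overall accuracy, accuracy separated by movement
#' speed, the 3x3 confusion matrix, class-wise precision/recall and the
#' macro F-score. All percentage fields are on a 0-100 scale.
#'
#' @param model An `nf_model`.
#' @param test List with `x` (images), `y` (true classes 0-2) and
#'   optionally `speed` (character vector of speed labels).
#' @param subject_id Subject identifier recorded in the report.
#' @return An object of class `nf_eval_report`.
#' @export
evaluate_model <- function(model, test, subject_id = NA_character_) {
  if (!length(test$y)) stop("empty test set")
  probs <- predict_model(model, test$x)
  pred <- max.col(probs, ties.method = "first") - 1L
  classification_report(test$y, pred, speed = test$speed,
                        subject_id = subject_id)
}

#' Build an evaluation report from labels and predictions
#'
#' The same report as [evaluate_model()] computed from explicit label and
#' prediction vectors (useful for baselines such as a chance-level
#' predictor).
#'
#' @param truth,pred Integer class vectors (0-based).
#' @param speed Optional speed labels, for per-speed accuracies.
#' @param subject_id Subject identifier.
#' @return An object of class `nf_eval_report`: confusion matrix, accuracy
#'   (%), per-speed accuracy (%), per-class precision/recall, macro
#'   F-score (%), and the test-set size.
#' @export
classification_report <- function(truth, pred, speed = NULL,
                                  subject_id = NA_character_) {
  stopifnot(length(truth) == length(pred))
  m <- confusion_matrix(truth, pred)
  acc <- 100 * sum(diag(m)) / sum(m)
  prf <- prf_from_confusion(m)
  speed_acc <- NULL
  if (!is.null(speed)) {
    speed_acc <- vapply(sort(unique(speed)), function(s) {
      i <- speed == s
      100 * mean(pred[i] == truth[i])
    }, numeric(1))
  }
  structure(list(subject_id = subject_id,
                 n = length(truth),
                 confusion = m,
                 accuracy = acc,
                 speed_accuracy = speed_acc,
                 precision = prf$precision,
                 recall = prf$recall,
                 f1 = prf$f1,
                 macro_f = 100 * mean(prf$f1),
                 prf_undefined = prf$undefined),
            class = "nf_eval_report")
}

#' @export
print.nf_eval_report <- function(x, ...) {
  cat(sprintf("<nf_eval_report> %s: accuracy %.2f%% (n = %d), macro F %.2f%%\n",
              x$subject_id, x$accuracy, x$n, x$macro_f))
  if (!is.null(x$speed_accuracy))
    cat("  per-speed accuracy:",
        paste(sprintf("%s %.2f%%", names(x$speed_accuracy),
                      x$speed_accuracy), collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Aggregate per-subject evaluation reports
#'
#' Subject accuracies are combined as an unweighted mean with the sample
#' (n-1) standard deviation; confusion matrices are summed element-wise
#' into a pooled matrix from which pooled precision/recall and a pooled
#' F-score are derived (the "combined classification results" convention).
#' The macro F-score averaged over subjects is also reported, since the
#' two conventions differ.
#'
#' @param reports List of `nf_eval_report` objects.
#' @return An object of class `nf_aggregate_report`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  accs <- vapply(reports, `[[`, numeric(1), "accuracy")
  pooled <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  prf <- prf_from_confusion(pooled)
  sd_flag <- length(accs) < 2
  structure(list(n_subjects = length(reports),
                 mean_accuracy = mean(accs),
                 sd_accuracy = if (sd_flag) 0 else stats::sd(accs),
                 sd_undefined = sd_flag,
                 subject_accuracy = accs,
                 pooled_confusion = pooled,
                 pooled_precision = prf$precision,
                 pooled_recall = prf$recall,
                 pooled_f = 100 * mean(prf$f1),
                 mean_macro_f = mean(vapply(reports, `[[`, numeric(1),
                                            "macro_f"))),
            class = "nf_aggregate_report")
}

#' @export
print.nf_aggregate_report <- function(x, ...) {
  cat(sprintf("<nf_aggregate_report> %d subject(s): accuracy %.2f +/- %.2f%%\n",
              x$n_subjects, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Compare models with a one-way within-subjects ANOVA
#'
#' Runs a one-way repeated-measures ANOVA on a subjects-by-models accuracy
#' table (F tested against the model-by-subject interaction stratum),
#' followed by all pairwise paired t-tests with Bonferroni correction
#' (adjusted p capped at 1). A pair with zero within-pair variance but a
#' nonzero mean difference has a degenerate (infinite) t statistic; its p
#' value is reported as 0 and flagged. A table where all models are
#' identical for every subject yields F = 0 and p = 1.
#'
#' @param acc Numeric matrix, rows = subjects, columns = models (complete:
#'   no missing cells).
#' @return List with `F`, `df`, `p`, the `pairwise_p` matrix of
#'   Bonferroni-adjusted p values, a logical `degenerate_pairs` matrix,
#'   and `alpha` (the 0.05 significance threshold used for reporting).
#' @export
compare_models <- function(acc) {
  acc <- as.matrix(acc)
  if (anyNA(acc)) stop("accuracy table has missing cells; no imputation is done")
  n <- nrow(acc); k <- ncol(acc)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 models")
  if (is.null(colnames(acc))) colnames(acc) <- paste0("model", seq_len(k))
  df <- data.frame(acc_value = as.vector(acc),
                   model = factor(rep(colnames(acc), each = n)),
                   subject = factor(rep(seq_len(n), times = k)))
  ss_model <- n * sum((colMeans(acc) - mean(acc))^2)
  if (ss_model < .Machine$double.eps * sum(acc^2 + 1)) {
    Fval <- 0; p <- 1
  } else {
    fit <- stats::aov(acc_value ~ model + Error(subject/model), data = df)
    tab <- summary(fit)[["Error: subject:model"]][[1]]
    Fval <- tab["model", "F value"]
    p <- tab["model", "Pr(>F)"]
    if (!is.finite(Fval)) { Fval <- Inf; p <- 0 }
  }
  n_pairs <- k * (k - 1) / 2
  pw <- matrix(NA_real_, k, k, dimnames = list(colnames(acc), colnames(acc)))
  degen <- matrix(FALSE, k, k, dimnames = dimnames(pw))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- acc[, i] - acc[, j]
      if (stats::sd(d) == 0) {
        praw <- if (mean(d) == 0) 1 else 0
        degen[i, j] <- degen[j, i] <- mean(d) != 0
      } else {
        praw <- stats::t.test(acc[, i], acc[, j], paired = TRUE)$p.value
      }
      pw[i, j] <- pw[j, i] <- min(1, praw * n_pairs)
    }
  }
  list(F = unname(Fval), df = c(k - 1, (k - 1) * (n - 1)), p = unname(p),
       pairwise_p = pw, degenerate_pairs = degen, alpha = 0.05)
}
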