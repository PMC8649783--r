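#' Hyperparameter search space
#'
#' The tunable ranges used by random search: 2D kernel sizes 3x3 or 5x5
#' (7x7 additionally allowed for the third convolution layer only, and all
#' kernels fixed at 3x3 for multi-channel inputs), 1D kernel widths 3-55 in
#' steps of 2, filter counts 8-1,024 in powers of two (capped at 512 for the
#' split-convolution family), dropout 0-0.5 in steps of 0.05, dense units
#' 20-500 in steps of 20, and an Adam learning rate sampled
#' log-uniformly on `[1e-5, 1e-2]`. Every tunable slot (per layer) is drawn
#' independently.
#'
#' @param kernel_sizes,kernel_sizes_l3 Candidate 2D kernel sizes (layers
#'   1-2, and layer 3).
#' @param kernel_widths Candidate 1D kernel widths.
#' @param filters Candidate filter counts.
#' @param dropout Candidate dropout probabilities.
#' @param dense_units Candidate fully-connected layer widths.
#' @param lr_range Learning-rate bounds for log-uniform sampling.
#' @return An object of class `search_space`.
#' @export
search_space <- function(kernel_sizes = c(3, 5),
                         kernel_sizes_l3 = c(3, 5, 7),
                         kernel_widths = seq(3, 55, by = 2),
                         filters = c(8, 16, 32, 64, 128, 256, 512, 1024),
                         dropout = seq(0, 0.5, by = 0.05),
                         dense_units = seq(20, 500, by = 20),
                         lr_range = c(1e-5, 1e-2)) {
  structure(list(kernel_sizes = kernel_sizes,
                 kernel_sizes_l3 = kernel_sizes_l3,
                 kernel_widths = kernel_widths,
                 filters = filters, dropout = dropout,
                 dense_units = dense_units, lr_range = lr_range),
            class = "search_space")
}

#' A reduced search space for quick runs
#'
#' Same structure as [search_space()] with smaller filter counts, narrower
#' dense layers and a learning-rate band centred where small models train
#' reliably; intended for the reduced-protocol runs used in continuous
#' integration and the quick pipeline mode.
#' @export
quick_search_space <- function() {
  search_space(kernel_sizes = c(3, 5), kernel_sizes_l3 = c(3, 5),
               kernel_widths = seq(3, 15, by = 2),
               filters = c(8, 16),
               dropout = seq(0, 0.3, by = 0.05),
               dense_units = seq(20, 100, by = 20),
               lr_range = c(1e-4, 3e-3))
}

#' Fixed training settings
#'
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch limit.
#' @param patience Early-stopping patience on validation loss.
#' @param search_trials Number of random hyperparameter combinations
#'   evaluated by [tune_model()].
#' @param trainings_per_trial Training repeats per combination; the score
#'   of a combination is the minimum validation loss across repeats.
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(batch_size = 32, max_epochs = 50, patience = 5,
                       search_trials = 50, trainings_per_trial = 2,
                       seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, patience >= 1,
            search_trials >= 1, trainings_per_trial >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 search_trials = as.integer(search_trials),
                 trainings_per_trial = as.integer(trainings_per_trial),
                 seed = as.integer(seed)),
            class = "train_spec")
}

cnn_families <- function() c("spectro2d", "split_conv", "conv1d")

#' Propagate tensor shapes through an architecture
#'
#' Applies the valid-padding convolution arithmetic `out = in - k + 1` and
#' the pooling arithmetic `out = floor(in / p)` along the layer chain of a
#' family, returning every intermediate shape and whether the chain stays
#' feasible (all spatial dimensions >= 1 throughout). Infeasible chains are
#' reported, not raised, so the random sampler can resample.
#'
#' @param family One of `"spectro2d"`, `"split_conv"`, `"conv1d"`.
#' @param input_shape `c(height, width, channels)` in model orientation.
#' @param hp Hyperparameter list as produced by [sample_config()].
#' @return List with `stages` (named shapes), `feasible` flag and, when
#'   infeasible, a `reason`.
#' @export
propagate_shapes <- function(family, input_shape, hp) {
  family <- match.arg(family, cnn_families())
  sh <- as.integer(input_shape)
  stages <- list(input = sh)
  fail <- function(reason)
    list(stages = stages, feasible = FALSE, reason = reason)
  conv <- function(kh, kw, f)
    as.integer(c(sh[1] - kh + 1, sh[2] - kw + 1, f))
  pool <- function(ph, pw)
    as.integer(c(sh[1] %/% ph, sh[2] %/% pw, sh[3]))
  push <- function(name, s) {
    stages[[name]] <<- s
    sh <<- s
    all(s >= 1L)
  }
  if (family == "spectro2d") {
    for (l in 1:3) {
      k <- hp$kernels[l]
      if (!push(sprintf("conv%d", l), conv(k, k, hp$filters[l])))
        return(fail(sprintf("conv%d output below 1x1", l)))
      if (!push(sprintf("pool%d", l), pool(2L, 2L)))
        return(fail(sprintf("pool%d output below 1x1", l)))
    }
  } else if (family == "split_conv") {
    if (!push("conv_temporal", conv(1L, hp$kernel_width, hp$filters[1])))
      return(fail("temporal convolution output below width 1"))
    if (!push("conv_spatial", conv(sh[1], 1L, hp$filters[2])))
      return(fail("spatial convolution output below 1x1"))
    if (!push("pool", pool(1L, 2L)))
      return(fail("pool output below width 1"))
  } else {
    for (l in 1:3) {
      if (!push(sprintf("conv%d", l),
                conv(1L, hp$kernel_widths[l], hp$filters[l])))
        return(fail(sprintf("conv%d output below width 1", l)))
      if (!push(sprintf("pool%d", l), pool(1L, 2L)))
        return(fail(sprintf("pool%d output below width 1", l)))
    }
  }
  stages$flatten <- as.integer(prod(sh))
  stages$dense1 <- as.integer(hp$dense_units[1])
  stages$dense2 <- as.integer(hp$dense_units[2])
  stages$output <- 3L
  list(stages = stages, feasible = TRUE)
}

#' Draw one random hyperparameter assignment
#'
#' Samples every tunable slot independently from the space, honouring the
#' family constraints (3x3 kernels forced for multi-channel spectrogram
#' inputs; split-convolution filters capped at 512) and resampling, up to
#' `max_tries` times, any assignment whose shape chain is infeasible for
#' the given input. Deterministic for a fixed RNG state.
#'
#' @param space A [search_space()].
#' @param family Architecture family.
#' @param input_shape `c(height, width, channels)` in model orientation.
#' @param max_tries Resampling budget for infeasible chains.
#' @return Hyperparameter list with per-layer kernels/filters/dropout,
#'   dense units/dropout, and `lr`.
#' @export
sample_config <- function(space, family, input_shape, max_tries = 100L) {
  family <- match.arg(family, cnn_families())
  pick <- function(v, n = 1L) v[sample.int(length(v), n, replace = TRUE)]
  for (try in seq_len(max_tries)) {
    hp <- list()
    if (family == "spectro2d") {
      multi <- input_shape[3] > 1L
      hp$kernels <- if (multi) c(3L, 3L, 3L) else
        c(pick(space$kernel_sizes), pick(space$kernel_sizes),
          pick(space$kernel_sizes_l3))
      hp$filters <- pick(space$filters, 3L)
      hp$conv_dropout <- pick(space$dropout, 3L)
    } else if (family == "split_conv") {
      hp$kernel_width <- pick(space$kernel_widths)
      hp$filters <- pick(space$filters[space$filters <= 512], 2L)
      hp$conv_dropout <- pick(space$dropout, 1L)
    } else {
      hp$kernel_widths <- pick(space$kernel_widths, 3L)
      hp$filters <- pick(space$filters, 3L)
      hp$conv_dropout <- pick(space$dropout, 3L)
    }
    hp$dense_units <- pick(space$dense_units, 2L)
    hp$dense_dropout <- pick(space$dropout, 2L)
    hp$lr <- 10^stats::runif(1, log10(space$lr_range[1]),
                             log10(space$lr_range[2]))
    if (propagate_shapes(family, input_shape, hp)$feasible) return(hp)
  }
  stop("no feasible hyperparameter assignment found after ", max_tries,
       " draws for input ", paste(input_shape, collapse = "x"))
}

# Reorient a dataset's native image array into the model input layout
# c(H, W, C, n): vertically stacked images become single-channel tensors,
# depth layouts pass through, signal images feed split_conv as
# channels x time x 1 and conv1d as 1 x time x channels.
prepare_input <- function(images, layout, family) {
  d <- dim(images)
  if (family == "spectro2d") {
    if (length(d) == 3) array(images, dim = c(d[1], d[2], 1L, d[3]))
    else images
  } else if (family == "split_conv") {
    stopifnot(length(d) == 3)
    array(images, dim = c(d[1], d[2], 1L, d[3]))
  } else {                                      # conv1d
    stopifnot(length(d) == 3)
    out <- array(0, dim = c(1L, d[2], d[1], d[3]))
    out[1, , , ] <- aperm(images, c(2, 1, 3))
    out
  }
}

model_input_shape <- function(images, layout, family) {
  d <- dim(prepare_input(images, layout, family))
  d[1:3]
}

# Slice batch b (indices ib) from a (H, W, C, n) array into the engine's
# (H, W, B, C) activation layout.
batch_tensor <- function(x, ib) {
  d <- dim(x)
  xb <- x[, , , ib, drop = FALSE]
  aperm(xb, c(1, 2, 4, 3))
}

eval_forward <- function(layers, x, y, batch_size = 64L) {
  n <- dim(x)[4]
  loss_sum <- 0; correct <- 0
  probs <- matrix(NA_real_, n, 3)
  for (at in seq.int(1L, n, by = batch_size)) {
    ib <- at:min(at + batch_size - 1L, n)
    out <- nn_forward(layers, batch_tensor(x, ib), train = FALSE)$out
    lg <- xent_loss_grad(out, y[ib])
    loss_sum <- loss_sum + lg$loss * length(ib)
    pred <- max.col(lg$probs, ties.method = "first") - 1L
    correct <- correct + sum(pred == y[ib])
    probs[ib, ] <- lg$probs
  }
  list(loss = loss_sum / n, acc = correct / n, probs = probs)
}

#' Train a CNN on an image dataset split
#'
#' Minimizes categorical cross-entropy with Adam (beta1 0.9, beta2 0.999,
#' epsilon 1e-7) in mini-batches, monitoring validation loss with early
#' stopping: training halts at `max_epochs` or once the validation loss has
#' failed to improve for `patience` consecutive epochs, and the best-epoch
#' weights are restored. All randomness (initialization, shuffling,
#' dropout) derives from `tspec$seed`, so a repeated call reproduces the
#' fitted model exactly.
#'
#' @param data List with `train` and `val`, each `list(x = images, y =
#'   labels)` where `x` is the dataset-native array and `y` an integer
#'   vector of classes 0-2. Build it with [model_data()].
#' @param family Architecture family (`"spectro2d"`, `"split_conv"`,
#'   `"conv1d"`).
#' @param hp Hyperparameters from [sample_config()] or hand-written.
#' @param tspec A [train_spec()].
#' @param layout Layout tag carried along for bookkeeping.
#' @return An object of class `nf_model`: layer chain, hyperparameters,
#'   per-epoch history, best/stopped epoch, and input metadata.
#' @export
train_model <- function(data, family, hp, tspec = train_spec(),
                        layout = NA_character_) {
  family <- match.arg(family, cnn_families())
  if (length(unique(data$train$y)) < 2L)
    stop("training split contains a single class; cannot fit a classifier")
  xin <- prepare_input(data$train$x, layout, family)
  xval <- prepare_input(data$val$x, layout, family)
  input_shape <- dim(xin)[1:3]
  n <- dim(xin)[4]
  with_local_seed(tspec$seed, function() {
    layers <- build_layers(family, input_shape, hp)
    best <- list(loss = Inf, epoch = 0L, weights = NULL)
    wait <- 0L
    history <- NULL
    diverged <- FALSE
    for (epoch in seq_len(tspec$max_epochs)) {
      ord <- sample.int(n)
      tl_sum <- 0; tc <- 0; t_step <- 0L
      for (at in seq.int(1L, n, by = tspec$batch_size)) {
        ib <- ord[at:min(at + tspec$batch_size - 1L, n)]
        fw <- nn_forward(layers, batch_tensor(xin, ib), train = TRUE)
        lg <- xent_loss_grad(fw$out, data$train$y[ib])
        if (!is.finite(lg$loss)) { diverged <- TRUE; break }
        nn_backward(layers, lg$dZ, fw$caches)
        t_step <- epoch_step_counter(layers)
        adam_step(layers, hp$lr, t_step)
        tl_sum <- tl_sum + lg$loss * length(ib)
        pred <- max.col(lg$probs, ties.method = "first") - 1L
        tc <- tc + sum(pred == data$train$y[ib])
      }
      if (diverged) {
        history <- rbind(history, data.frame(
          epoch = epoch, train_loss = Inf, train_acc = NA_real_,
          val_loss = Inf, val_acc = NA_real_))
        break
      }
      ev <- eval_forward(layers, xval, data$val$y,
                         batch_size = tspec$batch_size)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tl_sum / n, train_acc = tc / n,
        val_loss = ev$loss, val_acc = ev$acc))
      if (ev$loss < best$loss) {
        best <- list(loss = ev$loss, epoch = epoch,
                     weights = nn_get_weights(layers))
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tspec$patience) break
      }
    }
    if (!is.null(best$weights)) nn_set_weights(layers, best$weights)
    structure(list(family = family, layout = layout, hp = hp,
                   layers = layers, history = history,
                   best_epoch = best$epoch,
                   best_val_loss = best$loss,
                   stopped_epoch = if (is.null(history)) 0L else
                     max(history$epoch),
                   diverged = diverged,
                   input_shape = input_shape,
                   monitor = "val_loss"),
              class = "nf_model")
  })
}

# Global Adam step counter: one shared counter per model, stored on the
# first parameterized layer.
epoch_step_counter <- function(layers) {
  l1 <- layers[[1]]
  if (is.null(l1$t_step)) l1$t_step <- 0L
  l1$t_step <- l1$t_step + 1L
  l1$t_step
}

#' Predict class probabilities
#'
#' @param model An `nf_model`.
#' @param images Dataset-native image array (same layout the model was
#'   trained on).
#' @return Matrix n x 3 of softmax probabilities (rows sum to 1).
#' @export
predict_model <- function(model, images) {
  x <- prepare_input(images, model$layout, model$family)
  n <- dim(x)[4]
  eval_forward(model$layers, x, rep(0L, n))$probs
}

#' @export
print.nf_model <- function(x, ...) {
  cat(sprintf("<nf_model> %s (%s input %s): best val loss %.4f @ epoch %d/%d\n",
              x$family, x$layout, paste(x$input_shape, collapse = "x"),
              x$best_val_loss, x$best_epoch, x$stopped_epoch))
  invisible(x)
}

#' Random-search hyperparameter tuning
#'
#' Evaluates `tspec$search_trials` random hyperparameter combinations,
#' training each `tspec$trainings_per_trial` times; a combination's score
#' is the minimum validation loss across its repeats and the combination
#' with the lowest score wins. Diverged fits score `Inf`. An explicit
#' `candidates` list can replace random sampling (each candidate is then
#' one trial).
#'
#' @inheritParams train_model
#' @param space A [search_space()].
#' @param candidates Optional list of hyperparameter assignments to
#'   evaluate instead of sampling.
#' @return List with `best_hp`, `best_score`, `best_model` (the fitted
#'   model achieving the best score) and `log`, a data frame with one row
#'   per fit (trial, fit, validation loss/accuracy, epochs, and the
#'   hyperparameters serialized as JSON).
#' @export
tune_model <- function(data, family, space = search_space(),
                       tspec = train_spec(), layout = NA_character_,
                       candidates = NULL) {
  family <- match.arg(family, cnn_families())
  input_shape <- model_input_shape(data$train$x, layout, family)
  n_trials <- if (is.null(candidates)) tspec$search_trials
              else length(candidates)
  log <- NULL
  best <- list(score = Inf, hp = NULL, model = NULL)
  for (trial in seq_len(n_trials)) {
    hp <- if (is.null(candidates)) {
      with_local_seed(tspec$seed + 7919L * trial,
                      function() sample_config(space, family, input_shape))
    } else candidates[[trial]]
    scores <- numeric(tspec$trainings_per_trial)
    models <- vector("list", tspec$trainings_per_trial)
    for (fit in seq_len(tspec$trainings_per_trial)) {
      fit_spec <- tspec
      fit_spec$seed <- tspec$seed + 104729L * trial + fit
      m <- train_model(data, family, hp, fit_spec, layout = layout)
      scores[fit] <- if (m$diverged || !is.finite(m$best_val_loss)) Inf
                     else m$best_val_loss
      models[[fit]] <- m
      log <- rbind(log, data.frame(
        trial = trial, fit = fit,
        val_loss = scores[fit],
        val_acc = if (nrow(m$history) && is.finite(scores[fit]))
          m$history$val_acc[m$history$epoch == m$best_epoch][1] else NA_real_,
        epochs = m$stopped_epoch,
        hyperparameters = as.character(
          jsonlite::toJSON(hp, auto_unbox = TRUE, digits = NA))))
    }
    score <- min(scores)
    if (score < best$score) {
      best <- list(score = score, hp = hp,
                   model = models[[which.min(scores)]])
    }
  }
  if (is.null(best$hp))
    stop("every tuning fit diverged; widen the search space or lower lr")
  list(best_hp = best$hp, best_score = best$score,
       best_model = best$model, log = log)
}
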