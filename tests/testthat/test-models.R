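test_that("shape propagation reproduces the valid-conv/pool arithmetic", {
  hp <- list(kernels = c(3, 3, 3), filters = c(8, 8, 8),
             conv_dropout = c(0, 0, 0), dense_units = c(40, 20),
             dense_dropout = c(0, 0), lr = 1e-3)
  ps <- propagate_shapes("spectro2d", c(160, 68, 1), hp)
  expect_true(ps$feasible)
  expect_identical(ps$stages$conv1[1:2], c(158L, 66L))
  expect_identical(ps$stages$pool1[1:2], c(79L, 33L))
  expect_identical(ps$stages$conv2[1:2], c(77L, 31L))
  expect_identical(ps$stages$pool2[1:2], c(38L, 15L))
  expect_identical(ps$stages$conv3[1:2], c(36L, 13L))
  expect_identical(ps$stages$pool3[1:2], c(18L, 6L))

  hp_s <- list(kernel_width = 11, filters = c(8, 8), conv_dropout = 0,
               dense_units = c(40, 20), dense_dropout = c(0, 0), lr = 1e-3)
  ps <- propagate_shapes("split_conv", c(5, 1000, 1), hp_s)
  expect_true(ps$feasible)
  expect_identical(ps$stages$conv_temporal[1:2], c(5L, 990L))
  expect_identical(ps$stages$conv_spatial[1:2], c(1L, 990L))
  expect_identical(ps$stages$pool[1:2], c(1L, 495L))

  # multi-channel 32x68 input: 7x7 kernels everywhere are infeasible,
  # the fixed 3x3 chain is feasible
  hp7 <- hp; hp7$kernels <- c(7, 7, 7)
  expect_false(propagate_shapes("spectro2d", c(32, 68, 5), hp7)$feasible)
  expect_true(propagate_shapes("spectro2d", c(32, 68, 5), hp)$feasible)
})

test_that("propagated shapes equal the realized model tensor shapes", {
  realized <- get("realized_shapes", asNamespace("neurofuse"))
  build <- get("build_layers", asNamespace("neurofuse"))
  space <- search_space(filters = c(8, 16, 32, 64))
  cases <- list(list(fam = "spectro2d", shape = c(160L, 68L, 1L)),
                list(fam = "spectro2d", shape = c(32L, 68L, 5L)),
                list(fam = "split_conv", shape = c(5L, 1000L, 1L)),
                list(fam = "conv1d", shape = c(1L, 1000L, 5L)))
  set.seed(17)
  for (case in cases) {
    for (i in 1:5) {
      hp <- sample_config(space, case$fam, case$shape)
      ps <- propagate_shapes(case$fam, case$shape, hp)
      layers <- build(case$fam, case$shape, hp)
      got <- realized(layers, case$shape)
      # compare the conv/pool stages and final widths
      conv_pool <- Filter(function(s) s$type %in% c("conv", "pool"), got)
      want <- ps$stages[setdiff(names(ps$stages),
                                c("input", "flatten", "dense1", "dense2",
                                  "output"))]
      expect_length(conv_pool, length(want))
      for (j in seq_along(want)) {
        expect_identical(as.integer(conv_pool[[j]]$shape[c(1, 2)]),
                         want[[j]][c(1, 2)])
        expect_identical(as.integer(conv_pool[[j]]$shape[3]), want[[j]][3])
      }
      expect_identical(got[[length(got)]]$shape, 3L)
    }
  }
})

test_that("random configs respect the search space and constraints", {
  space <- search_space()
  set.seed(23)
  hp1 <- withr::with_seed(99, sample_config(space, "spectro2d", c(160, 68, 1)))
  hp2 <- withr::with_seed(99, sample_config(space, "spectro2d", c(160, 68, 1)))
  expect_identical(hp1, hp2)

  for (i in 1:20) {
    hp <- sample_config(space, "spectro2d", c(160, 68, 1))
    expect_true(all(hp$kernels[1:2] %in% c(3, 5)))
    expect_true(hp$kernels[3] %in% c(3, 5, 7))
    expect_true(all(hp$filters %in% space$filters))
    expect_true(all(hp$dense_units %in% space$dense_units))
    expect_true(all(hp$conv_dropout %in% space$dropout))
    expect_true(propagate_shapes("spectro2d", c(160, 68, 1), hp)$feasible)
  }
  # multi-channel inputs force 3x3 kernels
  for (i in 1:10) {
    hp <- sample_config(space, "spectro2d", c(32, 68, 5))
    expect_identical(hp$kernels, c(3L, 3L, 3L))
  }
  # split convolution caps filters at 512
  for (i in 1:20) {
    hp <- sample_config(space, "split_conv", c(5, 1000, 1))
    expect_true(all(hp$filters <= 512))
    expect_true(hp$kernel_width %in% seq(3, 55, 2))
  }
})

test_that("the Adam learning rate is sampled log-uniformly", {
  space <- search_space()
  set.seed(29)
  lrs <- replicate(4000, sample_config(space, "conv1d", c(1, 1000, 5))$lr)
  expect_true(all(lrs >= 1e-5 & lrs <= 1e-2))
  ks <- suppressWarnings(stats::ks.test(log10(lrs), "punif", -5, -2))
  expect_gt(ks$p.value, 0.01)
})

test_that("backpropagated gradients match central finite differences", {
  build <- get("build_layers", asNamespace("neurofuse"))
  fwd <- get("nn_forward", asNamespace("neurofuse"))
  bwd <- get("nn_backward", asNamespace("neurofuse"))
  loss_grad <- get("xent_loss_grad", asNamespace("neurofuse"))
  set.seed(42)
  hp <- list(kernels = c(3, 3, 3), filters = c(3, 4, 3),
             conv_dropout = c(0, 0, 0), dense_units = c(8, 6),
             dense_dropout = c(0, 0), lr = 1e-3)
  layers <- build("spectro2d", c(24, 24, 2), hp)
  X <- array(rnorm(24 * 24 * 4 * 2), dim = c(24, 24, 4, 2))
  y <- c(0L, 1L, 2L, 1L)
  run <- fwd(layers, X, train = TRUE)
  bwd(layers, loss_grad(run$out, y)$dZ, run$caches)
  eps <- 1e-5
  loss_at <- function() loss_grad(fwd(layers, X, FALSE)$out, y)$loss
  for (l in layers) {
    if (!l$type %in% c("conv", "dense")) next
    for (probe in 1:5) {
      i <- sample(length(l$Wmat), 1)
      w0 <- l$Wmat[i]
      l$Wmat[i] <- w0 + eps; up <- loss_at()
      l$Wmat[i] <- w0 - eps; dn <- loss_at()
      l$Wmat[i] <- w0
      numeric_grad <- (up - dn) / (2 * eps)
      expect_equal(l$dW[i], numeric_grad, tolerance = 1e-5)
    }
  }
})

test_that("training separates a toy three-class image problem", {
  data <- toy_image_data()
  m <- train_model(data, "spectro2d", toy_hp(),
                   train_spec(max_epochs = 30, seed = 3), layout = "grouped")
  expect_s3_class(m, "nf_model")
  expect_gte(utils::tail(m$history$train_acc, 1), 0.95)
  p <- predict_model(m, data$val$x)
  expect_identical(dim(p), c(dim(data$val$x)[3], 3L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  acc <- mean(max.col(p, ties.method = "first") - 1L == data$val$y)
  expect_gte(acc, 0.95)
})

test_that("training is reproducible and rejects single-class splits", {
  data <- toy_image_data(n = 90)
  ts <- train_spec(max_epochs = 3, seed = 11)
  m1 <- train_model(data, "spectro2d", toy_hp(), ts, layout = "grouped")
  m2 <- train_model(data, "spectro2d", toy_hp(), ts, layout = "grouped")
  expect_identical(m1$history, m2$history)
  expect_identical(predict_model(m1, data$val$x),
                   predict_model(m2, data$val$x))

  bad <- data
  bad$train$y <- rep(0L, length(bad$train$y))
  expect_error(train_model(bad, "spectro2d", toy_hp(), ts), "single class")
})

test_that("early stopping halts after patience epochs without improvement", {
  data <- toy_image_data(n = 90)
  # lr = 0: no parameter ever changes, so the validation loss never
  # improves after epoch 1
  m <- train_model(data, "spectro2d", toy_hp(lr = 0),
                   train_spec(max_epochs = 50, patience = 5, seed = 5),
                   layout = "grouped")
  expect_identical(m$best_epoch, 1L)
  expect_identical(m$stopped_epoch, 6L)
})

test_that("random search selects the stable configuration", {
  data <- toy_image_data(n = 120)
  good <- toy_hp(lr = 1e-3)
  degenerate <- toy_hp(lr = 3)        # diverges on this problem
  tuned <- tune_model(data, "spectro2d",
                      tspec = train_spec(max_epochs = 5, search_trials = 2,
                                         trainings_per_trial = 2, seed = 7),
                      layout = "grouped",
                      candidates = list(degenerate, good))
  expect_identical(tuned$best_hp$lr, 1e-3)
  expect_identical(nrow(tuned$log), 4L)   # 2 trials x 2 fits
  expect_true(is.finite(tuned$best_score))
  # repeat aggregation: trial score is the minimum across its fits
  t2 <- tuned$log[tuned$log$trial == 2, "val_loss"]
  expect_identical(tuned$best_score, min(t2))

  again <- tune_model(data, "spectro2d",
                      tspec = train_spec(max_epochs = 5, search_trials = 2,
                                         trainings_per_trial = 2, seed = 7),
                      layout = "grouped",
                      candidates = list(degenerate, good))
  expect_identical(tuned$log$val_loss, again$log$val_loss)
})
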