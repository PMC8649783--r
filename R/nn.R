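# Compact CNN engine: valid-padding convolution as im2col + GEMM and max
# pooling run in compiled code (src/conv_ops.cpp); inverted dropout, dense
# layers, softmax/cross-entropy and Adam live here. Activations travel
# through conv/pool stages as 4-d arrays in (height, width, batch, channel)
# layout so that the im2col GEMM output is already the next stage's input
# without transposition; dense stages use (batch x features) matrices.

# ---- layer constructors ------------------------------------------------

he_uniform <- function(fan_in, n) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

new_conv_layer <- function(kh, kw, c_in, filters, in_shape, need_dx = TRUE) {
  K <- kh * kw * c_in
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$kh <- kh; e$kw <- kw; e$c_in <- c_in; e$filters <- filters
  e$in_shape <- in_shape  # c(H, W, C)
  e$out_shape <- c(in_shape[1] - kh + 1L, in_shape[2] - kw + 1L, filters)
  e$Wmat <- matrix(he_uniform(K, K * filters), nrow = K)
  e$b <- numeric(filters)
  e$need_dx <- need_dx
  e
}

new_pool_layer <- function(ph, pw, in_shape) {
  e <- new.env(parent = emptyenv())
  e$type <- "pool"; e$ph <- ph; e$pw <- pw
  e$in_shape <- in_shape
  e$out_shape <- c(in_shape[1] %/% ph, in_shape[2] %/% pw, in_shape[3])
  e
}

new_dropout_layer <- function(rate, in_shape) {
  e <- new.env(parent = emptyenv())
  e$type <- "dropout"; e$rate <- rate; e$in_shape <- in_shape
  e$out_shape <- in_shape
  e
}

new_flatten_layer <- function(in_shape) {
  e <- new.env(parent = emptyenv())
  e$type <- "flatten"; e$in_shape <- in_shape
  e$out_shape <- prod(in_shape)
  e
}

new_dense_layer <- function(n_in, units, relu = TRUE) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$relu <- relu
  e$in_shape <- n_in; e$out_shape <- units
  e$Wmat <- matrix(he_uniform(n_in, n_in * units), nrow = n_in)
  e$b <- numeric(units)
  e
}

# ---- forward / backward ------------------------------------------------

conv_forward <- function(layer, X, train) {
  d <- dim(X)                      # (H, W, B, C)
  B <- d[3]
  r <- conv_fwd_cpp(X, d[1], d[2], B, d[4], layer$kh, layer$kw,
                    layer$Wmat, layer$b, keep_cols = train)
  os <- layer$out_shape
  A <- r$Y; dim(A) <- c(os[1], os[2], B, os[3])
  cache <- if (train) list(Xcol = r$Xcol, Y = r$Y, B = B, in_dim = d)
           else NULL
  list(out = A, cache = cache)
}

conv_backward <- function(layer, dA, cache) {
  os <- layer$out_shape
  dY <- dA; dim(dY) <- c(os[1] * os[2] * cache$B, os[3])
  d <- cache$in_dim
  r <- conv_bwd_cpp(cache$Y, dY, cache$Xcol, layer$Wmat,
                    d[1], d[2], d[3], d[4], layer$kh, layer$kw,
                    need_dx = layer$need_dx)
  layer$dW <- r$dW
  layer$db <- as.vector(r$db)
  if (!layer$need_dx) return(NULL)
  dX <- r$dx
  dim(dX) <- d
  dX
}

pool_forward <- function(layer, X, train) {
  d <- dim(X)
  r <- pool_fwd_cpp(X, d[1], d[2], d[3], d[4], layer$ph, layer$pw,
                    keep_argmax = train)
  os <- layer$out_shape
  m <- r$out; dim(m) <- c(os[1], os[2], d[3], os[3])
  cache <- if (train) list(argmax = r$argmax, in_dim = d) else NULL
  list(out = m, cache = cache)
}

pool_backward <- function(layer, dA, cache) {
  dX <- numeric(prod(cache$in_dim))
  dX[cache$argmax] <- dA
  dim(dX) <- cache$in_dim
  dX
}

dropout_forward <- function(layer, X, train) {
  if (!train || layer$rate <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - layer$rate
  mask <- (stats::runif(length(X)) < keep) / keep
  dim(mask) <- dim(X)
  list(out = X * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, dA, cache) {
  if (is.null(cache)) dA else dA * cache$mask
}

flatten_forward <- function(layer, X, train) {
  d <- dim(X)                      # (H, W, B, C)
  Xp <- aperm(X, c(1, 2, 4, 3))    # (H, W, C, B)
  dim(Xp) <- c(prod(d[c(1, 2, 4)]), d[3])
  list(out = t(Xp), cache = list(in_dim = d))
}

flatten_backward <- function(layer, dA, cache) {
  d <- cache$in_dim
  dX <- t(dA)
  dim(dX) <- c(d[1], d[2], d[4], d[3])
  aperm(dX, c(1, 2, 4, 3))
}

dense_forward <- function(layer, X, train) {
  Y <- X %*% layer$Wmat
  Y <- Y + rep(layer$b, each = nrow(Y))
  mask <- NULL
  if (layer$relu) {
    mask <- Y > 0
    Y[!mask] <- 0
  }
  list(out = Y, cache = if (train) list(X = X, mask = mask) else NULL)
}

dense_backward <- function(layer, dA, cache) {
  if (layer$relu) dA <- dA * cache$mask
  layer$dW <- crossprod(cache$X, dA)
  layer$db <- colSums(dA)
  tcrossprod(dA, layer$Wmat)
}

# dropout applied to dense activations works on plain matrices too (same
# elementwise code path).

nn_forward <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
                conv = conv_forward(l, X, train),
                pool = pool_forward(l, X, train),
                dropout = dropout_forward(l, X, train),
                flatten = flatten_forward(l, X, train),
                dense = dense_forward(l, X, train))
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

nn_backward <- function(layers, dZ, caches) {
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    dZ <- switch(l$type,
                 conv = conv_backward(l, dZ, caches[[i]]),
                 pool = pool_backward(l, dZ, caches[[i]]),
                 dropout = dropout_backward(l, dZ, caches[[i]]),
                 flatten = flatten_backward(l, dZ, caches[[i]]),
                 dense = dense_backward(l, dZ, caches[[i]]))
    if (is.null(dZ) && i > 1)
      stop("internal: gradient chain broken above layer ", i)
  }
  invisible(NULL)
}

softmax_probs <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and gradient wrt logits; y is 0-based class vector
xent_loss_grad <- function(z, y, n_class = 3L) {
  p <- softmax_probs(z)
  B <- nrow(z)
  picked <- p[cbind(seq_len(B), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- p
  dZ[cbind(seq_len(B), y + 1L)] <- dZ[cbind(seq_len(B), y + 1L)] - 1
  list(loss = loss, dZ = dZ / B, probs = p)
}

# ---- Adam --------------------------------------------------------------

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in layers) {
    if (!l$type %in% c("conv", "dense")) next
    if (is.null(l$mW)) {
      l$mW <- l$Wmat * 0; l$vW <- l$Wmat * 0
      l$mb <- l$b * 0; l$vb <- l$b * 0
    }
    l$mW <- beta1 * l$mW + (1 - beta1) * l$dW
    l$vW <- beta2 * l$vW + (1 - beta2) * l$dW^2
    l$Wmat <- l$Wmat - lr * (l$mW / bc1) / (sqrt(l$vW / bc2) + eps)
    l$mb <- beta1 * l$mb + (1 - beta1) * l$db
    l$vb <- beta2 * l$vb + (1 - beta2) * l$db^2
    l$b <- l$b - lr * (l$mb / bc1) / (sqrt(l$vb / bc2) + eps)
  }
  invisible(NULL)
}

nn_get_weights <- function(layers) {
  lapply(layers, function(l)
    if (l$type %in% c("conv", "dense")) list(W = l$Wmat, b = l$b) else NULL)
}

nn_set_weights <- function(layers, weights) {
  for (i in seq_along(layers)) {
    if (!is.null(weights[[i]])) {
      layers[[i]]$Wmat <- weights[[i]]$W
      layers[[i]]$b <- weights[[i]]$b
    }
  }
  invisible(NULL)
}

# ---- architecture assembly --------------------------------------------

# Build the layer chain for a family from hyperparameters; input_shape is
# c(H, W, C) in model orientation. Weight init draws from the current RNG
# stream.
build_layers <- function(family, input_shape, hp, n_class = 3L) {
  shapes <- propagate_shapes(family, input_shape, hp)
  if (!shapes$feasible)
    stop("infeasible architecture: ", shapes$reason)
  layers <- list()
  sh <- input_shape
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  if (family == "spectro2d") {
    for (l in 1:3) {
      k <- hp$kernels[l]
      add(new_conv_layer(k, k, sh[3], hp$filters[l], sh, need_dx = l > 1))
      sh <- layers[[length(layers)]]$out_shape
      add(new_pool_layer(2L, 2L, sh)); sh <- layers[[length(layers)]]$out_shape
      add(new_dropout_layer(hp$conv_dropout[l], sh))
    }
  } else if (family == "split_conv") {
    add(new_conv_layer(1L, hp$kernel_width, sh[3], hp$filters[1], sh,
                       need_dx = FALSE))
    sh <- layers[[length(layers)]]$out_shape
    add(new_conv_layer(sh[1], 1L, sh[3], hp$filters[2], sh))
    sh <- layers[[length(layers)]]$out_shape
    add(new_pool_layer(1L, 2L, sh)); sh <- layers[[length(layers)]]$out_shape
    add(new_dropout_layer(hp$conv_dropout[1], sh))
  } else if (family == "conv1d") {
    for (l in 1:3) {
      add(new_conv_layer(1L, hp$kernel_widths[l], sh[3], hp$filters[l], sh,
                         need_dx = l > 1))
      sh <- layers[[length(layers)]]$out_shape
      add(new_pool_layer(1L, 2L, sh)); sh <- layers[[length(layers)]]$out_shape
      add(new_dropout_layer(hp$conv_dropout[l], sh))
    }
  } else stop("unknown family: ", family)
  add(new_flatten_layer(sh))
  n_in <- prod(sh)
  for (l in 1:2) {
    add(new_dense_layer(n_in, hp$dense_units[l], relu = TRUE))
    n_in <- hp$dense_units[l]
    dl <- new_dropout_layer(hp$dense_dropout[l], n_in)
    add(dl)
  }
  add(new_dense_layer(n_in, n_class, relu = FALSE))
  layers
}

# Realized per-stage output shapes from a forward pass on a single input;
# used as the independent check against propagate_shapes().
realized_shapes <- function(layers, input_shape) {
  X <- array(0, dim = c(input_shape[1], input_shape[2], 1L, input_shape[3]))
  out <- list()
  for (l in layers) {
    X <- switch(l$type,
                conv = conv_forward(l, X, FALSE)$out,
                pool = pool_forward(l, X, FALSE)$out,
                dropout = X,
                flatten = flatten_forward(l, X, FALSE)$out,
                dense = dense_forward(l, X, FALSE)$out)
    sh <- if (is.matrix(X)) ncol(X) else dim(X)[c(1, 2, 4)]
    out[[length(out) + 1L]] <- list(type = l$type, shape = sh)
  }
  out
}
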