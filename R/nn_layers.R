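# Minimal neural-network engine used by the model zoo.
#
# Batches are numeric arrays of shape (batch, time, channels); after global
# pooling or flattening they become (batch, features) matrices. Layers are
# environments with a common S3 interface:
#   layer_init(layer, shape)        shape inference (no weights), returns the
#                                   output shape; errors name the stage when a
#                                   pooling chain exhausts the time axis
#   layer_materialize(layer)        allocate parameters (uses the current RNG)
#   layer_forward(layer, x, training)
#   layer_backward(layer, dy)       returns dx, accumulates parameter grads
#   layer_params(layer)             character vector of parameter field names
# Convolutions use im2col so the heavy lifting is one BLAS matrix product.

new_layer <- function(class, name, fields = list()) {
  env <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = env)
  env$name <- name
  class(env) <- c(class, "airsig_layer")
  env
}

layer_init <- function(layer, shape) UseMethod("layer_init")
layer_materialize <- function(layer) UseMethod("layer_materialize")
layer_forward <- function(layer, x, training = FALSE) UseMethod("layer_forward")
layer_backward <- function(layer, dy) UseMethod("layer_backward")
layer_params <- function(layer) UseMethod("layer_params")

#' @export
layer_materialize.default <- function(layer) invisible(layer)
#' @export
layer_params.default <- function(layer) character(0)

shape_lc <- function(L, C) list(L = as.integer(L), C = as.integer(C))
is_temporal <- function(shape) !is.null(shape$L)

shape_error <- function(layer, msg) {
  abort_airsig(sprintf("Stage %s: %s", sQuote(layer$name), msg), "airsig_shape_error")
}

glorot_mat <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

## ---- conv1d ----------------------------------------------------------------

layer_conv1d <- function(filters, kernel, stride = 1L, padding = "same",
                         name = "conv1d") {
  new_layer("layer_conv1d", name, list(
    filters = as.integer(filters), kernel = as.integer(kernel),
    stride = as.integer(stride), padding = padding
  ))
}

#' @export
layer_init.layer_conv1d <- function(layer, shape) {
  if (!is_temporal(shape)) shape_error(layer, "expects a (time, channel) input.")
  layer$in_shape <- shape
  if (layer$padding == "same") {
    if (layer$stride != 1L) shape_error(layer, "'same' padding requires stride 1.")
    layer$pad_left <- (layer$kernel - 1L) %/% 2L
    layer$pad_right <- layer$kernel - 1L - layer$pad_left
    L_out <- shape$L
  } else {
    layer$pad_left <- 0L
    layer$pad_right <- 0L
    L_out <- (shape$L - layer$kernel) %/% layer$stride + 1L
  }
  if (L_out < 1L) {
    shape_error(layer, sprintf(
      "kernel %d does not fit a time axis of length %d.", layer$kernel, shape$L
    ))
  }
  layer$out_shape <- shape_lc(L_out, layer$filters)
  layer$out_shape
}

#' @export
layer_materialize.layer_conv1d <- function(layer) {
  nin <- layer$kernel * layer$in_shape$C
  layer$W <- glorot_mat(nin, layer$filters)
  layer$b <- numeric(layer$filters)
  invisible(layer)
}

#' @export
layer_params.layer_conv1d <- function(layer) c("W", "b")

conv_im2col <- function(x, kernel, stride, pad_left, pad_right, L_out) {
  d <- dim(x)
  B <- d[1]; L <- d[2]; C <- d[3]
  if (pad_left + pad_right > 0L) {
    xp <- array(0, c(B, L + pad_left + pad_right, C))
    xp[, pad_left + seq_len(L), ] <- x
    x <- xp
  }
  cols <- array(0, c(B, L_out, kernel * C))
  starts <- (seq_len(L_out) - 1L) * stride
  for (t in seq_len(kernel)) {
    cols[, , ((t - 1L) * C + 1L):(t * C)] <- x[, starts + t, , drop = FALSE]
  }
  dim(cols) <- c(B * L_out, kernel * C)
  cols
}

#' @export
layer_forward.layer_conv1d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  L_out <- layer$out_shape$L
  cols <- conv_im2col(x, layer$kernel, layer$stride, layer$pad_left,
                      layer$pad_right, L_out)
  y <- cols %*% layer$W
  y <- sweep(y, 2L, layer$b, "+")
  layer$cache_cols <- cols
  layer$cache_B <- d[1]
  dim(y) <- c(d[1], L_out, layer$filters)
  y
}

#' @export
layer_backward.layer_conv1d <- function(layer, dy) {
  B <- layer$cache_B
  L_out <- layer$out_shape$L
  C <- layer$in_shape$C
  L <- layer$in_shape$L
  dim(dy) <- c(B * L_out, layer$filters)
  layer$dW <- crossprod(layer$cache_cols, dy)
  layer$db <- colSums(dy)
  dcols <- dy %*% t(layer$W)
  dim(dcols) <- c(B, L_out, layer$kernel * C)
  Lp <- L + layer$pad_left + layer$pad_right
  dxp <- array(0, c(B, Lp, C))
  starts <- (seq_len(L_out) - 1L) * layer$stride
  for (t in seq_len(layer$kernel)) {
    dxp[, starts + t, ] <- dxp[, starts + t, , drop = FALSE] +
      dcols[, , ((t - 1L) * C + 1L):(t * C), drop = FALSE]
  }
  dxp[, layer$pad_left + seq_len(L), , drop = FALSE]
}

## ---- batch normalization ---------------------------------------------------

layer_batchnorm <- function(name = "batchnorm", eps = 1e-5, momentum = 0.9) {
  new_layer("layer_batchnorm", name, list(eps = eps, momentum = momentum))
}

#' @export
layer_init.layer_batchnorm <- function(layer, shape) {
  if (!is_temporal(shape)) shape_error(layer, "expects a (time, channel) input.")
  layer$in_shape <- shape
  layer$out_shape <- shape
  shape
}

#' @export
layer_materialize.layer_batchnorm <- function(layer) {
  C <- layer$in_shape$C
  layer$gamma <- rep(1, C)
  layer$beta <- rep(0, C)
  layer$run_mean <- rep(0, C)
  layer$run_var <- rep(1, C)
  invisible(layer)
}

#' @export
layer_params.layer_batchnorm <- function(layer) c("gamma", "beta")

#' @export
layer_forward.layer_batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(sweep(m, 2L, mu, "-")^2)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(m, 2L, mu, "-"), 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  layer$cache_xhat <- xhat
  layer$cache_inv <- inv
  layer$cache_dims <- d
  dim(y) <- d
  y
}

#' @export
layer_backward.layer_batchnorm <- function(layer, dy) {
  d <- layer$cache_dims
  N <- d[1] * d[2]
  dim(dy) <- c(N, d[3])
  xhat <- layer$cache_xhat
  layer$dgamma <- colSums(dy * xhat)
  layer$dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, layer$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat * N, 2L, s1, "-") - sweep(xhat, 2L, s2, "*")
  dx <- sweep(dx, 2L, layer$cache_inv / N, "*")
  dim(dx) <- d
  dx
}

## ---- instance normalization -------------------------------------------------

layer_instancenorm <- function(name = "instancenorm", eps = 1e-5) {
  new_layer("layer_instancenorm", name, list(eps = eps))
}

#' @export
layer_init.layer_instancenorm <- function(layer, shape) {
  if (!is_temporal(shape)) shape_error(layer, "expects a (time, channel) input.")
  layer$in_shape <- shape
  layer$out_shape <- shape
  shape
}

#' @export
layer_materialize.layer_instancenorm <- function(layer) {
  C <- layer$in_shape$C
  layer$gamma <- rep(1, C)
  layer$beta <- rep(0, C)
  invisible(layer)
}

#' @export
layer_params.layer_instancenorm <- function(layer) c("gamma", "beta")

#' @export
layer_forward.layer_instancenorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  mu <- apply(x, c(1L, 3L), mean)                      # (B, C)
  ctr <- sweep(x, c(1L, 3L), mu, "-")
  v <- apply(ctr^2, c(1L, 3L), mean)
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(ctr, c(1L, 3L), inv, "*")
  y <- sweep(sweep(xhat, 3L, layer$gamma, "*"), 3L, layer$beta, "+")
  layer$cache_xhat <- xhat
  layer$cache_inv <- inv
  layer$cache_dims <- d
  y
}

#' @export
layer_backward.layer_instancenorm <- function(layer, dy) {
  d <- layer$cache_dims
  L <- d[2]
  xhat <- layer$cache_xhat
  layer$dgamma <- apply(dy * xhat, 3L, sum)
  layer$dbeta <- apply(dy, 3L, sum)
  dxhat <- sweep(dy, 3L, layer$gamma, "*")
  s1 <- apply(dxhat, c(1L, 3L), sum)
  s2 <- apply(dxhat * xhat, c(1L, 3L), sum)
  dx <- sweep(dxhat * L, c(1L, 3L), s1, "-") - sweep(xhat, c(1L, 3L), s2, "*")
  sweep(dx, c(1L, 3L), layer$cache_inv / L, "*")
}

## ---- activations -----------------------------------------------------------

layer_relu <- function(name = "relu") new_layer("layer_relu", name)

#' @export
layer_init.layer_relu <- function(layer, shape) {
  layer$in_shape <- shape
  layer$out_shape <- shape
  shape
}

#' @export
layer_forward.layer_relu <- function(layer, x, training = FALSE) {
  layer$cache_mask <- x > 0
  x * layer$cache_mask
}

#' @export
layer_backward.layer_relu <- function(layer, dy) dy * layer$cache_mask

# Parametric ReLU with one learnable slope per channel.
layer_prelu <- function(name = "prelu", init = 0.25) {
  new_layer("layer_prelu", name, list(init = init))
}

#' @export
layer_init.layer_prelu <- function(layer, shape) {
  if (!is_temporal(shape)) shape_error(layer, "expects a (time, channel) input.")
  layer$in_shape <- shape
  layer$out_shape <- shape
  shape
}

#' @export
layer_materialize.layer_prelu <- function(layer) {
  layer$alpha <- rep(layer$init, layer$in_shape$C)
  invisible(layer)
}

#' @export
layer_params.layer_prelu <- function(layer) "alpha"

#' @export
layer_forward.layer_prelu <- function(layer, x, training = FALSE) {
  pos <- x > 0
  layer$cache_x <- x
  layer$cache_pos <- pos
  x * pos + sweep(x * !pos, 3L, layer$alpha, "*")
}

#' @export
layer_backward.layer_prelu <- function(layer, dy) {
  neg <- !layer$cache_pos
  layer$dalpha <- apply(dy * layer$cache_x * neg, 3L, sum)
  dy * layer$cache_pos + sweep(dy * neg, 3L, layer$alpha, "*")
}

## ---- pooling ---------------------------------------------------------------

layer_pool <- function(mode = c("max", "avg"), kernel, stride = kernel,
                       padding = "valid", name = "pool") {
  mode <- match.arg(mode)
  new_layer("layer_pool", name, list(
    mode = mode, kernel = as.integer(kernel), stride = as.integer(stride),
    padding = padding
  ))
}

#' @export
layer_init.layer_pool <- function(layer, shape) {
  if (!is_temporal(shape)) shape_error(layer, "expects a (time, channel) input.")
  layer$in_shape <- shape
  if (layer$padding == "same") {
    if (layer$stride != 1L) shape_error(layer, "'same' pooling requires stride 1.")
    layer$pad_left <- (layer$kernel - 1L) %/% 2L
    layer$pad_right <- layer$kernel - 1L - layer$pad_left
    L_out <- shape$L
  } else {
    layer$pad_left <- 0L
    layer$pad_right <- 0L
    L_out <- (shape$L - layer$kernel) %/% layer$stride + 1L
  }
  if (L_out < 1L) {
    shape_error(layer, sprintf(
      "pooling kernel %d (stride %d) exhausts a time axis of length %d.",
      layer$kernel, layer$stride, shape$L
    ))
  }
  layer$out_shape <- shape_lc(L_out, shape$C)
  layer$out_shape
}

#' @export
layer_forward.layer_pool <- function(layer, x, training = FALSE) {
  d <- dim(x)
  B <- d[1]; C <- d[3]
  L_out <- layer$out_shape$L
  if (layer$pad_left + layer$pad_right > 0L) {
    fill <- if (layer$mode == "max") -Inf else 0
    xp <- array(fill, c(B, d[2] + layer$pad_left + layer$pad_right, C))
    xp[, layer$pad_left + seq_len(d[2]), ] <- x
    x <- xp
  }
  starts <- (seq_len(L_out) - 1L) * layer$stride
  if (layer$mode == "avg") {
    acc <- array(0, c(B, L_out, C))
    for (t in seq_len(layer$kernel)) {
      acc <- acc + x[, starts + t, , drop = FALSE]
    }
    layer$cache_dims <- d
    return(acc / layer$kernel)
  }
  best <- x[, starts + 1L, , drop = FALSE]
  arg <- array(1L, c(B, L_out, C))
  for (t in seq.int(2L, layer$kernel)) {
    slab <- x[, starts + t, , drop = FALSE]
    gt <- slab > best
    best[gt] <- slab[gt]
    arg[gt] <- t
  }
  layer$cache_dims <- d
  layer$cache_arg <- arg
  best
}

#' @export
layer_backward.layer_pool <- function(layer, dy) {
  d <- layer$cache_dims
  B <- d[1]; C <- d[3]
  L_out <- layer$out_shape$L
  Lp <- d[2] + layer$pad_left + layer$pad_right
  dxp <- array(0, c(B, Lp, C))
  starts <- (seq_len(L_out) - 1L) * layer$stride
  if (layer$mode == "avg") {
    share <- dy / layer$kernel
    for (t in seq_len(layer$kernel)) {
      dxp[, starts + t, ] <- dxp[, starts + t, , drop = FALSE] + share
    }
  } else {
    arg <- layer$cache_arg
    for (t in seq_len(layer$kernel)) {
      mask <- arg == t
      contrib <- dy * mask
      dxp[, starts + t, ] <- dxp[, starts + t, , drop = FALSE] + contrib
    }
  }
  dxp[, layer$pad_left + seq_len(d[2]), , drop = FALSE]
}

## ---- global average pooling / flatten / dense / dropout --------------------

layer_gap <- function(name = "gap") new_layer("layer_gap", name)

#' @export
layer_init.layer_gap <- function(layer, shape) {
  if (!is_temporal(shape)) shape_error(layer, "expects a (time, channel) input.")
  layer$in_shape <- shape
  layer$out_shape <- list(F = shape$C)
  layer$out_shape
}

#' @export
layer_forward.layer_gap <- function(layer, x, training = FALSE) {
  layer$cache_dims <- dim(x)
  apply(x, c(1L, 3L), mean)
}

#' @export
layer_backward.layer_gap <- function(layer, dy) {
  d <- layer$cache_dims
  aperm(array(dy / d[2], c(d[1], d[3], d[2])), c(1L, 3L, 2L))
}

layer_flatten <- function(name = "flatten") new_layer("layer_flatten", name)

#' @export
layer_init.layer_flatten <- function(layer, shape) {
  layer$in_shape <- shape
  layer$out_shape <- if (is_temporal(shape)) {
    list(F = shape$L * shape$C)
  } else {
    shape
  }
  layer$out_shape
}

#' @export
layer_forward.layer_flatten <- function(layer, x, training = FALSE) {
  layer$cache_dims <- dim(x)
  dim(x) <- c(dim(x)[1], prod(dim(x)[-1]))
  x
}

#' @export
layer_backward.layer_flatten <- function(layer, dy) {
  dim(dy) <- layer$cache_dims
  dy
}

layer_dense <- function(units, name = "dense") {
  new_layer("layer_dense", name, list(units = as.integer(units)))
}

#' @export
layer_init.layer_dense <- function(layer, shape) {
  if (is_temporal(shape)) shape_error(layer, "expects a flat feature input.")
  layer$in_shape <- shape
  layer$out_shape <- list(F = layer$units)
  layer$out_shape
}

#' @export
layer_materialize.layer_dense <- function(layer) {
  layer$W <- glorot_mat(layer$in_shape$F, layer$units)
  layer$b <- numeric(layer$units)
  invisible(layer)
}

#' @export
layer_params.layer_dense <- function(layer) c("W", "b")

#' @export
layer_forward.layer_dense <- function(layer, x, training = FALSE) {
  layer$cache_x <- x
  sweep(x %*% layer$W, 2L, layer$b, "+")
}

#' @export
layer_backward.layer_dense <- function(layer, dy) {
  layer$dW <- crossprod(layer$cache_x, dy)
  layer$db <- colSums(dy)
  dy %*% t(layer$W)
}

layer_dropout <- function(rate, name = "dropout") {
  new_layer("layer_dropout", name, list(rate = rate))
}

#' @export
layer_init.layer_dropout <- function(layer, shape) {
  layer$in_shape <- shape
  layer$out_shape <- shape
  shape
}

#' @export
layer_forward.layer_dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$rate <= 0) {
    layer$cache_mask <- NULL
    return(x)
  }
  keep <- 1 - layer$rate
  mask <- array(rbinom(length(x), 1L, keep) / keep, dim(x))
  layer$cache_mask <- mask
  x * mask
}

#' @export
layer_backward.layer_dropout <- function(layer, dy) {
  if (is.null(layer$cache_mask)) dy else dy * layer$cache_mask
}

## ---- attention pooling (Encoder head) --------------------------------------

# Splits the channels in half, softmaxes the second half over time, and
# contracts the first half against those attention weights (a dot product
# along time), yielding one pooled feature per retained channel.
layer_split_attention <- function(name = "split_attention") {
  new_layer("layer_split_attention", name)
}

#' @export
layer_init.layer_split_attention <- function(layer, shape) {
  if (!is_temporal(shape)) shape_error(layer, "expects a (time, channel) input.")
  if (shape$C %% 2L != 0L) {
    shape_error(layer, sprintf("needs an even channel count, got %d.", shape$C))
  }
  layer$in_shape <- shape
  layer$half <- shape$C %/% 2L
  layer$out_shape <- list(F = layer$half)
  layer$out_shape
}

#' @export
layer_forward.layer_split_attention <- function(layer, x, training = FALSE) {
  h <- layer$half
  A <- x[, , seq_len(h), drop = FALSE]
  G <- x[, , h + seq_len(h), drop = FALSE]
  Gs <- sweep(G, c(1L, 3L), apply(G, c(1L, 3L), max), "-")
  E <- exp(Gs)
  W <- sweep(E, c(1L, 3L), apply(E, c(1L, 3L), sum), "/")
  y <- apply(A * W, c(1L, 3L), sum)
  layer$cache_A <- A
  layer$cache_W <- W
  layer$cache_y <- y
  y
}

#' @export
layer_backward.layer_split_attention <- function(layer, dy) {
  A <- layer$cache_A
  W <- layer$cache_W
  y <- layer$cache_y
  d <- dim(A)
  dA <- sweep(W, c(1L, 3L), dy, "*")
  dG <- sweep(W * sweep(A, c(1L, 3L), y, "-"), c(1L, 3L), dy, "*")
  dx <- array(0, c(d[1], d[2], 2L * d[3]))
  dx[, , seq_len(d[3])] <- dA
  dx[, , d[3] + seq_len(d[3])] <- dG
  dx
}
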