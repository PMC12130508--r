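# Containers composing leaf layers into the seven architectures.

## ---- sequential ------------------------------------------------------------

nn_sequential <- function(layers, name = "sequential") {
  new_layer("nn_sequential", name, list(layers = layers))
}

#' @export
layer_init.nn_sequential <- function(layer, shape) {
  for (l in layer$layers) shape <- layer_init(l, shape)
  layer$out_shape <- shape
  shape
}

#' @export
layer_materialize.nn_sequential <- function(layer) {
  for (l in layer$layers) layer_materialize(l)
  invisible(layer)
}

#' @export
layer_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- layer_forward(l, x, training)
  x
}

#' @export
layer_backward.nn_sequential <- function(layer, dy) {
  for (l in rev(layer$layers)) dy <- layer_backward(l, dy)
  dy
}

## ---- residual block: relu(body(x) + shortcut(x)) ---------------------------

nn_residual <- function(body, shortcut, name = "residual") {
  new_layer("nn_residual", name, list(body = body, shortcut = shortcut))
}

#' @export
layer_init.nn_residual <- function(layer, shape) {
  s1 <- layer_init(layer$body, shape)
  s2 <- layer_init(layer$shortcut, shape)
  if (!identical(s1, s2)) {
    shape_error(layer, "body and shortcut output shapes differ.")
  }
  layer$out_shape <- s1
  s1
}

#' @export
layer_materialize.nn_residual <- function(layer) {
  layer_materialize(layer$body)
  layer_materialize(layer$shortcut)
  invisible(layer)
}

#' @export
layer_forward.nn_residual <- function(layer, x, training = FALSE) {
  s <- layer_forward(layer$body, x, training) +
    layer_forward(layer$shortcut, x, training)
  layer$cache_mask <- s > 0
  s * layer$cache_mask
}

#' @export
layer_backward.nn_residual <- function(layer, dy) {
  ds <- dy * layer$cache_mask
  layer_backward(layer$body, ds) + layer_backward(layer$shortcut, ds)
}

## ---- channel concat of parallel branches over the same input ---------------

nn_concat <- function(branches, name = "concat") {
  new_layer("nn_concat", name, list(branches = branches))
}

#' @export
layer_init.nn_concat <- function(layer, shape) {
  outs <- lapply(layer$branches, layer_init, shape = shape)
  Ls <- vapply(outs, function(s) s$L, integer(1))
  if (length(unique(Ls)) != 1L) {
    shape_error(layer, "branches disagree on output length.")
  }
  layer$branch_channels <- vapply(outs, function(s) s$C, integer(1))
  layer$out_shape <- shape_lc(Ls[1], sum(layer$branch_channels))
  layer$out_shape
}

#' @export
layer_materialize.nn_concat <- function(layer) {
  for (b in layer$branches) layer_materialize(b)
  invisible(layer)
}

#' @export
layer_forward.nn_concat <- function(layer, x, training = FALSE) {
  outs <- lapply(layer$branches, layer_forward, x = x, training = training)
  B <- dim(outs[[1]])[1]
  L <- dim(outs[[1]])[2]
  y <- array(0, c(B, L, sum(layer$branch_channels)))
  at <- 0L
  for (o in outs) {
    C <- dim(o)[3]
    y[, , at + seq_len(C)] <- o
    at <- at + C
  }
  y
}

#' @export
layer_backward.nn_concat <- function(layer, dy) {
  at <- 0L
  dx <- NULL
  for (b in seq_along(layer$branches)) {
    C <- layer$branch_channels[b]
    slice <- dy[, , at + seq_len(C), drop = FALSE]
    at <- at + C
    g <- layer_backward(layer$branches[[b]], slice)
    dx <- if (is.null(dx)) g else dx + g
  }
  dx
}

## ---- per-channel branch split (MC-DCNN) ------------------------------------

# Branch i sees only input channel i; flattened branch outputs are
# concatenated along the feature axis.
nn_channel_branches <- function(branches, name = "channel_branches") {
  new_layer("nn_channel_branches", name, list(branches = branches))
}

#' @export
layer_init.nn_channel_branches <- function(layer, shape) {
  if (length(layer$branches) != shape$C) {
    shape_error(layer, sprintf(
      "%d branches but %d input channels.", length(layer$branches), shape$C
    ))
  }
  outs <- lapply(layer$branches, layer_init, shape = shape_lc(shape$L, 1L))
  layer$branch_features <- vapply(outs, function(s) s$F, integer(1))
  layer$in_shape <- shape
  layer$out_shape <- list(F = sum(layer$branch_features))
  layer$out_shape
}

#' @export
layer_materialize.nn_channel_branches <- function(layer) {
  for (b in layer$branches) layer_materialize(b)
  invisible(layer)
}

#' @export
layer_forward.nn_channel_branches <- function(layer, x, training = FALSE) {
  outs <- lapply(seq_along(layer$branches), function(i) {
    layer_forward(layer$branches[[i]], x[, , i, drop = FALSE], training)
  })
  do.call(cbind, outs)
}

#' @export
layer_backward.nn_channel_branches <- function(layer, dy) {
  B <- nrow(dy)
  dx <- array(0, c(B, layer$in_shape$L, layer$in_shape$C))
  at <- 0L
  for (i in seq_along(layer$branches)) {
    f <- layer$branch_features[i]
    g <- layer_backward(layer$branches[[i]], dy[, at + seq_len(f), drop = FALSE])
    at <- at + f
    dx[, , i] <- g[, , 1L]
  }
  dx
}

## ---- walking the graph -----------------------------------------------------

collect_layers <- function(layer) {
  kids <- list()
  if (inherits(layer, "nn_sequential")) kids <- layer$layers
  if (inherits(layer, "nn_residual")) kids <- list(layer$body, layer$shortcut)
  if (inherits(layer, c("nn_concat", "nn_channel_branches"))) kids <- layer$branches
  if (length(kids) == 0L) return(list(layer))
  out <- list()
  for (k in kids) out <- c(out, collect_layers(k))
  out
}
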