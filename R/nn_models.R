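# Specifications and builders for the seven time-series classifiers.

ARCHITECTURES <- c("fcn", "mlp", "resnet", "encoder", "mcdcnn", "timecnn",
                   "inceptiontime")

#' Specification of a time-series classifier
#'
#' Captures the architecture, the input geometry and the architecture
#' parameters. Defaults follow the reference layer descriptions: FCN with
#' kernels (8, 5, 3) and filters (128, 256, 128); MLP with three 732-unit
#' hidden layers on the flattened input; Time-CNN with two kernel-7 stages of
#' 6 and 12 filters, each followed by average pooling (kernel 3, stride 3);
#' MC-DCNN with a per-channel branch of two kernel-5, 8-filter convolutions
#' each followed by max pooling (2, 2), concatenated into a 732-unit hidden
#' layer; Encoder with kernels (5, 11, 21), filters (128, 256, 512), PReLU,
#' instance normalization, max pooling (2, 2) after the first two stages,
#' dropout and a split-softmax attention head; ResNet with three residual
#' blocks of three convolutions (kernels 8, 5, 3), filters doubling
#' 64 -> 128 -> 256; InceptionTime with two blocks of three inception modules
#' (bottleneck 1x1, parallel kernels (3, 5, 8, 11, 17) plus a max-pool
#' branch) and residual connections input -> block 1 and block 1 -> block 2.
#'
#' @param architecture One of `"fcn"`, `"mlp"`, `"resnet"`, `"encoder"`,
#'   `"mcdcnn"`, `"timecnn"`, `"inceptiontime"`.
#' @param input_length Standardized record length fed to the model.
#' @param n_channels Number of channels (1..9).
#' @param n_classes Number of subjects (>= 2).
#' @param ... Architecture parameter overrides: `filters`, `kernels`,
#'   `hidden`, `dropout`, `bottleneck`, `modules_per_block`, `n_blocks`,
#'   `pool_kernel` — see the per-architecture defaults above. Smaller filter
#'   counts give the scaled-down profiles used for desk experiments.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture, input_length, n_channels, n_classes, ...) {
  architecture <- match.arg(tolower(architecture), ARCHITECTURES)
  input_length <- check_count(input_length, "input_length", min = 2L)
  n_channels <- check_count(n_channels, "n_channels")
  if (n_channels > 9L) {
    abort_airsig("`n_channels` must be in 1..9.", "airsig_config_error")
  }
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  defaults <- switch(architecture,
    fcn = list(filters = c(128L, 256L, 128L), kernels = c(8L, 5L, 3L)),
    mlp = list(hidden = c(732L, 732L, 732L)),
    resnet = list(filters = c(64L, 128L, 256L), kernels = c(8L, 5L, 3L)),
    encoder = list(filters = c(128L, 256L, 512L), kernels = c(5L, 11L, 21L),
                   dropout = 0.2),
    mcdcnn = list(filters = c(8L, 8L), kernels = c(5L, 5L), hidden = 732L),
    timecnn = list(filters = c(6L, 12L), kernels = c(7L, 7L), pool_kernel = 3L),
    inceptiontime = list(n_blocks = 2L, modules_per_block = 3L,
                         bottleneck = 32L, filters = 32L,
                         kernels = c(3L, 5L, 8L, 11L, 17L))
  )
  params <- modifyList(defaults, list(...))
  structure(
    c(list(architecture = architecture, input_length = input_length,
           n_channels = n_channels, n_classes = n_classes), params),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: L=%d, C=%d, K=%d classes\n",
              x$architecture, x$input_length, x$n_channels, x$n_classes))
  invisible(x)
}

conv_bn_relu <- function(filters, kernel, stage) {
  list(
    layer_conv1d(filters, kernel, name = paste0(stage, "_conv")),
    layer_batchnorm(name = paste0(stage, "_bn")),
    layer_relu(name = paste0(stage, "_relu"))
  )
}

build_fcn <- function(spec) {
  layers <- c(
    conv_bn_relu(spec$filters[1], spec$kernels[1], "stage1"),
    conv_bn_relu(spec$filters[2], spec$kernels[2], "stage2"),
    conv_bn_relu(spec$filters[3], spec$kernels[3], "stage3")
  )
  list(backbone = nn_sequential(layers, "fcn_backbone"), gap = TRUE)
}

build_mlp <- function(spec) {
  layers <- list(layer_flatten("flatten"))
  for (i in seq_along(spec$hidden)) {
    layers <- c(layers, list(
      layer_dense(spec$hidden[i], name = sprintf("hidden%d", i)),
      layer_relu(name = sprintf("hidden%d_relu", i))
    ))
  }
  list(backbone = nn_sequential(layers, "mlp_backbone"), gap = FALSE)
}

build_resnet <- function(spec) {
  blocks <- lapply(seq_along(spec$filters), function(b) {
    f <- spec$filters[b]
    body <- nn_sequential(list(
      layer_conv1d(f, spec$kernels[1], name = sprintf("block%d_conv1", b)),
      layer_batchnorm(name = sprintf("block%d_bn1", b)),
      layer_relu(name = sprintf("block%d_relu1", b)),
      layer_conv1d(f, spec$kernels[2], name = sprintf("block%d_conv2", b)),
      layer_batchnorm(name = sprintf("block%d_bn2", b)),
      layer_relu(name = sprintf("block%d_relu2", b)),
      layer_conv1d(f, spec$kernels[3], name = sprintf("block%d_conv3", b)),
      layer_batchnorm(name = sprintf("block%d_bn3", b))
    ), sprintf("block%d_body", b))
    shortcut <- nn_sequential(list(
      layer_conv1d(f, 1L, name = sprintf("block%d_shortcut_conv", b)),
      layer_batchnorm(name = sprintf("block%d_shortcut_bn", b))
    ), sprintf("block%d_shortcut", b))
    nn_residual(body, shortcut, sprintf("block%d", b))
  })
  list(backbone = nn_sequential(blocks, "resnet_backbone"), gap = TRUE)
}

build_encoder <- function(spec) {
  layers <- list()
  for (i in seq_along(spec$filters)) {
    stage <- sprintf("stage%d", i)
    layers <- c(layers, list(
      layer_conv1d(spec$filters[i], spec$kernels[i], padding = "valid",
                   name = paste0(stage, "_conv")),
      layer_instancenorm(name = paste0(stage, "_inorm")),
      layer_prelu(name = paste0(stage, "_prelu")),
      layer_dropout(spec$dropout, name = paste0(stage, "_dropout"))
    ))
    if (i < length(spec$filters)) {
      layers <- c(layers, list(
        layer_pool("max", 2L, 2L, name = paste0(stage, "_maxpool"))
      ))
    }
  }
  layers <- c(layers, list(layer_split_attention("attention")))
  list(backbone = nn_sequential(layers, "encoder_backbone"), gap = FALSE)
}

build_mcdcnn <- function(spec) {
  make_branch <- function(i) {
    nn_sequential(list(
      layer_conv1d(spec$filters[1], spec$kernels[1],
                   name = sprintf("branch%d_conv1", i)),
      layer_relu(name = sprintf("branch%d_relu1", i)),
      layer_pool("max", 2L, 2L, name = sprintf("branch%d_pool1", i)),
      layer_conv1d(spec$filters[2], spec$kernels[2],
                   name = sprintf("branch%d_conv2", i)),
      layer_relu(name = sprintf("branch%d_relu2", i)),
      layer_pool("max", 2L, 2L, name = sprintf("branch%d_pool2", i)),
      layer_flatten(name = sprintf("branch%d_flatten", i))
    ), sprintf("branch%d", i))
  }
  branches <- lapply(seq_len(spec$n_channels), make_branch)
  layers <- list(
    nn_channel_branches(branches, "channel_branches"),
    layer_dense(spec$hidden, name = "hidden"),
    layer_relu(name = "hidden_relu")
  )
  list(backbone = nn_sequential(layers, "mcdcnn_backbone"), gap = FALSE)
}

build_timecnn <- function(spec) {
  layers <- list(
    layer_conv1d(spec$filters[1], spec$kernels[1], name = "stage1_conv"),
    layer_relu(name = "stage1_relu"),
    layer_pool("avg", spec$pool_kernel, spec$pool_kernel, name = "stage1_avgpool"),
    layer_conv1d(spec$filters[2], spec$kernels[2], name = "stage2_conv"),
    layer_relu(name = "stage2_relu"),
    layer_pool("avg", spec$pool_kernel, spec$pool_kernel, name = "stage2_avgpool"),
    layer_flatten("flatten")
  )
  list(backbone = nn_sequential(layers, "timecnn_backbone"), gap = FALSE)
}

inception_module <- function(spec, tag) {
  conv_branches <- lapply(seq_along(spec$kernels), function(k) {
    nn_sequential(list(
      layer_conv1d(spec$bottleneck, 1L, name = sprintf("%s_bottleneck%d", tag, k)),
      layer_conv1d(spec$filters, spec$kernels[k],
                   name = sprintf("%s_conv_k%d", tag, spec$kernels[k]))
    ), sprintf("%s_branch%d", tag, k))
  })
  pool_branch <- nn_sequential(list(
    layer_pool("max", 3L, 1L, padding = "same", name = sprintf("%s_poolbranch", tag)),
    layer_conv1d(spec$filters, 1L, name = sprintf("%s_pool_conv", tag))
  ), sprintf("%s_poolbranch_seq", tag))
  nn_sequential(list(
    nn_concat(c(conv_branches, list(pool_branch)), sprintf("%s_concat", tag)),
    layer_batchnorm(name = sprintf("%s_bn", tag)),
    layer_relu(name = sprintf("%s_relu", tag))
  ), tag)
}

build_inceptiontime <- function(spec) {
  blocks <- lapply(seq_len(spec$n_blocks), function(b) {
    modules <- lapply(seq_len(spec$modules_per_block), function(m) {
      inception_module(spec, sprintf("block%d_module%d", b, m))
    })
    body <- nn_sequential(modules, sprintf("block%d_body", b))
    shortcut <- nn_sequential(list(
      layer_conv1d(spec$filters * (length(spec$kernels) + 1L), 1L,
                   name = sprintf("block%d_shortcut_conv", b)),
      layer_batchnorm(name = sprintf("block%d_shortcut_bn", b))
    ), sprintf("block%d_shortcut", b))
    nn_residual(body, shortcut, sprintf("block%d", b))
  })
  list(backbone = nn_sequential(blocks, "inception_backbone"), gap = TRUE)
}

#' Build an untrained classifier from a specification
#'
#' The model accepts batches of shape `(batch, input_length, n_channels)` and
#' outputs class-probability vectors summing to 1. Architectures ending in
#' global average pooling followed by the linear softmax head (FCN, ResNet,
#' InceptionTime) support class activation maps.
#'
#' @param spec A [model_spec()].
#' @param seed Seed for the (deterministic) weight initialization; training
#'   re-initializes under its own seed.
#' @return An object of class `airsig_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  built <- switch(spec$architecture,
    fcn = build_fcn(spec),
    mlp = build_mlp(spec),
    resnet = build_resnet(spec),
    encoder = build_encoder(spec),
    mcdcnn = build_mcdcnn(spec),
    timecnn = build_timecnn(spec),
    inceptiontime = build_inceptiontime(spec)
  )
  backbone <- built$backbone
  head <- list()
  if (built$gap) head <- c(head, list(layer_gap("gap")))
  head <- c(head, list(layer_dense(spec$n_classes, name = "head_dense")))
  head <- nn_sequential(head, "head")
  shape <- shape_lc(spec$input_length, spec$n_channels)
  shape <- layer_init(backbone, shape)
  layer_init(head, shape)
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$backbone <- backbone
  model$head <- head
  model$gap_head <- built$gap
  model$trained <- FALSE
  model$norm <- NULL
  class(model) <- "airsig_model"
  with_seed(check_count(seed, "seed", min = 0L), materialize_model(model))
  model
}

materialize_model <- function(model) {
  layer_materialize(model$backbone)
  layer_materialize(model$head)
  invisible(model)
}

model_forward <- function(model, x, training = FALSE) {
  feats <- layer_forward(model$backbone, x, training)
  layer_forward(model$head, feats, training)
}

model_backward <- function(model, dy) {
  dfeats <- layer_backward(model$head, dy)
  layer_backward(model$backbone, dfeats)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @export
print.airsig_model <- function(x, ...) {
  cat(sprintf(
    "<airsig_model> %s (L=%d, C=%d, %d classes), %s, %d parameters\n",
    x$spec$architecture, x$spec$input_length, x$spec$n_channels,
    x$spec$n_classes, if (x$trained) "trained" else "untrained",
    n_parameters(x)
  ))
  invisible(x)
}

#' Class probabilities for a batch
#'
#' @param object An [build_model()] model.
#' @param newdata Array `(batch, input_length, n_channels)`, a matrix
#'   `(input_length, n_channels)` for a single record, or a
#'   [signature_record()].
#' @param ... Unused.
#' @return Matrix `(batch, n_classes)` of probabilities; columns carry class
#'   labels once the model is trained.
#' @export
predict.airsig_model <- function(object, newdata, ...) {
  x <- tensorize_input(object, newdata)
  p <- softmax_rows(model_forward(object, x, training = FALSE))
  if (!is.null(object$classes)) colnames(p) <- object$classes
  p
}

tensorize_input <- function(model, newdata) {
  if (inherits(newdata, "signature_record")) newdata <- newdata$values
  if (is.matrix(newdata)) {
    newdata <- array(newdata, c(1L, nrow(newdata), ncol(newdata)))
  }
  if (length(dim(newdata)) != 3L) {
    abort_airsig("Input must be (batch, time, channels).", "airsig_data_error")
  }
  if (dim(newdata)[2] != model$spec$input_length ||
      dim(newdata)[3] != model$spec$n_channels) {
    abort_airsig(sprintf(
      "Input is %d x %d but the model expects %d x %d.",
      dim(newdata)[2], dim(newdata)[3],
      model$spec$input_length, model$spec$n_channels
    ), "airsig_data_error")
  }
  apply_normalization(model, newdata)
}

apply_normalization <- function(model, x) {
  if (is.null(model$norm)) return(x)
  sweep(sweep(x, 3L, model$norm$center, "-"), 3L, model$norm$scale, "/")
}

#' Audit the layer layout of a model
#'
#' Walks the layer graph and reports every leaf layer with its class, output
#' shape and parameter count — the hook for architecture-conformance checks
#' (hidden widths, branch counts, filter doubling).
#'
#' @param model An `airsig_model`.
#' @return A tibble with columns `name`, `class`, `out_length`,
#'   `out_channels`, `n_params`.
#' @export
model_layout <- function(model) {
  stopifnot(inherits(model, "airsig_model"))
  leaves <- c(collect_layers(model$backbone), collect_layers(model$head))
  tibble::tibble(
    name = vapply(leaves, function(l) l$name, character(1)),
    class = vapply(leaves, function(l) class(l)[1], character(1)),
    out_length = vapply(leaves, function(l) {
      s <- l$out_shape
      if (is_temporal(s)) s$L else NA_integer_
    }, integer(1)),
    out_channels = vapply(leaves, function(l) {
      s <- l$out_shape
      if (is_temporal(s)) s$C else s$F
    }, integer(1)),
    n_params = vapply(leaves, function(l) {
      sum(vapply(layer_params(l), function(p) length(l[[p]]), integer(1)))
    }, integer(1))
  )
}

#' Total trainable parameter count
#' @param model An `airsig_model`.
#' @return Integer.
#' @export
n_parameters <- function(model) sum(model_layout(model)$n_params)
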