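# Class activation maps for the global-average-pooling architectures.

#' Class activation map of a record
#'
#' For architectures whose head is global average pooling followed by a
#' linear softmax layer (FCN, ResNet, InceptionTime), the class activation
#' map at time t is the class-weighted sum of the final convolutional
#' feature maps, `CAM(t) = sum_k w_k^c f_k(t)`, linearly upsampled to the
#' record length and min–max normalized to `[0, 1]` (a constant map becomes
#' all zeros). Red/high regions mark the stretches of the signature the
#' classifier found most distinguishing — often including the start/end
#' dwell periods.
#'
#' @param model A trained `airsig_model` with a GAP head.
#' @param record A [signature_record()], or a `(input_length, n_channels)`
#'   matrix.
#' @param class_index Class to explain: an index into `model$classes`, a
#'   class label, or `NULL` (default) for the predicted class.
#' @param normalize Min–max normalize to `[0, 1]`; default `TRUE`.
#' @return An object of class `cam_result`: `activation` (length = record
#'   length), `class_index`, `class_label`, `architecture`.
#' @export
compute_cam <- function(model, record, class_index = NULL, normalize = TRUE) {
  stopifnot(inherits(model, "airsig_model"))
  if (!isTRUE(model$gap_head)) {
    abort_airsig(
      sprintf(
        "Architecture %s has no global-average-pooling head; CAM supports fcn, resnet and inceptiontime.",
        model$spec$architecture
      ),
      "airsig_unsupported_architecture_error"
    )
  }
  m <- if (inherits(record, "signature_record")) record$values else record
  target_len <- nrow(m)
  if (target_len != model$spec$input_length) {
    old_t <- seq(0, 1, length.out = target_len)
    new_t <- seq(0, 1, length.out = model$spec$input_length)
    m <- apply(m, 2L, function(col) approx(old_t, col, xout = new_t)$y)
  }
  x <- tensorize_input(model, m)
  feats <- layer_forward(model$backbone, x, training = FALSE)  # (1, L', K)
  head_dense <- model$head$layers[[2L]]
  stopifnot(inherits(head_dense, "layer_dense"))
  if (is.null(class_index)) {
    p <- layer_forward(model$head, feats, training = FALSE)
    class_index <- which.max(p[1, ])
  } else if (is.character(class_index)) {
    idx <- match(class_index, model$classes)
    if (is.na(idx)) {
      abort_airsig(sprintf("Unknown class label %s.", sQuote(class_index)),
                   "airsig_config_error")
    }
    class_index <- idx
  } else {
    class_index <- check_count(class_index, "class_index")
    if (class_index > model$spec$n_classes) {
      abort_airsig("`class_index` out of range.", "airsig_config_error")
    }
  }
  fmap <- feats[1, , ]                      # (L', K)
  if (is.null(dim(fmap))) fmap <- matrix(fmap, ncol = dim(feats)[3])
  cam <- as.numeric(fmap %*% head_dense$W[, class_index])
  if (length(cam) != target_len) {
    cam <- approx(seq(0, 1, length.out = length(cam)), cam,
                  xout = seq(0, 1, length.out = target_len))$y
  }
  if (normalize) {
    rng <- range(cam)
    cam <- if (diff(rng) > 0) (cam - rng[1]) / diff(rng) else rep(0, length(cam))
  }
  structure(
    list(
      activation = cam,
      class_index = class_index,
      class_label = if (!is.null(model$classes)) model$classes[class_index] else NA,
      architecture = model$spec$architecture
    ),
    class = "cam_result"
  )
}

#' @export
print.cam_result <- function(x, ...) {
  cat(sprintf("<cam_result> %s, class %s, length %d, peak at t=%d\n",
              x$architecture, x$class_label %||% x$class_index,
              length(x$activation), which.max(x$activation)))
  invisible(x)
}
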