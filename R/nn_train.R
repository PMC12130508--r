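# Optimizers and the deterministic training/evaluation harness.

#' Training configuration
#'
#' Desk defaults are sized for laptop-scale experiments: 150 epochs, batch
#' 16, and per-optimizer learning rates that converge quickly (Adam 1e-3,
#' Adadelta 1.0, SGD 0.01 with momentum 0.9). The reference settings —
#' learning rate 1e-5 and 1500 epochs for every architecture, Adam for
#' FCN/ResNet/Encoder/Time-CNN/InceptionTime, Adadelta for MLP and SGD for
#' MC-DCNN — are reproduced exactly by `paper_defaults = TRUE`.
#'
#' @param architecture Optional architecture name; picks the matching default
#'   optimizer (Adadelta for `"mlp"`, SGD for `"mcdcnn"`, Adam otherwise).
#' @param optimizer `"adam"`, `"adadelta"` or `"sgd"`.
#' @param learning_rate Step size; `NULL` picks the optimizer default.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param momentum SGD momentum.
#' @param normalize Z-score each channel using training-set statistics.
#' @param stop_at_train_acc Optional early-stop threshold on the running
#'   training accuracy; curves are truncated at the stopping epoch.
#' @param paper_defaults If `TRUE`, apply the reference hyper-parameters
#'   (learning rate 1e-5, 1500 epochs, per-architecture optimizer).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(architecture = NULL, optimizer = NULL,
                         learning_rate = NULL, epochs = 150L,
                         batch_size = 16L, momentum = 0.9,
                         normalize = TRUE, stop_at_train_acc = NULL,
                         paper_defaults = FALSE, seed = 1L) {
  paper_defaults <- check_flag(paper_defaults, "paper_defaults")
  if (is.null(optimizer)) {
    optimizer <- if (is.null(architecture)) {
      "adam"
    } else {
      switch(match.arg(tolower(architecture), ARCHITECTURES),
             mlp = "adadelta", mcdcnn = "sgd", "adam")
    }
  }
  optimizer <- match.arg(optimizer, c("adam", "adadelta", "sgd"))
  if (paper_defaults) {
    learning_rate <- 1e-5
    epochs <- 1500L
  }
  if (is.null(learning_rate)) {
    learning_rate <- switch(optimizer, adam = 1e-3, adadelta = 1.0, sgd = 0.01)
  }
  if (!is.null(stop_at_train_acc)) {
    stop_at_train_acc <- check_number(stop_at_train_acc, "stop_at_train_acc",
                                      min = 0, max = 1)
  }
  structure(
    list(
      optimizer = optimizer,
      learning_rate = check_number(learning_rate, "learning_rate", min = 0),
      epochs = check_count(epochs, "epochs"),
      batch_size = check_count(batch_size, "batch_size"),
      momentum = check_number(momentum, "momentum", min = 0, max = 1),
      normalize = check_flag(normalize, "normalize"),
      stop_at_train_acc = stop_at_train_acc,
      paper_defaults = paper_defaults,
      seed = check_count(seed, "seed", min = 0L)
    ),
    class = "train_config"
  )
}

## ---- optimizers ------------------------------------------------------------

make_optimizer <- function(config, layers) {
  env <- new.env(parent = emptyenv())
  env$t <- 0L
  env$step <- switch(config$optimizer,
    sgd = function() {
      for (l in layers) {
        for (p in layer_params(l)) {
          g <- l[[paste0("d", p)]]
          key <- paste0(".vel_", p)
          v <- if (is.null(l[[key]])) g * 0 else l[[key]]
          v <- config$momentum * v - config$learning_rate * g
          l[[key]] <- v
          l[[p]] <- l[[p]] + v
        }
      }
    },
    adam = function() {
      env$t <- env$t + 1L
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      corr1 <- 1 - b1^env$t
      corr2 <- 1 - b2^env$t
      for (l in layers) {
        for (p in layer_params(l)) {
          g <- l[[paste0("d", p)]]
          mk <- paste0(".m_", p); vk <- paste0(".v_", p)
          m <- if (is.null(l[[mk]])) g * 0 else l[[mk]]
          v <- if (is.null(l[[vk]])) g * 0 else l[[vk]]
          m <- b1 * m + (1 - b1) * g
          v <- b2 * v + (1 - b2) * g^2
          l[[mk]] <- m
          l[[vk]] <- v
          l[[p]] <- l[[p]] - config$learning_rate * (m / corr1) /
            (sqrt(v / corr2) + eps)
        }
      }
    },
    adadelta = function() {
      rho <- 0.95; eps <- 1e-6
      for (l in layers) {
        for (p in layer_params(l)) {
          g <- l[[paste0("d", p)]]
          gk <- paste0(".Eg_", p); dk <- paste0(".Ed_", p)
          Eg <- if (is.null(l[[gk]])) g * 0 else l[[gk]]
          Ed <- if (is.null(l[[dk]])) g * 0 else l[[dk]]
          Eg <- rho * Eg + (1 - rho) * g^2
          upd <- -sqrt(Ed + eps) / sqrt(Eg + eps) * g
          Ed <- rho * Ed + (1 - rho) * upd^2
          l[[gk]] <- Eg
          l[[dk]] <- Ed
          l[[p]] <- l[[p]] + config$learning_rate * upd
        }
      }
    }
  )
  env
}

## ---- dataset tensorization -------------------------------------------------

#' Convert a dataset to model input tensors
#'
#' Standardizes every record to `input_length` samples and stacks them into
#' a `(batch, time, channels)` array with a subject-label vector.
#'
#' @param dataset A [signature_dataset()].
#' @param input_length Target record length.
#' @param classes Optional fixed class-label vector (use the training set's
#'   levels when tensorizing validation data).
#' @return List with `x` (array), `y` (integer class indices), `classes`.
#' @export
as_model_input <- function(dataset, input_length, classes = NULL) {
  stopifnot(inherits(dataset, "signature_dataset"))
  if (length(dataset$records) == 0L) {
    abort_airsig("Cannot tensorize an empty dataset.", "airsig_data_error")
  }
  subj <- dataset_subject_ids(dataset)
  if (is.null(classes)) classes <- sort(unique(subj))
  y <- match(subj, classes)
  if (anyNA(y)) {
    abort_airsig(
      sprintf("Class absent from the training label set: %s",
              paste(unique(subj[is.na(y)]), collapse = ", ")),
      "airsig_data_error"
    )
  }
  C <- ncol(dataset$records[[1]]$values)
  x <- array(0, c(length(dataset$records), input_length, C))
  for (i in seq_along(dataset$records)) {
    x[i, , ] <- standardize_length(dataset$records[[i]], input_length)$values
  }
  list(x = x, y = y, classes = classes)
}

weighted_xent <- function(probs, y, w) {
  p <- pmax(probs[cbind(seq_along(y), y)], 1e-12)
  sum(w * -log(p)) / sum(w)
}

## ---- training --------------------------------------------------------------

#' Train a classifier
#'
#' Deterministic given `config$seed` (initialization, shuffling and dropout
#' all draw from one stream). Sample weights, e.g. from
#' [reweight_for_missing()], weight the cross-entropy loss.
#'
#' @param model An [build_model()] model (re-initialized under the training
#'   seed).
#' @param train,val [signature_dataset()]s, or lists as returned by
#'   [as_model_input()]. Every class must appear in `train`.
#' @param config A [train_config()].
#' @param sample_weights Optional per-record training weights.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_result`: per-epoch `train_loss`,
#'   `val_loss`, `train_acc`, `val_acc` curves, final accuracies, the label
#'   set and a config echo. The model is updated in place and keeps the
#'   normalization statistics for prediction.
#' @export
train_model <- function(model, train, val = NULL, config = train_config(),
                        sample_weights = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "airsig_model"), inherits(config, "train_config"))
  L <- model$spec$input_length
  if (inherits(train, "signature_dataset")) train <- as_model_input(train, L)
  if (inherits(val, "signature_dataset")) {
    val <- as_model_input(val, L, classes = train$classes)
  }
  if (length(unique(train$y)) < model$spec$n_classes) {
    abort_airsig("Some class has no training records.", "airsig_data_error")
  }
  n <- dim(train$x)[1]
  w <- if (is.null(sample_weights)) rep(1, n) else as.numeric(sample_weights)
  if (length(w) != n) {
    abort_airsig("`sample_weights` length must match the training set.",
                 "airsig_data_error")
  }
  if (config$normalize) {
    center <- apply(train$x, 3L, mean)
    scale <- apply(train$x, 3L, sd)
    scale[scale < 1e-12] <- 1
    model$norm <- list(center = center, scale = scale)
  } else {
    model$norm <- NULL
  }
  x <- apply_normalization(model, train$x)
  xv <- if (!is.null(val)) apply_normalization(model, val$x)
  K <- model$spec$n_classes

  train_loss <- train_acc <- val_loss <- val_acc <- numeric(0)
  with_seed(config$seed, {
    materialize_model(model)
    layers <- Filter(function(l) length(layer_params(l)) > 0,
                     c(collect_layers(model$backbone), collect_layers(model$head)))
    opt <- make_optimizer(config, layers)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(n)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      ep_loss <- 0; ep_w <- 0; ep_correct <- 0
      for (b in batches) {
        xb <- x[b, , , drop = FALSE]
        yb <- train$y[b]
        wb <- w[b]
        logits <- model_forward(model, xb, training = TRUE)
        probs <- softmax_rows(logits)
        loss <- weighted_xent(probs, yb, wb)
        grad <- probs
        grad[cbind(seq_along(yb), yb)] <- grad[cbind(seq_along(yb), yb)] - 1
        grad <- grad * (wb / sum(wb))
        model_backward(model, grad)
        opt$step()
        if (!all(is.finite(loss))) {
          abort_airsig(sprintf("Training diverged (NaN loss) at epoch %d.", epoch),
                       "airsig_training_error")
        }
        ep_loss <- ep_loss + loss * sum(wb)
        ep_w <- ep_w + sum(wb)
        ep_correct <- ep_correct + sum(max.col(probs) == yb)
      }
      train_loss[epoch] <- ep_loss / ep_w
      train_acc[epoch] <- ep_correct / n
      if (!is.null(val)) {
        pv <- softmax_rows(model_forward(model, xv, training = FALSE))
        val_loss[epoch] <- weighted_xent(pv, val$y, rep(1, length(val$y)))
        val_acc[epoch] <- mean(max.col(pv) == val$y)
      }
      if (verbose) {
        message(sprintf("epoch %d/%d loss %.4f acc %.3f%s",
                        epoch, config$epochs, train_loss[epoch], train_acc[epoch],
                        if (is.null(val)) "" else
                          sprintf(" val_acc %.3f", val_acc[epoch])))
      }
      if (!is.null(config$stop_at_train_acc) &&
          train_acc[epoch] >= config$stop_at_train_acc) break
    }
  })
  model$trained <- TRUE
  model$classes <- train$classes
  structure(
    list(
      train_loss = train_loss, val_loss = val_loss,
      train_acc_curve = train_acc, val_acc_curve = val_acc,
      train_acc = tail(train_acc, 1),
      val_acc = if (is.null(val)) NA_real_ else tail(val_acc, 1),
      epochs_run = length(train_loss),
      classes = train$classes,
      config = config, spec = model$spec
    ),
    class = "train_result"
  )
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "<train_result> %s: %d epoch(s), train acc %.3f%s\n",
    x$spec$architecture, x$epochs_run, x$train_acc,
    if (is.na(x$val_acc)) "" else sprintf(", val acc %.3f", x$val_acc)
  ))
  invisible(x)
}

#' Accuracy of a trained model on a dataset
#'
#' @param model A trained `airsig_model`.
#' @param dataset A [signature_dataset()] or [as_model_input()] list.
#' @return Classification accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, dataset) {
  stopifnot(inherits(model, "airsig_model"))
  if (inherits(dataset, "signature_dataset")) {
    dataset <- as_model_input(dataset, model$spec$input_length,
                              classes = model$classes)
  }
  p <- softmax_rows(model_forward(model, apply_normalization(model, dataset$x),
                                  training = FALSE))
  mean(max.col(p) == dataset$y)
}
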