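# The model-selection experiment grid: (9 uni-variate views + 1 multivariate
# view) x 7 architectures x devices.

#' The model-selection experiment design
#'
#' Enumerates one cell per (device, dimension view, architecture): the nine
#' uni-variate channel views plus the full multivariate view, crossed with
#' the seven architectures. Two devices give 10 x 7 x 2 = 140 cells.
#'
#' @param devices Character vector of device names.
#' @param architectures Architectures to include; default all seven.
#' @return A tibble with columns `device`, `view`, `channels` (list column of
#'   channel indices) and `architecture`.
#' @export
model_selection_design <- function(devices = c("phone", "smartwatch"),
                                   architectures = ARCHITECTURES) {
  views <- c(channel_schema()$names, "multivariate")
  grid <- expand.grid(
    architecture = architectures, view = views, device = devices,
    stringsAsFactors = FALSE
  )[, c("device", "view", "architecture")]
  grid <- tibble::as_tibble(grid)
  grid$channels <- lapply(grid$view, function(v) {
    if (v == "multivariate") 1:9 else match(v, channel_schema()$names)
  })
  grid
}

#' The coalition experiment design
#'
#' One cell per (device, coalition): all `2^p` channel subsets including the
#' empty set, for each device. With `p = 9` and two devices this is
#' 512 x 2 = 1024 cells, covering `2^p * n_records` coalition-restricted
#' signals per device.
#'
#' @param p Number of channels; default 9.
#' @param devices Character vector of device names.
#' @return A tibble with columns `device`, `coalition` (list column) and
#'   `size`.
#' @export
coalition_design <- function(p = 9L, devices = c("phone", "smartwatch")) {
  coalitions <- enumerate_coalitions(p)
  grid <- tibble::tibble(
    device = rep(devices, each = length(coalitions)),
    coalition = rep(coalitions, times = length(devices))
  )
  grid$size <- vapply(grid$coalition, function(co) length(co$members), integer(1))
  grid
}

#' Run the model-selection grid
#'
#' Trains every (device, view, architecture) cell of
#' [model_selection_design()] and reports train/validation loss and accuracy
#' per cell. Failed cells are flagged and the grid completes.
#'
#' @param datasets Named list of [signature_dataset()]s, one per device.
#' @param specs Function `(architecture, n_channels, n_classes) ->`
#'   [model_spec()]; defaults to the reference layer parameters at
#'   `input_length`.
#' @param config A [train_config()] applied to every cell (the optimizer is
#'   re-resolved per architecture).
#' @param input_length Standardized length fed to the models.
#' @param split A [split_spec()] shared by all cells.
#' @param architectures Architectures to include.
#' @param verbose Print per-cell progress.
#' @return The design tibble extended with `train_loss`, `val_loss`,
#'   `train_acc`, `val_acc`, `error` columns.
#' @export
run_model_selection <- function(datasets, specs = NULL,
                                config = train_config(),
                                input_length = 100L,
                                split = split_spec(),
                                architectures = ARCHITECTURES,
                                verbose = FALSE) {
  stopifnot(is.list(datasets), length(names(datasets)) == length(datasets))
  design <- model_selection_design(names(datasets), architectures)
  out <- cbind(design, tibble::tibble(
    train_loss = NA_real_, val_loss = NA_real_,
    train_acc = NA_real_, val_acc = NA_real_, error = NA_character_
  ))
  splits <- lapply(datasets, split_dataset, spec = split)
  for (i in seq_len(nrow(out))) {
    dev <- out$device[i]
    cell <- tryCatch({
      tr <- extract_coalition(splits[[dev]]$train, coalition(out$channels[[i]]))
      te <- extract_coalition(splits[[dev]]$test, coalition(out$channels[[i]]))
      n_classes <- length(dataset_subjects(tr))
      spec <- if (is.null(specs)) {
        model_spec(out$architecture[i], input_length,
                   length(out$channels[[i]]), n_classes)
      } else {
        specs(out$architecture[i], length(out$channels[[i]]), n_classes)
      }
      cfg <- config
      cfg$optimizer <- train_config(architecture = out$architecture[i],
                                    paper_defaults = config$paper_defaults)$optimizer
      model <- build_model(spec, seed = config$seed)
      res <- train_model(model, tr, te, cfg)
      list(train_loss = tail(res$train_loss, 1),
           val_loss = tail(res$val_loss, 1),
           train_acc = res$train_acc, val_acc = res$val_acc, error = NA_character_)
    }, error = function(e) {
      list(train_loss = NA_real_, val_loss = NA_real_,
           train_acc = NA_real_, val_acc = NA_real_,
           error = conditionMessage(e))
    })
    out$train_loss[i] <- cell$train_loss
    out$val_loss[i] <- cell$val_loss %||% NA_real_
    out$train_acc[i] <- cell$train_acc
    out$val_acc[i] <- cell$val_acc
    out$error[i] <- cell$error
    if (verbose) {
      message(sprintf("[%d/%d] %s %s %s: val acc %.3f", i, nrow(out),
                      dev, out$view[i], out$architecture[i], out$val_acc[i]))
    }
  }
  tibble::as_tibble(out)
}
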