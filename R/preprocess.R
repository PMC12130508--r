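# Length standardization, subject-stratified splitting, missing-data
# re-weighting, coalition slicing, and the corpus heatmap statistic.

#' Resample a record to a fixed length
#'
#' Linear interpolation on a uniform grid over the original time span. The
#' sampling interval metadata is rescaled so the record still covers the same
#' wall-clock duration.
#'
#' @param record A [signature_record()].
#' @param target_length Desired number of samples (>= 2); default 1000.
#' @return A [signature_record()] with exactly `target_length` rows.
#' @export
standardize_length <- function(record, target_length = 1000L) {
  stopifnot(inherits(record, "signature_record"))
  target_length <- check_count(target_length, "target_length", min = 2L)
  n <- nrow(record$values)
  if (n == target_length) return(record)
  old_t <- seq(0, 1, length.out = n)
  new_t <- seq(0, 1, length.out = target_length)
  vals <- apply(record$values, 2L, function(col) {
    approx(old_t, col, xout = new_t, method = "linear")$y
  })
  colnames(vals) <- colnames(record$values)
  new_interval <- record$sampling_interval_ms * (n - 1) / (target_length - 1)
  rec <- record
  rec$values <- vals
  # keep metadata truthful but within the plausible envelope
  rec$sampling_interval_ms <- min(max(new_interval, 18), 230)
  rec
}

#' Standardize every record of a dataset
#' @inheritParams standardize_length
#' @param dataset A [signature_dataset()].
#' @return A [signature_dataset()] whose records all have `target_length` rows.
#' @export
standardize_dataset <- function(dataset, target_length = 1000L) {
  stopifnot(inherits(dataset, "signature_dataset"))
  recs <- lapply(dataset$records, standardize_length, target_length = target_length)
  signature_dataset(recs, dataset$device,
                    c(dataset$provenance, list(standardized_length = target_length)))
}

#' Train/test split specification
#'
#' @param test_fraction Fraction of records held out; default 0.2.
#' @param stratify_by_subject If `TRUE` (default) each subject contributes
#'   `floor(n_i * test_fraction)` records (at least 1 when `n_i >= 5`) to the
#'   test set, so every subject stays represented in training — a requirement
#'   for closed-set identification.
#' @param seed RNG seed for the draw.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, stratify_by_subject = TRUE, seed = 1L) {
  test_fraction <- check_number(test_fraction, "test_fraction")
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort_airsig("`test_fraction` must be in (0, 1).", "airsig_config_error")
  }
  structure(
    list(test_fraction = test_fraction,
         stratify_by_subject = check_flag(stratify_by_subject, "stratify_by_subject"),
         seed = check_count(seed, "seed", min = 0L)),
    class = "split_spec"
  )
}

#' Split a dataset into train and test partitions
#'
#' The partition is disjoint and exhaustive; under stratification every
#' subject appears in the training partition.
#'
#' @param dataset A [signature_dataset()].
#' @param spec A [split_spec()].
#' @return A list with elements `train` and `test` ([signature_dataset()]s)
#'   and `test_indices` (positions of the test records in `dataset`).
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "signature_dataset"), inherits(spec, "split_spec"))
  n <- length(dataset$records)
  if (n == 0L) abort_airsig("Cannot split an empty dataset.", "airsig_data_error")
  subj <- dataset_subject_ids(dataset)
  test_idx <- with_seed(spec$seed, {
    if (spec$stratify_by_subject) {
      idx <- integer(0)
      for (s in unique(subj)) {
        pos <- which(subj == s)
        n_i <- length(pos)
        if (n_i < 2L) {
          abort_airsig(
            sprintf("Subject %s has %d record(s); stratified splitting needs >= 2.", s, n_i),
            "airsig_stratification_error"
          )
        }
        k <- floor(n_i * spec$test_fraction)
        if (k < 1L && n_i >= 5L) k <- 1L
        if (k >= n_i) k <- n_i - 1L
        if (k > 0L) idx <- c(idx, sample(pos, k))
      }
      idx
    } else {
      sample(n, max(1L, round(n * spec$test_fraction)))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  list(
    train = subset_dataset(dataset, train_idx, "train partition"),
    test = subset_dataset(dataset, test_idx, "test partition"),
    test_indices = test_idx
  )
}

#' Sampling weights that compensate for missing records
#'
#' Subjects with lost records would otherwise appear less often than complete
#' subjects; re-weighting restores each subject's expected frequency. The
#' weight of every record of a subject is `expected_count / actual_count`, so
#' complete subjects get weight 1 and the weighted total per subject equals
#' the expected count.
#'
#' @param dataset A [signature_dataset()] (typically the training partition).
#' @param full_counts Either a single expected per-subject count or a named
#'   numeric vector mapping subject id to expected count.
#' @return Numeric vector of per-record weights, in record order.
#' @export
reweight_for_missing <- function(dataset, full_counts) {
  stopifnot(inherits(dataset, "signature_dataset"))
  subj <- dataset_subject_ids(dataset)
  if (length(subj) == 0L) {
    abort_airsig("Cannot re-weight an empty dataset.", "airsig_data_error")
  }
  counts <- table(subj)
  expected <- if (length(full_counts) == 1L && is.null(names(full_counts))) {
    setNames(rep(as.numeric(full_counts), length(counts)), names(counts))
  } else {
    miss <- setdiff(names(counts), names(full_counts))
    if (length(miss) > 0L) {
      abort_airsig(
        sprintf("No expected count for subject(s): %s", paste(miss, collapse = ", ")),
        "airsig_config_error"
      )
    }
    full_counts[names(counts)]
  }
  w <- as.numeric(expected[subj] / counts[subj])
  setNames(w, vapply(dataset$records, record_key, character(1)))
}

#' A coalition of channels
#'
#' A coalition is a subset of the 9 channel indices, treated as the set of
#' cooperating "players" available to a classifier. The empty coalition is
#' valid (its value is supplied by the attribution baseline, not by training).
#'
#' @param members Integer vector of channel indices in 1..9 (may be empty),
#'   or channel names.
#' @param p Number of players; default 9.
#' @return An object of class `coalition`: sorted integer members plus `p`.
#' @export
coalition <- function(members = integer(0), p = 9L) {
  p <- check_count(p, "p")
  if (is.character(members)) {
    members <- match(members, channel_schema()$names[seq_len(p)])
    if (anyNA(members)) {
      abort_airsig("Unknown channel name in coalition.", "airsig_config_error")
    }
  }
  members <- as.integer(members)
  if (anyDuplicated(members) || any(members < 1L | members > p)) {
    abort_airsig(sprintf("Coalition members must be distinct indices in 1..%d.", p),
                 "airsig_config_error")
  }
  structure(list(members = sort(members), p = p), class = "coalition")
}

#' @export
print.coalition <- function(x, ...) {
  cat(sprintf("<coalition> {%s} of %d players\n",
              paste(x$members, collapse = ","), x$p))
  invisible(x)
}

coalition_key <- function(members) paste(sort(as.integer(members)), collapse = ",")

#' Restrict a dataset to the channels of a coalition
#'
#' @param dataset A [signature_dataset()] with all 9 channels.
#' @param coal A [coalition()] with at least one member, or an integer vector
#'   of channel indices.
#' @return A [signature_dataset()] whose records carry only the member
#'   channels, in canonical order.
#' @export
extract_coalition <- function(dataset, coal) {
  stopifnot(inherits(dataset, "signature_dataset"))
  if (!inherits(coal, "coalition")) coal <- coalition(coal)
  if (length(coal$members) == 0L) {
    abort_airsig(
      "Empty coalition: no channels to extract (its value is the attribution baseline).",
      "airsig_empty_coalition_error"
    )
  }
  have <- colnames(dataset$records[[1]]$values)
  want <- channel_schema()$names[coal$members]
  if (!all(want %in% have)) {
    abort_airsig("Dataset lacks some coalition channels.", "airsig_config_error")
  }
  recs <- lapply(dataset$records, function(r) {
    r$values <- r$values[, want, drop = FALSE]
    r
  })
  signature_dataset(recs, dataset$device,
                    c(dataset$provenance, list(coalition = coal$members)))
}

#' Per-subject mean series for the corpus heatmap
#'
#' For each subject, averages the 9 channels and all repetitions into one
#' series summarising the first `horizon` time stamps. Records whose length
#' differs from `horizon` are linearly resampled first.
#'
#' @param dataset A [signature_dataset()].
#' @param horizon Number of leading time stamps summarised; default 1000.
#' @param normalize If `TRUE`, min–max normalize the whole matrix to `[0, 1]`
#'   (a display convention for heatmaps); default `FALSE`.
#' @return A `subjects x horizon` matrix with subject ids as row names.
#' @export
subject_mean_series <- function(dataset, horizon = 1000L, normalize = FALSE) {
  stopifnot(inherits(dataset, "signature_dataset"))
  horizon <- check_count(horizon, "horizon", min = 2L)
  if (length(dataset$records) == 0L) {
    abort_airsig("Cannot summarise an empty dataset.", "airsig_data_error")
  }
  subj <- dataset_subject_ids(dataset)
  subjects <- sort(unique(subj))
  out <- matrix(0, length(subjects), horizon, dimnames = list(subjects, NULL))
  for (i in seq_along(subjects)) {
    pos <- which(subj == subjects[i])
    acc <- numeric(horizon)
    for (j in pos) {
      r <- standardize_length(dataset$records[[j]], horizon)
      acc <- acc + rowMeans(r$values)
    }
    out[i, ] <- acc / length(pos)
  }
  if (normalize) {
    rng <- range(out)
    if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  }
  out
}
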