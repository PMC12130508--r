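# Per-signature CSV dialect: a header row with the 9 channel names (any of
# the accepted spellings) followed by T numeric rows. Corpus layout: one
# directory per device containing {subject}_{round}_{session}.csv files and
# an optional provenance.json sidecar.

#' Read one per-signature CSV file
#'
#' Columns may appear in any order and under either accepted spelling
#' (`acc_x`/`Acc_x`, `att_*`/`Ori_*`); they are normalized to schema order.
#'
#' @param path Path to the CSV file.
#' @param subject_id,round_index,session,device Record metadata (see
#'   [signature_record()]).
#' @param sampling_interval_ms Sampling interval in milliseconds.
#' @return A [signature_record()].
#' @examples
#' f <- system.file("extdata", "phone_sample_subject1.csv", package = "airsig")
#' r <- read_signature_csv(f, "S001", 1, 1, "phone", 220)
#' r$values[1, c("acc_x", "att_z")]
#' @export
read_signature_csv <- function(path, subject_id, round_index, session, device,
                               sampling_interval_ms = 220) {
  if (!file.exists(path)) {
    abort_airsig(sprintf("File not found: %s", path), "airsig_io_error")
  }
  df <- tryCatch(
    read.csv(path, header = TRUE, check.names = FALSE, colClasses = "character"),
    error = function(e) {
      abort_airsig(sprintf("Cannot parse %s: %s", path, conditionMessage(e)),
                   "airsig_parse_error")
    }
  )
  canon <- normalize_channel_names(names(df))
  names(df) <- canon
  df <- df[, channel_schema()$names, drop = FALSE]
  if (nrow(df) < 2L) {
    abort_airsig(
      sprintf("%s has %d data rows; a signature needs at least 2.", path, nrow(df)),
      "airsig_empty_signal_error"
    )
  }
  mat <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      abort_airsig(
        sprintf(
          "Non-numeric cell in %s at row %d, column %s: %s",
          path, row, names(df)[j], sQuote(df[[j]][row])
        ),
        "airsig_parse_error"
      )
    }
    mat[, j] <- v
  }
  signature_record(mat, subject_id, round_index, session, device,
                   sampling_interval_ms)
}

#' Write one signature record as CSV
#'
#' Values are written with 6 decimal places, so a write/read round trip
#' reproduces the matrix to 1e-6 and the metadata exactly.
#'
#' @param record A [signature_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_csv <- function(record, path) {
  stopifnot(inherits(record, "signature_record"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_airsig(sprintf("Directory does not exist: %s", dir), "airsig_io_error")
  }
  df <- as.data.frame(round(record$values, 6))
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort_airsig(sprintf("Cannot write %s", path), "airsig_io_error")
  }
  invisible(path)
}

dataset_filename <- function(record) {
  sprintf("%s_%d_%d.csv", record$subject_id, record$round_index, record$session)
}

#' Write a whole corpus as a directory of per-signature CSV files
#'
#' Emits one `{subject}_{round}_{session}.csv` per record plus a
#' `provenance.json` sidecar carrying device, per-record sampling intervals
#' and the dataset provenance.
#'
#' @param dataset A [signature_dataset()].
#' @param root Output directory (created if absent).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "signature_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    device = dataset$device,
    provenance = dataset$provenance,
    sampling_interval_ms = setNames(
      lapply(dataset$records, function(r) r$sampling_interval_ms),
      vapply(dataset$records, dataset_filename, character(1))
    )
  )
  for (r in dataset$records) {
    write_signature_csv(r, file.path(root, dataset_filename(r)))
  }
  jsonlite::write_json(meta, file.path(root, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(root)
}

#' Load a corpus from a directory of per-signature CSV files
#'
#' Files must follow the `{subject}_{round}_{session}.csv` naming convention.
#' Files that do not match the convention are skipped with a warning; a
#' duplicated (subject, round, session) triple is an integrity error.
#'
#' @param root Directory containing the CSV files.
#' @param device `"phone"` or `"smartwatch"`.
#' @param sampling_interval_ms Fallback sampling interval for files without a
#'   provenance sidecar entry.
#' @return A [signature_dataset()].
#' @export
load_dataset <- function(root, device, sampling_interval_ms = 220) {
  device <- check_device(device)
  if (!dir.exists(root)) {
    abort_airsig(sprintf("Directory not found: %s", root), "airsig_io_error")
  }
  files <- sort(list.files(root, pattern = "\\.csv$", full.names = FALSE))
  intervals <- list()
  prov_path <- file.path(root, "provenance.json")
  if (file.exists(prov_path)) {
    sidecar <- jsonlite::read_json(prov_path)
    intervals <- sidecar$sampling_interval_ms %||% list()
  }
  records <- list()
  rejected <- character(0)
  for (f in files) {
    m <- regmatches(f, regexec("^(.*)_([0-9]+)_([0-9]+)\\.csv$", f))[[1]]
    if (length(m) != 4L) {
      rejected <- c(rejected, f)
      next
    }
    interval <- intervals[[f]] %||% sampling_interval_ms
    records[[length(records) + 1L]] <- read_signature_csv(
      file.path(root, f),
      subject_id = m[2], round_index = as.integer(m[3]),
      session = as.integer(m[4]), device = device,
      sampling_interval_ms = as.numeric(interval)
    )
  }
  if (length(rejected) > 0L) {
    warning(sprintf(
      "Skipped %d file(s) not matching {subject}_{round}_{session}.csv: %s",
      length(rejected), paste(rejected, collapse = ", ")
    ), call. = FALSE)
  }
  if (length(records) == 0L) {
    warning(sprintf("No signature files found under %s; empty dataset.", root),
            call. = FALSE)
  }
  signature_dataset(records, device, provenance = list(source = root))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
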