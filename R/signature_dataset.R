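#' A corpus of in-air signature records
#'
#' All records in a dataset share one device and the channel schema, and the
#' `(subject_id, round_index, session)` triple of every record is unique.
#'
#' @param records List of [signature_record()] objects.
#' @param device `"phone"` or `"smartwatch"`.
#' @param provenance Free-form list describing where the corpus came from
#'   (source directory, or generator config plus seed).
#' @return An object of class `signature_dataset`.
#' @export
signature_dataset <- function(records, device, provenance = list()) {
  device <- check_device(device)
  if (!is.list(records)) {
    abort_airsig("`records` must be a list of signature_record objects.", "airsig_data_error")
  }
  for (r in records) {
    if (!inherits(r, "signature_record")) {
      abort_airsig("Every element of `records` must be a signature_record.", "airsig_data_error")
    }
    if (!identical(r$device, device)) {
      abort_airsig(
        sprintf(
          "Mixed devices: dataset is %s but record %s is %s.",
          device, record_key(r), r$device
        ),
        "airsig_integrity_error"
      )
    }
  }
  keys <- vapply(records, record_key, character(1))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    abort_airsig(
      sprintf("Duplicate (subject, round, session) triple: %s.", dup),
      "airsig_integrity_error"
    )
  }
  structure(
    list(records = records, schema = channel_schema(), device = device,
         provenance = provenance),
    class = "signature_dataset"
  )
}

#' @export
length.signature_dataset <- function(x) length(x$records)

#' @export
print.signature_dataset <- function(x, ...) {
  subj <- dataset_subjects(x)
  lens <- vapply(x$records, function(r) nrow(r$values), integer(1))
  cat(sprintf(
    "<signature_dataset> %d records, %d subjects, device %s\n",
    length(x$records), length(subj), x$device
  ))
  if (length(x$records) > 0L) {
    cat(sprintf(
      "  channels: %d, lengths: %d-%d\n",
      ncol(x$records[[1]]$values), min(lens), max(lens)
    ))
  }
  invisible(x)
}

#' Subjects of a dataset
#' @param dataset A [signature_dataset()].
#' @return Sorted character vector of unique subject ids.
#' @export
dataset_subjects <- function(dataset) {
  sort(unique(vapply(dataset$records, function(r) r$subject_id, character(1))))
}

dataset_subject_ids <- function(dataset) {
  vapply(dataset$records, function(r) r$subject_id, character(1))
}

subset_dataset <- function(dataset, idx, provenance_note = NULL) {
  prov <- dataset$provenance
  if (!is.null(provenance_note)) prov <- c(prov, list(note = provenance_note))
  signature_dataset(dataset$records[idx], dataset$device, prov)
}
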