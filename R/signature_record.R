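#' A single in-air signature record
#'
#' Bundles one multivariate inertial signal (a `T x 9` numeric matrix, or
#' fewer columns after coalition projection) with its subject, round, session
#' and device metadata.
#'
#' @param values Numeric matrix with `T >= 2` rows and columns named after
#'   (a subset of) the channel schema, in schema order.
#' @param subject_id Character scalar identifying the signer.
#' @param round_index Integer repetition index, 1..10.
#' @param session Integer session index (1 or 2; capture sessions were held
#'   days apart).
#' @param device `"phone"` or `"smartwatch"`.
#' @param sampling_interval_ms Positive sampling interval in milliseconds.
#'   Must lie in `interval_range`.
#' @param interval_range Length-2 numeric giving the plausible sampling
#'   interval range; default 18–230 ms, the span of the device sampling
#'   modes.
#' @return An object of class `signature_record`.
#' @examples
#' m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("acc_x", "gyr_y")))
#' r <- signature_record(m, "S001", 1, 1, "phone", 220)
#' dim(r$values)
#' @export
signature_record <- function(values, subject_id, round_index, session,
                             device, sampling_interval_ms,
                             interval_range = c(18, 230)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_airsig("`values` must be a numeric matrix.", "airsig_data_error")
  }
  if (nrow(values) < 2L) {
    abort_airsig(
      "A signature needs at least 2 samples (empty or single-row signal).",
      "airsig_empty_signal_error"
    )
  }
  if (anyNA(values)) {
    abort_airsig("`values` must not contain missing cells.", "airsig_data_error")
  }
  schema <- channel_schema()$names
  cols <- colnames(values)
  if (is.null(cols) || !all(cols %in% schema)) {
    abort_airsig(
      "`values` columns must be named with channel-schema labels.",
      "airsig_schema_error"
    )
  }
  if (!identical(cols, schema[schema %in% cols])) {
    abort_airsig(
      "`values` columns must appear in channel-schema order.",
      "airsig_schema_error"
    )
  }
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    abort_airsig("`subject_id` must be a non-empty string.", "airsig_data_error")
  }
  round_index <- check_count(round_index, "round_index", min = 1L)
  if (round_index > 10L) {
    abort_airsig("`round_index` must be in 1..10.", "airsig_data_error")
  }
  session <- check_count(session, "session", min = 1L)
  if (!(session %in% c(1L, 2L))) {
    abort_airsig("`session` must be 1 or 2.", "airsig_data_error")
  }
  device <- check_device(device)
  sampling_interval_ms <- check_number(
    sampling_interval_ms, "sampling_interval_ms",
    min = interval_range[1], max = interval_range[2]
  )
  structure(
    list(
      values = values,
      subject_id = subject_id,
      round_index = round_index,
      session = session,
      device = device,
      sampling_interval_ms = sampling_interval_ms
    ),
    class = "signature_record"
  )
}

#' @export
print.signature_record <- function(x, ...) {
  cat(sprintf(
    "<signature_record> subject %s round %d session %d (%s), %d x %d, %.1f ms/sample\n",
    x$subject_id, x$round_index, x$session, x$device,
    nrow(x$values), ncol(x$values), x$sampling_interval_ms
  ))
  invisible(x)
}

record_key <- function(record) {
  sprintf("%s_%d_%d", record$subject_id, record$round_index, record$session)
}
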