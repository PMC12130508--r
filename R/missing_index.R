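#' Index of missing signature records
#'
#' A missing-record index lists `(participant_index, signature_index,
#' section)` triples describing signatures lost during corpus collection or
#' transfer. Participant indices are positional: entry `k` refers to the
#' `k`-th subject in the sorted unique subject list of the dataset the index
#' is applied to.
#'
#' @param participant_index Integer vector of participant positions (>= 1).
#' @param signature_index Integer vector of repetition rounds (1..10).
#' @param section Integer vector of capture sessions (1 or 2).
#' @return An object of class `missing_index` (a data frame of the triples).
#' @seealso [apply_missing()], [phone_missing_index()]
#' @export
missing_index <- function(participant_index, signature_index, section) {
  n <- length(participant_index)
  if (length(signature_index) != n || length(section) != n) {
    abort_airsig("Missing-index columns must have equal length.", "airsig_config_error")
  }
  participant_index <- vapply(participant_index, check_count, integer(1),
                              name = "participant_index")
  signature_index <- vapply(signature_index, check_count, integer(1),
                            name = "signature_index")
  if (any(signature_index > 10L)) {
    abort_airsig("`signature_index` must be in 1..10.", "airsig_config_error")
  }
  if (!all(section %in% c(1L, 2L))) {
    abort_airsig("`section` must be 1 or 2.", "airsig_config_error")
  }
  structure(
    data.frame(
      participant_index = participant_index,
      signature_index = signature_index,
      section = as.integer(section)
    ),
    class = c("missing_index", "data.frame")
  )
}

#' The 23-entry missing-record pattern of the phone corpus
#'
#' The reference phone corpus lost 23 signatures during data transfer;
#' this index reproduces that pattern so synthetic corpora can emulate the
#' same incompleteness. Note every lost signature satisfies
#' `section == 1` exactly when `signature_index <= 5`, i.e. rounds 1–5
#' belong to the first capture session.
#'
#' @return A [missing_index()] with 23 entries.
#' @export
phone_missing_index <- function() {
  missing_index(
    participant_index = c(16L, 18L, 18L, 58L, 78L, 88L, 99L, 100L, 137L,
                          156L, 165L, 178L, 189L, 204L, 210L, 211L, 230L,
                          239L, 270L, 270L, 278L, 279L, 280L),
    signature_index = c(5L, 6L, 7L, 4L, 3L, 4L, 8L, 1L, 7L,
                        9L, 8L, 5L, 3L, 7L, 4L, 5L, 5L,
                        6L, 6L, 9L, 4L, 2L, 1L),
    section = c(1L, 2L, 2L, 1L, 1L, 1L, 2L, 1L, 2L,
                2L, 2L, 1L, 1L, 2L, 1L, 1L, 1L,
                2L, 2L, 2L, 1L, 1L, 1L)
  )
}
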