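# Seeded synthetic-corpus generator. Each subject owns a smooth latent
# "motor program" per channel (a band-limited sum of random sinusoids); a
# record mixes that latent with record-specific smooth noise according to the
# per-channel informativeness, adds white repetition noise, a per-subject
# session-2 offset, and noisy dwell segments at both ends (signers hold the
# device still for a moment before and after signing).

#' Configuration for the synthetic signature generator
#'
#' @param n_subjects Number of signers.
#' @param n_repetitions Repetitions (rounds) per signer; default 10.
#' @param n_sessions Capture sessions; default 2. With two sessions, rounds
#'   `1..ceiling(n/2)` belong to session 1 and the rest to session 2,
#'   matching the half/half session layout of the reference corpora.
#' @param duration_steps Nominal record length in samples; default 1000 (the
#'   horizon the corpus-level heatmap summarises).
#' @param sampling_interval_ms Either a single value or a length-2 range from
#'   which each record's interval is drawn uniformly; default `c(215, 230)`,
#'   the interval of the normal-rate sampling mode.
#' @param channel_informativeness 9-vector in `[0, 1]`: the fraction of each
#'   channel's variance carried by the subject-specific latent rather than
#'   record noise. Default 0.7 for all channels.
#' @param repetition_noise_sd White-noise sd added to every sample; default
#'   0.1.
#' @param session_shift_sd Sd of the per-subject, per-channel constant offset
#'   applied to session-2 records; default 0.2.
#' @param dwell_steps Length of the noisy start/end dwell segments; default 5.
#' @param dwell_sd Sd of the dwell-segment noise; default 0.15.
#' @param n_harmonics Number of sinusoids per latent trajectory; default 6.
#' @param jitter_length If `TRUE` (default) record lengths are jittered
#'   uniformly within ±10% of `duration_steps`, forcing downstream length
#'   standardization.
#' @param missing Optional [missing_index()] applied after generation.
#' @param seed Integer RNG seed. Each record derives its own stream from
#'   `(seed, subject, round, session)`, so removing a record never shifts
#'   the others.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects,
                             n_repetitions = 10L,
                             n_sessions = 2L,
                             duration_steps = 1000L,
                             sampling_interval_ms = c(215, 230),
                             channel_informativeness = rep(0.7, 9),
                             repetition_noise_sd = 0.1,
                             session_shift_sd = 0.2,
                             dwell_steps = 5L,
                             dwell_sd = 0.15,
                             n_harmonics = 6L,
                             jitter_length = TRUE,
                             missing = NULL,
                             seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_repetitions <- check_count(n_repetitions, "n_repetitions")
  n_sessions <- check_count(n_sessions, "n_sessions")
  if (!(n_sessions %in% c(1L, 2L))) {
    abort_airsig("`n_sessions` must be 1 or 2.", "airsig_config_error")
  }
  duration_steps <- check_count(duration_steps, "duration_steps", min = 3L)
  dwell_steps <- check_count(dwell_steps, "dwell_steps", min = 0L)
  if (duration_steps <= 2L * dwell_steps) {
    abort_airsig("`duration_steps` must exceed 2 * dwell_steps.", "airsig_config_error")
  }
  if (length(sampling_interval_ms) == 1L) {
    sampling_interval_ms <- rep(sampling_interval_ms, 2L)
  }
  if (length(sampling_interval_ms) != 2L || any(sampling_interval_ms <= 0) ||
      sampling_interval_ms[1] > sampling_interval_ms[2]) {
    abort_airsig("`sampling_interval_ms` must be a value or increasing range.",
                 "airsig_config_error")
  }
  if (length(channel_informativeness) != 9L ||
      any(channel_informativeness < 0 | channel_informativeness > 1)) {
    abort_airsig("`channel_informativeness` must be a 9-vector in [0, 1].",
                 "airsig_config_error")
  }
  repetition_noise_sd <- check_number(repetition_noise_sd, "repetition_noise_sd", min = 0)
  session_shift_sd <- check_number(session_shift_sd, "session_shift_sd", min = 0)
  dwell_sd <- check_number(dwell_sd, "dwell_sd", min = 0)
  n_harmonics <- check_count(n_harmonics, "n_harmonics")
  if (!is.null(missing) && !inherits(missing, "missing_index")) {
    abort_airsig("`missing` must be a missing_index or NULL.", "airsig_config_error")
  }
  structure(
    list(
      n_subjects = n_subjects, n_repetitions = n_repetitions,
      n_sessions = n_sessions, duration_steps = duration_steps,
      sampling_interval_ms = as.numeric(sampling_interval_ms),
      channel_informativeness = as.numeric(channel_informativeness),
      repetition_noise_sd = repetition_noise_sd,
      session_shift_sd = session_shift_sd,
      dwell_steps = dwell_steps, dwell_sd = dwell_sd,
      n_harmonics = n_harmonics,
      jitter_length = check_flag(jitter_length, "jitter_length"),
      missing = missing, seed = check_count(seed, "seed", min = 0L)
    ),
    class = "generator_config"
  )
}

# A unit-variance band-limited trajectory: sum of `k` sinusoids with random
# frequencies below the Nyquist limit, random phases and Gaussian amplitudes,
# rescaled to unit variance. Sampled on 1..n with time step dt (seconds).
band_limited_trajectory <- function(n, dt, k) {
  nyquist <- 1 / (2 * dt)
  freqs <- runif(k, 0.05, min(1.0, 0.9 * nyquist))
  phases <- runif(k, 0, 2 * pi)
  amps <- rnorm(k)
  t <- seq_len(n) * dt
  x <- rowSums(vapply(
    seq_len(k),
    function(i) amps[i] * sin(2 * pi * freqs[i] * t + phases[i]),
    numeric(n)
  ))
  s <- sqrt(sum(amps^2) / 2)
  if (s > 0) x / s else x
}

subject_latent <- function(config, subject) {
  with_seed(derive_seed(config$seed, subject, 0L, 0L), {
    dt <- mean(config$sampling_interval_ms) / 1000
    n <- ceiling(config$duration_steps * 1.1) + 1L
    latent <- vapply(
      seq_len(9L),
      function(ch) band_limited_trajectory(n, dt, config$n_harmonics),
      numeric(n)
    )
    shift <- rnorm(9L, sd = config$session_shift_sd)
    list(latent = latent, session_shift = shift)
  })
}

generate_record <- function(config, subject, round, session, latent, device) {
  with_seed(derive_seed(config$seed, subject, round, session), {
    n_nominal <- config$duration_steps
    n <- if (config$jitter_length) {
      lo <- max(2L * config$dwell_steps + 1L, ceiling(n_nominal * 0.9))
      hi <- floor(n_nominal * 1.1)
      sample(seq.int(lo, hi), 1L)
    } else {
      n_nominal
    }
    interval <- runif(1, config$sampling_interval_ms[1], config$sampling_interval_ms[2])
    dt <- interval / 1000
    inf <- config$channel_informativeness
    vals <- matrix(0, n, 9L, dimnames = list(NULL, channel_schema()$names))
    for (ch in seq_len(9L)) {
      noise_traj <- band_limited_trajectory(n, dt, config$n_harmonics)
      x <- sqrt(inf[ch]) * latent$latent[seq_len(n), ch] +
        sqrt(1 - inf[ch]) * noise_traj
      x <- x + rnorm(n, sd = config$repetition_noise_sd)
      if (session == 2L) x <- x + latent$session_shift[ch]
      vals[, ch] <- x
    }
    if (config$dwell_steps > 0L) {
      d <- config$dwell_steps
      vals[seq_len(d), ] <- rnorm(d * 9L, sd = config$dwell_sd)
      vals[seq.int(n - d + 1L, n), ] <- rnorm(d * 9L, sd = config$dwell_sd)
    }
    signature_record(vals, sprintf("S%03d", subject), round, session, device,
                     interval)
  })
}

#' Generate a synthetic in-air signature corpus
#'
#' @param config A [generator_config()].
#' @param device `"phone"` or `"smartwatch"`.
#' @return A [signature_dataset()] with `n_subjects * n_repetitions` records
#'   (minus any entries listed in `config$missing`). The same config and
#'   seed always produce the identical corpus.
#' @examples
#' ds <- generate_dataset(generator_config(3, duration_steps = 40, seed = 7),
#'                        "smartwatch")
#' length(ds)
#' @export
generate_dataset <- function(config, device = "phone") {
  stopifnot(inherits(config, "generator_config"))
  device <- check_device(device)
  records <- vector("list", config$n_subjects * config$n_repetitions)
  k <- 0L
  for (subject in seq_len(config$n_subjects)) {
    latent <- subject_latent(config, subject)
    for (round in seq_len(config$n_repetitions)) {
      session <- if (config$n_sessions == 1L) {
        1L
      } else if (round <= ceiling(config$n_repetitions / 2)) 1L else 2L
      k <- k + 1L
      records[[k]] <- generate_record(config, subject, round, session, latent, device)
    }
  }
  ds <- signature_dataset(
    records, device,
    provenance = list(generator = "airsig synthetic", seed = config$seed,
                      n_subjects = config$n_subjects,
                      n_repetitions = config$n_repetitions)
  )
  if (!is.null(config$missing)) ds <- apply_missing(ds, config$missing)
  ds
}

#' Remove the records listed in a missing-record index
#'
#' @param dataset A [signature_dataset()].
#' @param missing A [missing_index()]; participant indices refer to positions
#'   in the sorted unique subject list.
#' @return The dataset without the listed records; the count drops by exactly
#'   `nrow(missing)`.
#' @export
apply_missing <- function(dataset, missing) {
  stopifnot(inherits(dataset, "signature_dataset"),
            inherits(missing, "missing_index"))
  subjects <- dataset_subjects(dataset)
  keys <- vapply(dataset$records, record_key, character(1))
  drop <- integer(0)
  for (i in seq_len(nrow(missing))) {
    p <- missing$participant_index[i]
    if (p > length(subjects)) {
      abort_airsig(
        sprintf("Missing-index entry %d references absent participant %d.", i, p),
        "airsig_lookup_error"
      )
    }
    key <- sprintf("%s_%d_%d", subjects[p], missing$signature_index[i],
                   missing$section[i])
    j <- match(key, keys)
    if (is.na(j)) {
      abort_airsig(
        sprintf("Missing-index entry %d (%s) matches no record.", i, key),
        "airsig_lookup_error"
      )
    }
    drop <- c(drop, j)
  }
  if (anyDuplicated(drop)) {
    abort_airsig("Missing-index entries reference the same record twice.",
                 "airsig_lookup_error")
  }
  keep <- setdiff(seq_along(dataset$records), drop)
  subset_dataset(dataset, keep,
                 provenance_note = sprintf("%d records removed by missing index", length(drop)))
}

#' Ground-truth discriminability ranking of the generator's channels
#'
#' Ranks channels by their configured informativeness (the share of variance
#' carried by the subject latent). Used as ground truth when testing whether
#' attribution methods recover the channels that actually discriminate
#' subjects. Ties share the minimum rank.
#'
#' @param config A [generator_config()].
#' @return Integer 9-vector of ranks (1 = most discriminative).
#' @export
informativeness_oracle <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  x <- config$channel_informativeness
  r <- rank(-x, ties.method = "min")
  setNames(as.integer(r), channel_schema()$names)
}
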