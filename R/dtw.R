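# Dynamic time warping with accumulated cost matrix and warping path, the
# per-subject relative average DTW statistic, and the
# time/frequency/complexity descriptor set.

#' Dynamic time warping distance between two sequences
#'
#' Builds the accumulated cost matrix `D` with `D[0,0] = 0` and the rest of
#' the first row and column at `+Inf`; each interior cell adds the local cost
#' `|a_i - b_j|` (or its square) to the minimum of the three predecessor
#' cells (diagonal, left, below), each scaled by a tuning coefficient. The
#' distance is the final cell; the warping path is recovered by traceback
#' with a deterministic tie-break (diagonal, then vertical, then horizontal).
#'
#' @param a,b Numeric sequences (length >= 1, finite values).
#' @param weights Length-3 step coefficients `(diagonal, left, vertical)`;
#'   default `c(1, 1, 1)`.
#' @param squared Use squared differences as local cost instead of absolute
#'   differences; default `FALSE`.
#' @return An object of class `dtw_result`: list with `distance`,
#'   `cost_matrix` (the `(n+1) x (m+1)` accumulated matrix) and `path` (a
#'   two-column matrix of index pairs from `(1,1)` to `(n,m)`).
#' @examples
#' d <- dtw(c(0, 1, 2), c(0, 2))
#' d$distance
#' @export
dtw <- function(a, b, weights = c(1, 1, 1), squared = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) {
    abort_airsig("DTW needs non-empty sequences.", "airsig_data_error")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort_airsig("DTW sequences must be finite.", "airsig_data_error")
  }
  if (length(weights) != 3L || any(weights <= 0)) {
    abort_airsig("`weights` must be 3 positive step coefficients.", "airsig_config_error")
  }
  D <- .dtw_cost_matrix(a, b, as.numeric(weights), isTRUE(squared))
  n <- length(a); m <- length(b)
  # traceback: prefer diagonal, then vertical (i-1, j), then horizontal
  path <- matrix(NA_integer_, n + m, 2L)
  i <- n; j <- m; k <- 0L
  while (i >= 1L && j >= 1L) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    cand <- c(
      diag = weights[1] * D[i, j],        # D is 1-indexed: D[i, j] == D_{i-1, j-1}
      vert = weights[3] * D[i, j + 1L],
      horiz = weights[2] * D[i + 1L, j]
    )
    step <- which.min(cand)  # which.min takes the first minimum: diag wins ties
    if (step == 1L) { i <- i - 1L; j <- j - 1L }
    else if (step == 2L) i <- i - 1L
    else j <- j - 1L
  }
  path <- path[seq_len(k), , drop = FALSE][k:1, , drop = FALSE]
  colnames(path) <- c("a", "b")
  structure(
    list(distance = D[n + 1L, m + 1L], cost_matrix = D, path = path),
    class = "dtw_result"
  )
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.6g, path length %d\n",
              x$distance, nrow(x$path)))
  invisible(x)
}

# Reduce a multichannel record to one sequence. "channel_mean" averages the
# channels at each time stamp (the same merge used by the corpus heatmap).
reduce_record <- function(record, reducer = "channel_mean") {
  if (is.function(reducer)) return(reducer(record$values))
  switch(reducer,
    channel_mean = rowMeans(record$values),
    channel_sum = rowSums(record$values),
    abort_airsig("Unknown reducer.", "airsig_config_error")
  )
}

#' Relative average DTW distance per subject
#'
#' For every subject, the mean DTW distance from each of that subject's
#' signatures to all signatures of *other* subjects, after reducing each
#' record to one sequence. Subjects whose signals sit far from everyone
#' else's stand out as above the global mean.
#'
#' @param dataset A [signature_dataset()] with at least 2 subjects.
#' @param reducer `"channel_mean"` (default), `"channel_sum"`, or a function
#'   `matrix -> numeric`.
#' @param weights,squared Passed to [dtw()].
#' @return An object of class `relative_dtw_report`: list with `per_subject`
#'   (named numeric), `global_mean`, and `above_mean_flags`.
#' @export
relative_average_dtw <- function(dataset, reducer = "channel_mean",
                                 weights = c(1, 1, 1), squared = FALSE) {
  stopifnot(inherits(dataset, "signature_dataset"))
  subj <- dataset_subject_ids(dataset)
  subjects <- sort(unique(subj))
  if (length(subjects) < 2L) {
    abort_airsig("Relative average DTW needs at least 2 subjects.", "airsig_data_error")
  }
  series <- lapply(dataset$records, reduce_record, reducer = reducer)
  n <- length(series)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- dtw(series[[i]], series[[j]], weights = weights, squared = squared)$distance
      dmat[i, j] <- d
      dmat[j, i] <- d
    }
  }
  per_subject <- vapply(subjects, function(s) {
    own <- which(subj == s)
    other <- which(subj != s)
    mean(dmat[own, other, drop = FALSE])
  }, numeric(1))
  global_mean <- mean(per_subject)
  structure(
    list(
      per_subject = per_subject,
      global_mean = global_mean,
      above_mean_flags = per_subject > global_mean
    ),
    class = "relative_dtw_report"
  )
}

#' @export
print.relative_dtw_report <- function(x, ...) {
  cat(sprintf("<relative_dtw_report> %d subjects, global mean %.6g (%d above)\n",
              length(x$per_subject), x$global_mean, sum(x$above_mean_flags)))
  invisible(x)
}

#' Time, frequency and complexity descriptors of a sequence
#'
#' Time domain: mean, standard deviation, root mean square. Frequency
#' domain: dominant frequency (Hz) and spectral centroid of the magnitude
#' spectrum (DC excluded). Complexity: permutation entropy of order 3,
#' normalized to `[0, 1]`, with ties broken by order of occurrence (a
#' constant sequence therefore has entropy 0 and white noise approaches 1).
#'
#' @param sequence Numeric vector, length >= 8.
#' @param sampling_interval_ms Sampling interval in milliseconds (converts
#'   spectral bins to Hz).
#' @return Named numeric vector: `mean`, `sd`, `rms`, `dominant_freq_hz`,
#'   `spectral_centroid_hz`, `permutation_entropy`.
#' @export
descriptors <- function(sequence, sampling_interval_ms = 220) {
  x <- as.numeric(sequence)
  if (length(x) < 8L) {
    abort_airsig("Descriptors need a sequence of length >= 8.", "airsig_data_error")
  }
  if (!all(is.finite(x))) {
    abort_airsig("Descriptor input must be finite.", "airsig_data_error")
  }
  fs <- 1000 / check_number(sampling_interval_ms, "sampling_interval_ms", min = 1e-9)
  n <- length(x)
  spec <- Mod(fft(x - mean(x)))
  half <- 2:(floor(n / 2) + 1L)        # positive frequencies, DC excluded
  freqs <- (half - 1L) * fs / n
  mag <- spec[half]
  dominant <- if (sum(mag) == 0) 0 else freqs[which.max(mag)]
  centroid <- if (sum(mag) == 0) 0 else sum(freqs * mag) / sum(mag)
  c(
    mean = mean(x),
    sd = sd(x),
    rms = sqrt(mean(x^2)),
    dominant_freq_hz = dominant,
    spectral_centroid_hz = centroid,
    permutation_entropy = permutation_entropy(x, order = 3L)
  )
}

# Normalized permutation entropy: distribution of ordinal patterns of
# `order` consecutive samples, entropy scaled by log(order!).
permutation_entropy <- function(x, order = 3L) {
  n <- length(x) - order + 1L
  patterns <- vapply(seq_len(n), function(i) {
    paste(order(x[i:(i + order - 1L)]), collapse = "")
  }, character(1))
  p <- table(patterns) / n
  h <- -sum(p * log(p))
  h / log(factorial(order))
}
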