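# Exhaustive coalition experiments and exact Shapley attribution.
#
# The characteristic function v(S) maps a channel coalition S to the
# validation accuracy of a classifier trained on exactly those channels; the
# empty coalition gets a baseline (chance accuracy by default). The Shapley
# value of channel i is the coalition-weighted average of its marginal
# contributions:
#   phi_i = sum over S not containing i of
#           |S|! (p - |S| - 1)! / p!  *  [v(S u {i}) - v(S)].

#' Enumerate all coalitions of p players
#'
#' @param p Number of players, 1..20 (2^p subsets are materialized).
#' @return List of [coalition()]s, ordered by size then lexicographically;
#'   the empty coalition comes first, the grand coalition last.
#' @examples
#' length(enumerate_coalitions(9))  # 512
#' @export
enumerate_coalitions <- function(p) {
  p <- check_count(p, "p")
  if (p > 20L) {
    abort_airsig("`p` must be at most 20 (2^p coalitions).", "airsig_config_error")
  }
  out <- list(coalition(integer(0), p))
  for (k in seq_len(p)) {
    sets <- combn(p, k, simplify = FALSE)
    out <- c(out, lapply(sets, coalition, p = p))
  }
  out
}

#' Characteristic map of a coalition game
#'
#' @param p Number of players.
#' @param values Named numeric vector: names are coalition keys (sorted
#'   member indices joined by `,`; `""` for the empty set), values the
#'   characteristic values.
#' @param baseline Value of the empty coalition.
#' @param provenance Optional metadata (model spec, seeds, split).
#' @return An object of class `characteristic_map`.
#' @export
characteristic_map <- function(p, values, baseline, provenance = list()) {
  p <- check_count(p, "p")
  baseline <- check_number(baseline, "baseline")
  if (!("" %in% names(values))) {
    values <- c(setNames(baseline, ""), values)
  }
  structure(
    list(p = p, values = values, baseline = baseline, provenance = provenance),
    class = "characteristic_map"
  )
}

#' @export
print.characteristic_map <- function(x, ...) {
  cat(sprintf("<characteristic_map> p=%d, %d/%d coalition values\n",
              x$p, length(x$values), 2^x$p))
  invisible(x)
}

char_value <- function(char, members) {
  i <- match(coalition_key(members), names(char$values))
  if (is.na(i)) NA_real_ else unname(char$values[i])
}

missing_coalitions <- function(char) {
  keys <- vapply(enumerate_coalitions(char$p),
                 function(co) coalition_key(co$members), character(1))
  setdiff(keys, names(char$values))
}

#' Train the full coalition grid and collect the characteristic map
#'
#' For every non-empty coalition: restrict the corpus to the member
#' channels, split it with one shared subject-stratified split, train one
#' classifier, and record its validation accuracy. The empty coalition is
#' assigned the baseline without training (`"chance"` = 1/n_classes,
#' `"zero"` = 0). One shared split and training seed isolate the channel
#' effect from sampling noise. Coalition results can be cached to disk as
#' JSON keyed by a config hash, so interrupted grids resume.
#'
#' @param dataset A [signature_dataset()].
#' @param spec_for Function `(n_channels, n_classes) -> `[model_spec()]
#'   building the per-coalition classifier.
#' @param config A [train_config()].
#' @param coalitions List of [coalition()]s; default all `2^p` for the
#'   dataset's channel count.
#' @param baseline `"chance"` or `"zero"`.
#' @param split A [split_spec()].
#' @param sample_weights Optional full-corpus record weights (subset per
#'   split), e.g. from [reweight_for_missing()].
#' @param cache_dir Optional directory for per-coalition JSON cache records.
#' @param verbose Print a coalition counter.
#' @return A [characteristic_map()] with `2^p` entries (baseline included).
#' @export
compute_characteristic <- function(dataset, spec_for, config = train_config(),
                                   coalitions = NULL,
                                   baseline = c("chance", "zero"),
                                   split = split_spec(),
                                   sample_weights = NULL,
                                   cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "signature_dataset"))
  baseline <- match.arg(baseline)
  p <- ncol(dataset$records[[1]]$values)
  if (is.null(coalitions)) coalitions <- enumerate_coalitions(p)
  n_classes <- length(dataset_subjects(dataset))
  base_value <- if (baseline == "chance") 1 / n_classes else 0
  parts <- split_dataset(dataset, split)
  w_train <- NULL
  if (!is.null(sample_weights)) {
    train_idx <- setdiff(seq_along(dataset$records), parts$test_indices)
    w_train <- sample_weights[train_idx]
  }
  cfg_hash <- rlang::hash(list(
    spec = spec_for(p, n_classes), config = config, split = split,
    baseline = baseline, n = length(dataset$records)
  ))
  values <- numeric(0)
  failed <- character(0)
  for (k in seq_along(coalitions)) {
    co <- coalitions[[k]]
    key <- coalition_key(co$members)
    if (verbose) {
      message(sprintf("coalition %d/%d {%s}", k, length(coalitions), key))
    }
    if (length(co$members) == 0L) {
      values <- c(values, setNames(base_value, ""))
      next
    }
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, sprintf("coalition_%s.json", gsub(",", "-", key)))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rec <- jsonlite::read_json(cache_file)
      if (identical(rec$hash, cfg_hash)) {
        values[[key]] <- as.numeric(rec$value)
        next
      }
    }
    acc <- tryCatch({
      tr <- extract_coalition(parts$train, co)
      te <- extract_coalition(parts$test, co)
      spec <- spec_for(length(co$members), n_classes)
      model <- build_model(spec, seed = config$seed)
      res <- train_model(model, tr, te, config, sample_weights = w_train)
      res$val_acc
    }, error = function(e) {
      failed <<- c(failed, sprintf("{%s}: %s", key, conditionMessage(e)))
      NA_real_
    })
    if (!is.na(acc)) {
      values[[key]] <- acc
      if (!is.null(cache_file)) {
        dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(list(hash = cfg_hash, coalition = co$members,
                                  value = acc),
                             cache_file, auto_unbox = TRUE, digits = NA)
      }
    }
  }
  if (length(failed) > 0L) {
    warning(sprintf("Characteristic map incomplete; %d coalition(s) failed:\n%s",
                    length(failed), paste(failed, collapse = "\n")), call. = FALSE)
  }
  characteristic_map(
    p, values, base_value,
    provenance = list(hash = cfg_hash, baseline = baseline,
                      split_seed = split$seed, train_seed = config$seed,
                      failed = failed)
  )
}

#' Exact Shapley values of a characteristic map
#'
#' Computes `phi_i` by direct summation over all subsets not containing `i`,
#' with the exact factorial weights accumulated in double precision, and the
#' empty set valued at the baseline. Efficiency holds by construction:
#' `sum(phi) = v(P) - v(empty)`.
#'
#' @param char A complete [characteristic_map()].
#' @return An object of class `shapley_report`: `phi` (named raw values),
#'   `shares` (percentages normalized to 100, see [normalize_shares()]),
#'   `grand_value`, `baseline`.
#' @export
shapley_values <- function(char) {
  stopifnot(inherits(char, "characteristic_map"))
  miss <- missing_coalitions(char)
  if (length(miss) > 0L) {
    abort_airsig(
      sprintf("Characteristic map incomplete; missing coalition(s): %s",
              paste(sprintf("{%s}", miss), collapse = ", ")),
      "airsig_incomplete_map_error"
    )
  }
  p <- char$p
  lfact <- lfactorial(0:p)
  phi <- numeric(p)
  others <- lapply(seq_len(p), function(i) setdiff(seq_len(p), i))
  for (i in seq_len(p)) {
    rest <- others[[i]]
    n_rest <- length(rest)
    for (mask in 0:(2^n_rest - 1)) {
      S <- rest[bitwAnd(mask, 2^(seq_len(n_rest) - 1)) > 0]
      s <- length(S)
      wgt <- exp(lfact[s + 1] + lfact[p - s] - lfact[p + 1])
      phi[i] <- phi[i] + wgt * (char_value(char, c(S, i)) - char_value(char, S))
    }
  }
  names(phi) <- if (p == 9L) channel_schema()$names else paste0("ch", seq_len(p))
  grand <- char_value(char, seq_len(p))
  report <- structure(
    list(phi = phi, shares = NULL, grand_value = grand,
         baseline = char$baseline, p = p),
    class = "shapley_report"
  )
  # percentage shares are undefined for degenerate games (non-positive
  # total); the signed phi vector stays the primary output, so the clipping
  # warning is raised by normalize_shares() only when called directly
  report$shares <- tryCatch(suppressWarnings(normalize_shares(report)),
                            error = function(e) rep(NA_real_, p))
  report
}

#' @export
print.shapley_report <- function(x, ...) {
  cat(sprintf("<shapley_report> p=%d, sum(phi)=%.6g = v(P) - v(0) = %.6g\n",
              x$p, sum(x$phi), x$grand_value - x$baseline))
  if (anyNA(x$shares)) {
    cat("  (degenerate game: percentage shares undefined)\n")
  }
  df <- data.frame(phi = round(x$phi, 6), share_pct = round(x$shares, 4))
  print(df)
  invisible(x)
}

#' Normalize Shapley values to percentage shares
#'
#' `share_i = 100 * phi_i / sum(phi)`. Negative raw values (possible with
#' noisy accuracies) are clipped at zero before renormalization, with a
#' warning; set `clip_negative = FALSE` to keep signed shares.
#'
#' @param report A `shapley_report` (or a bare numeric vector of phi).
#' @param clip_negative Clip negative contributions to 0 before
#'   renormalizing; default `TRUE`.
#' @return Numeric vector of percentages summing to 100.
#' @export
normalize_shares <- function(report, clip_negative = TRUE) {
  phi <- if (inherits(report, "shapley_report")) report$phi else report
  if (any(phi < 0) && clip_negative) {
    warning("Negative Shapley value(s) clipped to 0 for percentage shares.",
            call. = FALSE)
    phi <- pmax(phi, 0)
  }
  total <- sum(phi)
  if (total == 0) {
    abort_airsig("Cannot normalize shares: total Shapley value is zero.",
                 "airsig_data_error")
  }
  100 * phi / total
}

#' Dimension-compatibility curves
#'
#' For each coalition size `k` and each channel `i`, the mean characteristic
#' value over size-`k` coalitions containing `i` and over those excluding
#' `i`, plus the global mean-by-size curve. A channel whose exclusion drags
#' the mean down at every size is highly compatible with the rest.
#'
#' @param char A complete [characteristic_map()].
#' @return A list with `by_channel` (tibble: `channel`, `size`,
#'   `mean_including`, `mean_excluding`) and `overall` (tibble: `size`,
#'   `mean_value`, `n_coalitions`).
#' @export
compatibility_curves <- function(char) {
  stopifnot(inherits(char, "characteristic_map"))
  miss <- missing_coalitions(char)
  if (length(miss) > 0L) {
    abort_airsig("Characteristic map incomplete.", "airsig_incomplete_map_error")
  }
  p <- char$p
  coalitions <- enumerate_coalitions(p)
  sizes <- vapply(coalitions, function(co) length(co$members), integer(1))
  vals <- vapply(coalitions, function(co) char_value(char, co$members), numeric(1))
  chan_names <- if (p == 9L) channel_schema()$names else paste0("ch", seq_len(p))
  rows <- list()
  for (i in seq_len(p)) {
    has_i <- vapply(coalitions, function(co) i %in% co$members, logical(1))
    for (k in seq_len(p)) {
      at_k <- sizes == k
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = chan_names[i], size = k,
        mean_including = mean(vals[at_k & has_i]),
        mean_excluding = if (any(at_k & !has_i)) mean(vals[at_k & !has_i]) else NA_real_
      )
    }
  }
  overall <- tibble::tibble(
    size = seq_len(p),
    mean_value = vapply(seq_len(p), function(k) mean(vals[sizes == k]), numeric(1)),
    n_coalitions = vapply(seq_len(p), function(k) sum(sizes == k), integer(1))
  )
  list(by_channel = do.call(rbind, rows), overall = overall)
}
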