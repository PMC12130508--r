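# Internal helpers: error classes, seeded evaluation, small validators.

abort_airsig <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "airsig_error"), ...)
}

#' @noRd
check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_airsig(sprintf("`%s` must be TRUE or FALSE.", name), "airsig_config_error")
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort_airsig(
      sprintf("`%s` must be a single integer >= %d.", name, min),
      "airsig_config_error"
    )
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort_airsig(
      sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
      "airsig_config_error"
    )
  }
  as.numeric(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps record-level streams independent.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Derive a child seed below 2^31 from a base seed and integer keys, so each
# (record, stage) gets its own reproducible stream.
derive_seed <- function(seed, ...) {
  keys <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (k in keys) {
    h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}
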