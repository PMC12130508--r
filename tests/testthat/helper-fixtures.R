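# Fixtures built in code: separable toy corpora and small random records.

schema_names <- channel_schema()$names

# A corpus whose classes differ by a constant offset: trivially separable,
# so any functioning classifier can overfit it.
make_separable_dataset <- function(n_classes = 5, n_per_class = 4, L = 128,
                                   C = 3, sd = 0.1, seed = 1,
                                   device = "phone") {
  withr::with_seed(seed, {
    recs <- list()
    for (cls in seq_len(n_classes)) {
      for (i in seq_len(n_per_class)) {
        m <- matrix(rnorm(L * C, mean = cls, sd = sd), L, C,
                    dimnames = list(NULL, schema_names[seq_len(C)]))
        recs[[length(recs) + 1L]] <- signature_record(
          m, sprintf("S%03d", cls), i, 1L, device, 220
        )
      }
    }
    signature_dataset(recs, device)
  })
}

random_record <- function(L = 20, C = 9, subject = "S001", round = 1,
                          session = 1, device = "phone", seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(L * C), L, C,
                dimnames = list(NULL, schema_names[seq_len(C)]))
    signature_record(m, subject, round, session, device, 220)
  })
}

# Exhaustive warping-path oracle: minimum path cost over every admissible
# monotone path from (1,1) to (n,m) with steps (1,0), (0,1), (1,1).
# Independent of the dynamic-programming implementation.
dtw_bruteforce <- function(a, b) {
  n <- length(a); m <- length(b)
  recurse <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, recurse(i - 1, j - 1))
    if (i > 1) best <- min(best, recurse(i - 1, j))
    if (j > 1) best <- min(best, recurse(i, j - 1))
    cost + best
  }
  recurse(n, m)
}

# Permutation-average Shapley oracle: mean marginal contribution of each
# player over all p! orderings. Independent of the subset-sum formula.
shapley_permutation_oracle <- function(char) {
  p <- char$p
  perms <- perm_all(seq_len(p))
  phi <- numeric(p)
  lookup <- function(S) {
    if (length(S) == 0) return(char$baseline)
    unname(char$values[match(paste(sort(S), collapse = ","), names(char$values))])
  }
  for (perm in perms) {
    before <- integer(0)
    for (i in perm) {
      phi[i] <- phi[i] + lookup(c(before, i)) - lookup(before)
      before <- c(before, i)
    }
  }
  phi / length(perms)
}

perm_all <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perm_all(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# A random complete characteristic map on p players with values in [0, 1].
random_characteristic <- function(p, seed) {
  withr::with_seed(seed, {
    coals <- enumerate_coalitions(p)
    vals <- setNames(
      runif(length(coals)),
      vapply(coals, function(co) paste(co$members, collapse = ","), character(1))
    )
    baseline <- unname(vals[names(vals) == ""])
    characteristic_map(p, vals, baseline)
  })
}
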