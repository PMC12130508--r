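# Coalition enumeration, the characteristic experiment, exact Shapley
# attribution and the game-theoretic axioms.

test_that("coalition enumeration is complete and canonically ordered", {
  p3 <- enumerate_coalitions(3)
  expect_length(p3, 8)
  sizes <- vapply(p3, function(co) length(co$members), integer(1))
  expect_equal(sizes, c(0, 1, 1, 1, 2, 2, 2, 3))
  expect_equal(p3[[5]]$members, c(1L, 2L))

  p1 <- enumerate_coalitions(1)
  expect_length(p1, 2)
  expect_equal(p1[[1]]$members, integer(0))
  expect_equal(p1[[2]]$members, 1L)

  expect_error(enumerate_coalitions(21), class = "airsig_config_error")
  expect_error(coalition(c(1, 1)), class = "airsig_config_error")
  expect_error(coalition(10), class = "airsig_config_error")
})

test_that("a dummy player receives zero Shapley value", {
  # v depends only on whether player 1 is present; players 2 and 3 are dummies
  vals <- c()
  for (co in enumerate_coalitions(3)) {
    vals[paste(co$members, collapse = ",")] <- as.numeric(1 %in% co$members)
  }
  char <- characteristic_map(3, vals, baseline = 0)
  rep <- shapley_values(char)
  expect_equal(unname(rep$phi), c(1, 0, 0), tolerance = 1e-12)
})

test_that("symmetric players receive equal Shapley values", {
  # v(S) = |S intersect {1,2}| : players 1 and 2 interchangeable
  vals <- c()
  for (co in enumerate_coalitions(4)) {
    vals[paste(co$members, collapse = ",")] <- sum(co$members %in% c(1, 2)) / 2
  }
  char <- characteristic_map(4, vals, baseline = 0)
  rep <- shapley_values(char)
  expect_equal(rep$phi[[1]], rep$phi[[2]], tolerance = 1e-12)
  expect_equal(rep$phi[[3]], 0, tolerance = 1e-12)
})

test_that("efficiency holds exactly on random characteristic maps", {
  for (seed in 1:20) {
    p <- 2 + (seed %% 4)
    char <- random_characteristic(p, seed)
    rep <- shapley_values(char)
    expect_equal(sum(rep$phi), rep$grand_value - rep$baseline,
                 tolerance = 1e-9)
  }
})

test_that("Shapley values are additive over independent games", {
  for (seed in 1:10) {
    p <- 3 + (seed %% 3)
    v <- random_characteristic(p, seed)
    w <- random_characteristic(p, seed + 100)
    vw <- characteristic_map(
      p, v$values + w$values[match(names(v$values), names(w$values))],
      baseline = v$baseline + w$baseline
    )
    expect_equal(shapley_values(vw)$phi,
                 shapley_values(v)$phi + shapley_values(w)$phi,
                 tolerance = 1e-12)
  }
})

test_that("the subset-sum formula matches the permutation-average oracle", {
  for (seed in 1:12) {
    p <- 2 + (seed %% 4)  # p in 2..5
    char <- random_characteristic(p, seed)
    expect_equal(unname(shapley_values(char)$phi),
                 shapley_permutation_oracle(char),
                 tolerance = 1e-12)
  }
})

test_that("incomplete maps are refused with the missing coalitions listed", {
  vals <- setNames(c(0.5, 0.6), c("1", "2"))
  char <- characteristic_map(2, vals, baseline = 0.1)
  err <- expect_error(shapley_values(char),
                      class = "airsig_incomplete_map_error")
  expect_match(conditionMessage(err), "\\{1,2\\}")
})

test_that("percentage shares normalize to 100 with the documented policies", {
  equal <- setNames(rep(0.25, 9), channel_schema()$names)
  shares <- normalize_shares(equal)
  expect_equal(unname(shares), rep(100 / 9, 9))
  expect_equal(sum(shares), 100, tolerance = 1e-6)

  spike <- c(1, rep(0, 8))
  expect_equal(unname(normalize_shares(spike)), c(100, rep(0, 8)))

  expect_warning(s <- normalize_shares(c(0.5, -0.1, 0.6)), regexp = "clipped")
  expect_equal(sum(s), 100, tolerance = 1e-6)
  expect_equal(s[2], 0)
  signed <- normalize_shares(c(0.5, -0.1, 0.6), clip_negative = FALSE)
  expect_equal(sum(signed), 100, tolerance = 1e-6)
  expect_lt(signed[2], 0)

  expect_error(normalize_shares(rep(0, 4)), class = "airsig_data_error")
})

test_that("compatibility curves match the closed form for v(S) = |S|/p", {
  p <- 5
  vals <- c()
  for (co in enumerate_coalitions(p)) {
    vals[paste(co$members, collapse = ",")] <- length(co$members) / p
  }
  char <- characteristic_map(p, vals, baseline = 0)
  curves <- compatibility_curves(char)
  expect_equal(curves$by_channel$mean_including,
               curves$by_channel$size / p)
  expect_equal(curves$overall$mean_value, (1:p) / p)
  expect_equal(curves$overall$mean_value[p], 1)  # grand coalition
  expect_equal(curves$overall$n_coalitions, choose(p, 1:p))
})

test_that("each channel appears in exactly half the coalitions", {
  design <- coalition_design(9, "phone")
  expect_equal(nrow(design), 512)
  has_ch1 <- vapply(design$coalition, function(co) 1L %in% co$members, logical(1))
  expect_equal(sum(has_ch1), 256)
  expect_equal(sum(!has_ch1), 256)
})

test_that("the coalition experiment trains each non-empty cell once and caches", {
  ds <- extract_coalition(
    generate_dataset(
      generator_config(3, n_repetitions = 4, duration_steps = 24,
                       dwell_steps = 2, seed = 31,
                       channel_informativeness = c(0.9, 0.6, rep(0.3, 7))),
      "phone"
    ),
    coalition(1:2)
  )
  cache <- withr::local_tempdir()
  spec_for <- function(nc, k) model_spec("timecnn", 24, nc, k)
  cfg <- train_config("timecnn", epochs = 4, seed = 2)
  char <- compute_characteristic(ds, spec_for, cfg,
                                 split = split_spec(0.25, seed = 2),
                                 cache_dir = cache)
  expect_length(char$values, 4)  # 2^2 including the empty set
  expect_equal(char_values_baseline <- char$baseline, 1 / 3)
  expect_true(all(char$values >= 0 & char$values <= 1))
  expect_length(list.files(cache, pattern = "^coalition_.*json$"), 3)

  # cached rerun reproduces the same map without retraining (values pass
  # through a JSON round trip, so equality is to numeric tolerance)
  char2 <- compute_characteristic(ds, spec_for, cfg,
                                  split = split_spec(0.25, seed = 2),
                                  cache_dir = cache)
  expect_equal(char$values, char2$values, tolerance = 1e-12)

  # grand-coalition value is consistent with a direct training run
  parts <- split_dataset(ds, split_spec(0.25, seed = 2))
  res <- train_model(build_model(spec_for(2, 3), seed = cfg$seed),
                     parts$train, parts$test, cfg)
  expect_equal(unname(char$values[match("1,2", names(char$values))]),
               res$val_acc)
})

test_that("zero-baseline mode assigns 0 to the empty coalition", {
  ds <- extract_coalition(
    generate_dataset(
      generator_config(2, n_repetitions = 4, duration_steps = 24,
                       dwell_steps = 2, seed = 32),
      "phone"
    ),
    coalition(1)
  )
  char <- compute_characteristic(
    ds, function(nc, k) model_spec("timecnn", 24, nc, k),
    train_config("timecnn", epochs = 2, seed = 1),
    baseline = "zero", split = split_spec(0.25, seed = 1)
  )
  expect_equal(char$baseline, 0)
  expect_equal(unname(char$values[names(char$values) == ""]), 0)
})
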