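# Synthetic corpus generator: determinism, structure, missing pattern,
# session effect and discriminability control.

small_config <- function(seed = 7, ...) {
  generator_config(n_subjects = 4, duration_steps = 32, dwell_steps = 3,
                   seed = seed, ...)
}

test_that("corpus counts follow subjects x repetitions", {
  ds <- generate_dataset(small_config(), "phone")
  expect_equal(length(ds), 40)
  lens <- vapply(ds$records, function(r) nrow(r$values), integer(1))
  expect_true(all(lens >= 29 & lens <= 35))  # +/-10% jitter around 32
  fixed <- generate_dataset(small_config(jitter_length = FALSE), "phone")
  expect_true(all(vapply(fixed$records, function(r) nrow(r$values),
                         integer(1)) == 32))
})

test_that("same config and seed give byte-identical corpora", {
  a <- generate_dataset(small_config(), "phone")
  b <- generate_dataset(small_config(), "phone")
  expect_identical(
    lapply(a$records, function(r) r$values),
    lapply(b$records, function(r) r$values)
  )
  c <- generate_dataset(small_config(seed = 8), "phone")
  expect_false(identical(a$records[[1]]$values, c$records[[1]]$values))
})

test_that("record streams are keyed, so corpora nest across subject counts", {
  small <- generate_dataset(generator_config(2, duration_steps = 32,
                                             dwell_steps = 3, seed = 7), "phone")
  big <- generate_dataset(generator_config(5, duration_steps = 32,
                                           dwell_steps = 3, seed = 7), "phone")
  expect_identical(small$records[[1]]$values, big$records[[1]]$values)
  expect_identical(small$records[[20]]$values, big$records[[20]]$values)
})

test_that("rounds 1-5 map to session 1 and 6-10 to session 2", {
  ds <- generate_dataset(small_config(), "phone")
  for (r in ds$records) {
    expect_equal(r$session, if (r$round_index <= 5) 1L else 2L)
  }
})

test_that("the missing-record index removes exactly the listed records", {
  idx <- missing_index(c(2L, 4L), c(3L, 7L), c(1L, 2L))
  ds <- generate_dataset(small_config(), "phone")
  pruned <- apply_missing(ds, idx)
  expect_equal(length(pruned), 38)
  keys <- vapply(pruned$records, function(r) {
    sprintf("%s_%d_%d", r$subject_id, r$round_index, r$session)
  }, character(1))
  expect_false("S002_3_1" %in% keys)
  expect_false("S004_7_2" %in% keys)

  expect_error(apply_missing(ds, missing_index(9L, 1L, 1L)),
               class = "airsig_lookup_error")
  expect_error(apply_missing(ds, missing_index(1L, 6L, 1L)),  # round 6 is session 2
               class = "airsig_lookup_error")
})

test_that("the bundled phone missing pattern has 23 session-consistent entries", {
  idx <- phone_missing_index()
  expect_equal(nrow(idx), 23)
  expect_true(all(idx$section == ifelse(idx$signature_index <= 5, 1L, 2L)))
})

test_that("sampling intervals fall in the configured range", {
  ds <- generate_dataset(small_config(), "phone")
  iv <- vapply(ds$records, function(r) r$sampling_interval_ms, numeric(1))
  expect_true(all(iv >= 215 & iv <= 230))
  expect_gt(length(unique(iv)), 1)
})

test_that("session-2 offsets match the configured shift scale", {
  cfg <- generator_config(40, duration_steps = 96, dwell_steps = 0,
                          repetition_noise_sd = 0.01, session_shift_sd = 1.0,
                          channel_informativeness = rep(1, 9),
                          jitter_length = FALSE, seed = 21)
  ds <- generate_dataset(cfg, "phone")
  subj <- vapply(ds$records, function(r) r$subject_id, character(1))
  diffs <- c()
  for (s in unique(subj)) {
    recs <- ds$records[subj == s]
    sess <- vapply(recs, function(r) r$session, integer(1))
    m1 <- Reduce(`+`, lapply(recs[sess == 1], function(r) colMeans(r$values))) / sum(sess == 1)
    m2 <- Reduce(`+`, lapply(recs[sess == 2], function(r) colMeans(r$values))) / sum(sess == 2)
    diffs <- c(diffs, m2 - m1)
  }
  # 360 subject-channel differences, each ~N(0, 1): sd within 3 SE of 1
  expect_lt(abs(sd(diffs) - 1), 3 / sqrt(2 * (length(diffs) - 1)) + 0.1)

  flat <- generate_dataset(
    generator_config(10, duration_steps = 96, dwell_steps = 0,
                     repetition_noise_sd = 0.01, session_shift_sd = 0,
                     channel_informativeness = rep(1, 9),
                     jitter_length = FALSE, seed = 21), "phone")
  fsubj <- vapply(flat$records, function(r) r$subject_id, character(1))
  fdiffs <- c()
  for (s in unique(fsubj)) {
    recs <- flat$records[fsubj == s]
    sess <- vapply(recs, function(r) r$session, integer(1))
    m1 <- Reduce(`+`, lapply(recs[sess == 1], function(r) colMeans(r$values))) / sum(sess == 1)
    m2 <- Reduce(`+`, lapply(recs[sess == 2], function(r) colMeans(r$values))) / sum(sess == 2)
    fdiffs <- c(fdiffs, m2 - m1)
  }
  expect_lt(sd(fdiffs), 0.2)
})

test_that("an informative channel discriminates subjects, a noise channel does not", {
  cfg <- generator_config(10, duration_steps = 64, dwell_steps = 0,
                          repetition_noise_sd = 0.05,
                          channel_informativeness = c(0.95, rep(0, 8)),
                          jitter_length = FALSE, seed = 13)
  ds <- generate_dataset(cfg, "phone")
  subj <- vapply(ds$records, function(r) r$subject_id, character(1))
  nearest_centroid_acc <- function(channel) {
    X <- t(vapply(ds$records, function(r) r$values[, channel], numeric(64)))
    rounds <- vapply(ds$records, function(r) r$round_index, integer(1))
    train <- rounds <= 8
    centroids <- do.call(rbind, lapply(sort(unique(subj)), function(s) {
      colMeans(X[train & subj == s, , drop = FALSE])
    }))
    test_idx <- which(!train)
    pred <- vapply(test_idx, function(i) {
      d <- rowSums(sweep(centroids, 2L, X[i, ], "-")^2)
      sort(unique(subj))[which.min(d)]
    }, character(1))
    mean(pred == subj[test_idx])
  }
  acc_high <- nearest_centroid_acc(1)
  acc_low <- nearest_centroid_acc(5)
  n_test <- 20
  se <- sqrt(acc_high * (1 - acc_high) / n_test + 0.1 * 0.9 / n_test + 1e-6)
  expect_gt(acc_high - acc_low, 3 * se)
})

test_that("informativeness oracle ranks channels by configured share", {
  cfg1 <- small_config(channel_informativeness = c(1, rep(0, 8)))
  expect_equal(unname(informativeness_oracle(cfg1)[1]), 1L)
  expect_true(all(informativeness_oracle(cfg1)[-1] == 2L))
  cfg2 <- small_config(channel_informativeness = rep(0.4, 9))
  expect_true(all(informativeness_oracle(cfg2) == 1L))
  cfg3 <- small_config(channel_informativeness = c(0.9, 0.5, 0.1, rep(0, 6)))
  expect_equal(unname(informativeness_oracle(cfg3)[1:3]), c(1L, 2L, 3L))
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(3, duration_steps = 10, dwell_steps = 5),
               class = "airsig_config_error")
  expect_error(generator_config(3, repetition_noise_sd = -1),
               class = "airsig_config_error")
  expect_error(generator_config(3, channel_informativeness = rep(2, 9)),
               class = "airsig_config_error")
  expect_error(generator_config(0), class = "airsig_config_error")
})
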