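# DTW distance, cost matrix, warping path, relative average DTW and the
# descriptor set.

test_that("identical sequences have zero distance and a diagonal path", {
  a <- c(0.3, -1.2, 2.5, 0.0, 4.1)
  res <- dtw(a, a)
  expect_equal(res$distance, 0)
  expect_equal(res$path, cbind(a = 1:5, b = 1:5), ignore_attr = TRUE)
})

test_that("single-element sequences reduce to the local cost", {
  expect_equal(dtw(0, 5)$distance, 5)
  expect_equal(dtw(-2, 3)$distance, 5)
})

test_that("the cost matrix honours the stated initialization", {
  res <- dtw(c(1, 2), c(1, 3))
  D <- res$cost_matrix
  expect_equal(D[1, 1], 0)
  expect_true(all(is.infinite(D[1, -1])))
  expect_true(all(is.infinite(D[-1, 1])))
  expect_equal(D[2, 2], 0)            # |1 - 1| + D[0,0]
  expect_equal(res$distance, D[3, 3])
})

test_that("dtw is symmetric, non-negative, and respects step weights", {
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- rnorm(sample(2:8, 1))
      b <- rnorm(sample(2:8, 1))
      expect_equal(dtw(a, b)$distance, dtw(b, a)$distance)
      expect_gte(dtw(a, b)$distance, 0)
    }
  })
  # heavy off-diagonal weights force the diagonal
  a <- c(0, 1, 2, 3)
  b <- c(0, 1, 2, 3) + 0.1
  res <- dtw(a, b, weights = c(1, 100, 100))
  expect_equal(res$path, cbind(a = 1:4, b = 1:4), ignore_attr = TRUE)
})

test_that("warping paths are valid monotone paths with admissible steps", {
  withr::with_seed(7, {
    for (i in 1:25) {
      a <- rnorm(sample(2:10, 1))
      b <- rnorm(sample(2:10, 1))
      p <- dtw(a, b)$path
      expect_equal(p[1, ], c(a = 1, b = 1), ignore_attr = TRUE)
      expect_equal(p[nrow(p), ], c(a = length(a), b = length(b)),
                   ignore_attr = TRUE)
      steps <- diff(p)
      expect_true(all(steps >= 0 & steps <= 1))
      expect_true(all(rowSums(steps) >= 1))
    }
  })
})

test_that("squared-cost mode squares the local differences", {
  expect_equal(dtw(0, 3, squared = TRUE)$distance, 9)
  expect_equal(dtw(c(0, 0), c(2, 2), squared = TRUE)$distance, 8)
})

test_that("empty or non-finite input is rejected", {
  expect_error(dtw(numeric(0), 1), class = "airsig_data_error")
  expect_error(dtw(c(1, NA), 1), class = "airsig_data_error")
  expect_error(dtw(c(1, Inf), 1), class = "airsig_data_error")
})

test_that("relative average DTW is zero for identical signals and matches a naive loop", {
  m <- matrix(rep(sin(seq(0, 3, length.out = 20)), 9), 20, 9,
              dimnames = list(NULL, schema_names))
  recs <- list()
  for (s in 1:3) {
    for (k in 1:2) {
      recs[[length(recs) + 1L]] <- signature_record(
        m, sprintf("S%03d", s), k, 1, "phone", 220)
    }
  }
  same <- signature_dataset(recs, "phone")
  rep0 <- relative_average_dtw(same)
  expect_true(all(rep0$per_subject == 0))
  expect_equal(rep0$global_mean, 0)

  withr::with_seed(11, {
    recs <- list()
    for (s in 1:4) {
      for (k in 1:3) {
        v <- matrix(rnorm(15 * 9, mean = s), 15, 9,
                    dimnames = list(NULL, schema_names))
        recs[[length(recs) + 1L]] <- signature_record(
          v, sprintf("S%03d", s), k, 1, "phone", 220)
      }
    }
  })
  ds <- signature_dataset(recs, "phone")
  report <- relative_average_dtw(ds)
  # naive O(N^2) recomputation
  subj <- vapply(ds$records, function(r) r$subject_id, character(1))
  series <- lapply(ds$records, function(r) rowMeans(r$values))
  for (s in sort(unique(subj))) {
    vals <- c()
    for (i in which(subj == s)) {
      for (j in which(subj != s)) {
        vals <- c(vals, dtw(series[[i]], series[[j]])$distance)
      }
    }
    expect_equal(unname(report$per_subject[s]), mean(vals))
  }
  expect_equal(report$global_mean, mean(report$per_subject))
  expect_equal(report$above_mean_flags,
               report$per_subject > report$global_mean)
})

test_that("well-separated clusters give smaller within- than between-cluster DTW", {
  withr::with_seed(3, {
    low <- lapply(1:3, function(k) runif(12, 0, 0.5))
    high <- lapply(1:3, function(k) runif(12, 10, 10.5))
  })
  within <- c(
    sapply(1:2, function(i) dtw(low[[i]], low[[i + 1]])$distance),
    sapply(1:2, function(i) dtw(high[[i]], high[[i + 1]])$distance)
  )
  between <- unlist(lapply(low, function(a) {
    lapply(high, function(b) dtw(a, b)$distance)
  }))
  expect_true(max(within) < min(between))
})

test_that("relative DTW refuses a single-subject corpus", {
  recs <- list(random_record(seed = 1), random_record(seed = 2, round = 2))
  expect_error(relative_average_dtw(signature_dataset(recs, "phone")),
               class = "airsig_data_error")
})

test_that("descriptors handle constants, sinusoids and white noise", {
  d <- descriptors(rep(-2.5, 64), 220)
  expect_equal(unname(d["sd"]), 0)
  expect_equal(unname(d["rms"]), 2.5)
  expect_equal(unname(d["permutation_entropy"]), 0)

  # a pure sinusoid's dominant frequency lands within one spectral bin
  fs <- 1000 / 220
  n <- 256
  f0 <- 0.8
  x <- sin(2 * pi * f0 * (1:n) / fs)
  d2 <- descriptors(x, 220)
  expect_lt(abs(d2[["dominant_freq_hz"]] - f0), fs / n + 1e-9)
  expect_gt(d2[["spectral_centroid_hz"]], 0)

  # white noise has near-maximal permutation entropy
  pe <- vapply(1:20, function(seed) {
    withr::with_seed(seed, descriptors(rnorm(4096), 220)[["permutation_entropy"]])
  }, numeric(1))
  expect_true(all(abs(pe - 1) < 0.05))

  expect_error(descriptors(rnorm(5), 220), class = "airsig_data_error")
})
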