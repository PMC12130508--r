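# Model zoo: architecture conformance, probability contracts, determinism,
# chance-level sanity and the experiment designs.

toy_spec <- function(arch, L = 64, C = 3, K = 4, ...) {
  model_spec(arch, L, C, K, ...)
}

test_that("every architecture outputs probability vectors summing to 1", {
  withr::with_seed(5, {
    x <- array(rnorm(2 * 128 * 3), c(2, 128, 3))
  })
  for (arch in c("fcn", "mlp", "resnet", "encoder", "mcdcnn", "timecnn",
                 "inceptiontime")) {
    m <- build_model(model_spec(arch, 128, 3, 5), seed = 2)
    p <- predict(m, x)
    expect_equal(dim(p), c(2, 5))
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("MLP hidden layers are 732 units wide", {
  m <- build_model(toy_spec("mlp"), seed = 1)
  layout <- model_layout(m)
  hidden <- layout[layout$class == "layer_dense" & grepl("^hidden", layout$name), ]
  expect_equal(nrow(hidden), 3)
  expect_true(all(hidden$out_channels == 732))
})

test_that("MC-DCNN builds one branch per input channel plus a 732-unit head", {
  m <- build_model(model_spec("mcdcnn", 64, 9, 4), seed = 1)
  layout <- model_layout(m)
  branch_convs <- layout[grepl("^branch[0-9]+_conv1$", layout$name), ]
  expect_equal(nrow(branch_convs), 9)
  expect_true(all(branch_convs$out_channels == 8))
  expect_equal(layout$out_channels[layout$name == "hidden"], 732)
})

test_that("InceptionTime modules concatenate 5 convolution branches and 1 pool branch", {
  m <- build_model(toy_spec("inceptiontime"), seed = 1)
  layout <- model_layout(m)
  mod1 <- layout[grepl("^block1_module1_", layout$name), ]
  expect_equal(sum(grepl("_conv_k[0-9]+$", mod1$name)), 5)
  expect_equal(sum(mod1$class == "layer_pool"), 1)
  kernel_names <- sort(as.integer(sub(".*_conv_k", "", grep("_conv_k",
                                                            mod1$name, value = TRUE))))
  expect_equal(kernel_names, c(3, 5, 8, 11, 17))
  # residual connections: one shortcut per block
  expect_equal(sum(grepl("shortcut_conv", layout$name)), 2)
})

test_that("ResNet filters double 64 -> 128 -> 256 across blocks", {
  m <- build_model(toy_spec("resnet"), seed = 1)
  layout <- model_layout(m)
  for (b in 1:3) {
    convs <- layout[grepl(sprintf("^block%d_conv", b), layout$name), ]
    expect_equal(nrow(convs), 3)
    expect_true(all(convs$out_channels == 64 * 2^(b - 1)))
  }
})

test_that("FCN follows the (8,5,3)/(128,256,128) stage plan with a GAP head", {
  m <- build_model(toy_spec("fcn"), seed = 1)
  layout <- model_layout(m)
  convs <- layout[layout$class == "layer_conv1d", ]
  expect_equal(convs$out_channels, c(128L, 256L, 128L))
  expect_true("gap" %in% layout$name)
  expect_equal(sum(layout$class == "layer_batchnorm"), 3)
})

test_that("a pooling chain that exhausts the time axis names the stage", {
  err <- expect_error(build_model(model_spec("encoder", 50, 3, 4)),
                      class = "airsig_shape_error")
  expect_match(conditionMessage(err), "stage")
  err2 <- expect_error(build_model(model_spec("mcdcnn", 3, 3, 4)),
                       class = "airsig_shape_error")
  expect_match(conditionMessage(err2), "branch")
})

test_that("training is deterministic given the seed", {
  ds <- make_separable_dataset(n_classes = 3, n_per_class = 4, L = 32, C = 2)
  inp <- as_model_input(ds, 32)
  cfg <- train_config("fcn", epochs = 5, seed = 9)
  spec <- model_spec("fcn", 32, 2, 3, filters = c(4, 8, 4))
  r1 <- train_model(build_model(spec), inp, inp, cfg)
  r2 <- train_model(build_model(spec), inp, inp, cfg)
  expect_identical(r1$train_loss, r2$train_loss)
  expect_identical(r1$val_loss, r2$val_loss)
  r3 <- train_model(build_model(spec), inp, inp,
                    train_config("fcn", epochs = 5, seed = 10))
  expect_false(identical(r1$train_loss, r3$train_loss))
})

test_that("random labels yield chance-level validation accuracy", {
  withr::with_seed(17, {
    recs <- list()
    for (s in 1:4) {
      for (k in 1:10) {
        m <- matrix(rnorm(32 * 2), 32, 2,
                    dimnames = list(NULL, schema_names[1:2]))
        recs[[length(recs) + 1L]] <- signature_record(
          m, sprintf("S%03d", s), k, 1, "phone", 220)
      }
    }
  })
  ds <- signature_dataset(recs, "phone")
  parts <- split_dataset(ds, split_spec(test_fraction = 0.5, seed = 1))
  res <- train_model(
    build_model(model_spec("timecnn", 32, 2, 4)),
    parts$train, parts$test,
    train_config("timecnn", epochs = 20, seed = 1)
  )
  n_val <- length(parts$test)
  se <- sqrt(0.25 * 0.75 / n_val)
  expect_lt(abs(res$val_acc - 0.25), 3 * se + 1e-9)
})

test_that("a separable two-class toy is learned to perfection", {
  ds <- make_separable_dataset(n_classes = 2, n_per_class = 6, L = 32, C = 2)
  inp <- as_model_input(ds, 32)
  res <- train_model(
    build_model(model_spec("timecnn", 32, 2, 2)),
    inp, NULL,
    train_config("timecnn", epochs = 200, seed = 3, stop_at_train_acc = 1)
  )
  expect_equal(res$train_acc, 1)
})

test_that("train/val loss and accuracy curves have matching lengths and ranges", {
  ds <- make_separable_dataset(n_classes = 3, n_per_class = 4, L = 32, C = 2)
  parts <- split_dataset(ds, split_spec(test_fraction = 0.25, seed = 2))
  res <- train_model(
    build_model(model_spec("fcn", 32, 2, 3, filters = c(4, 8, 4))),
    parts$train, parts$test,
    train_config("fcn", epochs = 7, seed = 4)
  )
  expect_length(res$train_loss, 7)
  expect_length(res$val_loss, 7)
  expect_length(res$val_acc_curve, 7)
  expect_true(all(res$train_acc_curve >= 0 & res$train_acc_curve <= 1))
  expect_true(all(res$val_acc_curve >= 0 & res$val_acc_curve <= 1))
})

test_that("missing classes and weight mismatches are rejected", {
  ds <- make_separable_dataset(n_classes = 3, n_per_class = 3, L = 32, C = 2)
  inp <- as_model_input(ds, 32)
  spec <- model_spec("fcn", 32, 2, 4, filters = c(4, 8, 4))  # 4 classes, 3 present
  expect_error(
    train_model(build_model(spec), inp, NULL, train_config("fcn", epochs = 2)),
    class = "airsig_data_error"
  )
  spec3 <- model_spec("fcn", 32, 2, 3, filters = c(4, 8, 4))
  expect_error(
    train_model(build_model(spec3), inp, NULL, train_config("fcn", epochs = 2),
                sample_weights = c(1, 2)),
    class = "airsig_data_error"
  )
})

test_that("paper-default training configs reproduce the reference table", {
  expected_opt <- c(fcn = "adam", mlp = "adadelta", resnet = "adam",
                    encoder = "adam", mcdcnn = "sgd", timecnn = "adam",
                    inceptiontime = "adam")
  for (arch in names(expected_opt)) {
    cfg <- train_config(arch, paper_defaults = TRUE)
    expect_identical(cfg$optimizer, unname(expected_opt[arch]))
    expect_equal(cfg$learning_rate, 1e-5)
    expect_equal(cfg$epochs, 1500L)
  }
})

test_that("the model-selection design enumerates the full grid", {
  two <- model_selection_design()
  expect_equal(nrow(two), 140)
  one <- model_selection_design("smartwatch")
  expect_equal(nrow(one), 70)
  expect_equal(sum(two$view == "multivariate"), 14)
  expect_true(all(lengths(two$channels[two$view == "multivariate"]) == 9))
})

test_that("run_model_selection fills every cell of a reduced grid", {
  ds <- generate_dataset(
    generator_config(3, n_repetitions = 4, duration_steps = 24,
                     dwell_steps = 2, seed = 12,
                     channel_informativeness = rep(0.8, 9)),
    "smartwatch"
  )
  res <- run_model_selection(
    list(smartwatch = ds),
    config = train_config(epochs = 3, seed = 1),
    input_length = 24,
    split = split_spec(test_fraction = 0.25, seed = 1),
    architectures = "timecnn"
  )
  expect_equal(nrow(res), 10)  # 9 uni-variate + 1 multivariate, 1 model, 1 device
  expect_true(all(is.na(res$error)))
  expect_true(all(res$train_acc >= 0 & res$train_acc <= 1))
  expect_true(all(res$val_acc >= 0 & res$val_acc <= 1))
})
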