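# Construct a small dataset whose decimated time features form two separable
# clouds, so classical baselines can be checked quickly.
blob_dataset <- function(n_per_class = 24, seed = 51) {
  set.seed(seed)
  rows <- purrr::map(seq_len(2 * n_per_class), function(i) {
    cls <- if (i <= n_per_class) "F" else "N"
    mu <- if (cls == "F") 1 else -1
    tibble::tibble(
      example_id = sprintf("b%03d", i),
      record_id = sprintf("S%02d", (i - 1) %/% 6 + 1),
      group_index = i,
      label = factor(cls, levels = c("F", "N")),
      vas = if (cls == "F") 90 else 40,
      age = 20L + (i %% 8), gender = if (i %% 3 == 0) "female" else "male",
      signal = list(rnorm(1300, mean = mu, sd = 0.3)),
      spectrograms = list(array(rnorm(10 * 17 * 25, mean = mu, sd = 0.3),
                                c(10, 17, 25)))
    )
  })
  dplyr::bind_rows(rows)
}

test_that("baseline configs default to the reference hyperparameters", {
  svm <- baseline_config("svm")
  expect_equal(svm[c("cost", "gamma", "kernel")],
               list(cost = 0.1, gamma = 10, kernel = "sigmoid"))
  rf <- baseline_config("rf")
  expect_equal(rf[c("num_trees", "rf_seed", "max_depth")],
               list(num_trees = 100, rf_seed = 40, max_depth = 100))
  cnn <- baseline_config("cnn")
  expect_equal(cnn$n_layers, 18)
  expect_equal(cnn$kernel, 3)
  expect_equal(cnn$feature_source, "spec_image")
  lstm <- baseline_config("lstm")
  expect_equal(lstm[c("depth", "hidden", "input_dim")],
               list(depth = 6, hidden = 64, input_dim = 64))
  expect_false(lstm$bidirectional)
  expect_true(baseline_config("bilstm")$bidirectional)
  # overrides flow through
  expect_equal(baseline_config("svm", kernel = "radial")$kernel, "radial")
})

test_that("an SVM with an RBF override separates two Gaussian blobs", {
  ds <- blob_dataset()
  parts <- split_dataset(ds, split_spec(train_fraction = 0.8, seed = 1))
  fit <- fit_baseline(parts$train, baseline_config("svm", kernel = "radial",
                                                   gamma = 1 / 325, cost = 1))
  ev <- evaluate(predict(fit, parts$test), parts$test$label)
  expect_equal(ev$accuracy, 100)
})

test_that("the random forest is seeded-deterministic and learns the blobs", {
  ds <- blob_dataset(seed = 52)
  parts <- split_dataset(ds, split_spec(train_fraction = 0.8, seed = 2))
  f1 <- fit_baseline(parts$train, baseline_config("rf"))
  f2 <- fit_baseline(parts$train, baseline_config("rf"))
  expect_identical(predict(f1, parts$test), predict(f2, parts$test))
  expect_equal(evaluate(predict(f1, parts$test), parts$test$label)$accuracy, 100)
})

test_that("baselines reject single-class training data", {
  ds <- blob_dataset()
  oneclass <- ds[ds$label == "F", ]
  expect_error(fit_baseline(oneclass, baseline_config("svm")),
               class = "fatiguecg_invalid_input")
  expect_error(fit_baseline(oneclass, baseline_config("rf")),
               class = "fatiguecg_invalid_input")
})

test_that("the CNN instantiates 18 weighted layers with 3x3 kernels", {
  ns <- asNamespace("fatiguecg")
  ctx <- ns$nn_ctx()
  cfg <- baseline_config("cnn")
  x <- array(rnorm(2 * 10 * 17 * 25), c(2, 10, 17, 25))
  res <- ns$fwd_cnn18(ctx, cfg, x)
  conv_w <- grep("^cnn\\.c\\d+\\.W$", ls(ctx$pars), value = TRUE)
  expect_length(conv_w, 17)                 # + 1 linear head = 18 weighted
  expect_true("cnn.head.W" %in% ls(ctx$pars))
  for (nm in conv_w) {
    W <- get(nm, envir = ctx$pars)
    expect_equal(nrow(W) %% 9, 0)           # every kernel is 3 x 3
  }
  expect_true(all(is.finite(res$logits)))
})

test_that("the bidirectional flag increases recurrent parameter count", {
  ns <- asNamespace("fatiguecg")
  count_pars <- function(bidir) {
    ctx <- ns$nn_ctx()
    cfg <- baseline_config(if (bidir) "bilstm" else "lstm", depth = 2, hidden = 8)
    x <- array(rnorm(2 * 20 * 64), c(2, 20, 64))
    ns$fwd_rnn_baseline(ctx, cfg, x)
    sum(vapply(ls(ctx$pars), function(n) length(get(n, envir = ctx$pars)),
               numeric(1)))
  }
  expect_gt(count_pars(TRUE), count_pars(FALSE))
})

test_that("neural baselines learn the separable blobs quickly", {
  ds <- blob_dataset(seed = 53)
  parts <- split_dataset(ds, split_spec(train_fraction = 0.8, seed = 3))
  for (m in c("cnn", "lstm")) {
    cfg <- baseline_config(m, seed = 7, epochs = 5,
                           channels = c(4, 8), depth = 2, hidden = 16)
    fit <- fit_baseline(parts$train, cfg)
    ev <- evaluate(predict(fit, parts$test), parts$test$label)
    expect_gt(ev$accuracy, 60)
    expect_equal(glance(fit)$method, m)
  }
})
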