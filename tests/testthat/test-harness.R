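test_that("splitting honors the 9:1 ratio and seeded determinism", {
  ds <- tibble::tibble(example_id = sprintf("e%03d", 1:100),
                       record_id = rep(sprintf("S%02d", 1:10), each = 10),
                       label = factor(rep(c("F", "N"), 50), levels = c("F", "N")))
  sp <- split_spec(seed = 5)
  parts <- split_dataset(ds, sp)
  expect_equal(nrow(parts$train), 90)
  expect_equal(nrow(parts$test), 10)
  expect_equal(nrow(dplyr::bind_rows(parts)), 100)
  parts2 <- split_dataset(ds, sp)
  expect_identical(parts$train$example_id, parts2$train$example_id)
  # subject-grouped: no subject id on both sides
  sg <- split_dataset(ds, split_spec(mode = "subject-grouped", seed = 2))
  expect_length(intersect(unique(sg$train$record_id), unique(sg$test$record_id)), 0)
  expect_gt(nrow(sg$test), 0)
  expect_error(split_spec(train_fraction = 0), class = "fatiguecg_config_error")
  expect_error(split_spec(train_fraction = 1.2), class = "fatiguecg_config_error")
})

test_that("evaluation metrics follow the confusion-count identities", {
  lab <- factor(rep(c("F", "N"), 10), levels = c("F", "N"))
  perfect <- evaluate(lab, lab)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 1)
  # degenerate all-N predictor on a balanced set
  allN <- evaluate(factor(rep("N", 20), levels = c("F", "N")), lab)
  expect_equal(allN$accuracy, 50)
  expect_equal(allN$f1, 0)
  expect_equal(allN$tp, 0)
  # hand-computed confusion counts
  p <- factor(c(rep("F", 50), rep("N", 50)), levels = c("F", "N"))
  y <- factor(c(rep("F", 45), rep("N", 5), rep("F", 5), rep("N", 45)),
              levels = c("F", "N"))
  ev <- evaluate(p, y)
  expect_equal(unlist(ev[, c("tp", "fp", "fn", "tn")]),
               c(tp = 45, fp = 5, fn = 5, tn = 45))
  expect_equal(ev$accuracy, 90)
  expect_equal(ev$f1, 0.9)
  expect_error(evaluate(p, y[1:10]), class = "fatiguecg_shape_error")
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(41)
  for (i in 1:200) {
    cts <- as.integer(rmultinom(1, sample(10:200, 1), prob = runif(4, 0.05, 1)))
    tp <- cts[1]; fp <- cts[2]; fn <- cts[3]; tn <- cts[4]
    p <- factor(c(rep("F", tp), rep("F", fp), rep("N", fn), rep("N", tn)),
                levels = c("F", "N"))
    y <- factor(c(rep("F", tp), rep("N", fp), rep("F", fn), rep("N", tn)),
                levels = c("F", "N"))
    ev <- evaluate(p, y)
    expect_equal(ev$accuracy, (tp + tn) / sum(cts) * 100)
    expect_equal(ev$f1, if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("training is reproducible and rejects degenerate inputs", {
  ds <- tiny_dataset(seed = 1, n_subjects = 4, duration_s = 20)
  cfg <- tiny_config(seed = 3)
  f1 <- fit_fatigue_model(ds, cfg, epochs = 2, batch_size = 4, val_fraction = 0)
  f2 <- fit_fatigue_model(ds, cfg, epochs = 2, batch_size = 4, val_fraction = 0)
  for (nm in ls(f1$ctx$pars)) {
    expect_identical(get(nm, envir = f1$ctx$pars), get(nm, envir = f2$ctx$pars))
  }
  expect_identical(f1$history, f2$history)
  # single-class training set is rejected
  oneclass <- ds[ds$label == "F", ]
  expect_error(fit_fatigue_model(oneclass, cfg), class = "fatiguecg_invalid_input")
  expect_error(fit_fatigue_model(ds[0, ], cfg), class = "fatiguecg_invalid_input")
})

test_that("tidy and glance expose training history and model summary", {
  ds <- tiny_dataset(seed = 1, n_subjects = 4, duration_s = 20)
  fit <- fit_fatigue_model(ds, tiny_config(seed = 4), epochs = 2, batch_size = 4,
                           val_fraction = 0)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_true(all(c("epoch", "train_loss") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$n_parameters, 0)
  expect_equal(gl$branches, "T+S+P")
  pr <- predict(fit, ds)
  expect_equal(nrow(pr), nrow(ds))
  expect_true(all(abs(pr$.pred_F + pr$.pred_N - 1) < 1e-6))
})

test_that("ablation configuration names parse into branch flags", {
  ns <- asNamespace("fatiguecg")
  expect_equal(ns$parse_ablation_flags("T+S+P"),
               list(use_T = TRUE, use_S = TRUE, use_P = TRUE))
  expect_equal(ns$parse_ablation_flags("S"),
               list(use_T = FALSE, use_S = TRUE, use_P = FALSE))
  expect_error(ns$parse_ablation_flags("X"), class = "fatiguecg_config_error")
})

test_that("a tiny ablation emits one labeled row per configuration", {
  ds <- tiny_dataset(seed = 2, n_subjects = 4, duration_s = 20)
  ab <- run_ablation(ds, configs = c("S", "T+S+P"),
                     split = split_spec(train_fraction = 0.75, seed = 1),
                     config = tiny_config(), epochs = 2, batch_size = 4, seed = 9)
  expect_equal(ab$model, c("S", "T+S+P"))
  expect_true(all(ab$accuracy >= 0 & ab$accuracy <= 100))
  expect_s3_class(tidy(ab), "tbl_df")
})
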