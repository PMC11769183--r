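# Dataset splitting, the training loop, evaluation metrics, and the
# six-configuration feature-branch ablation.

#' Train/test split specification
#'
#' @param train_fraction Fraction of examples assigned to training, in
#'   (0, 1\]; the default 0.9 gives the 9:1 split.
#' @param mode `"example-random"` (default; most literal reading of a 9:1
#'   example split) or `"subject-grouped"` (no subject contributes to both
#'   partitions; the leakage-safe alternative).
#' @param seed Split seed.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.9,
                       mode = c("example-random", "subject-grouped"),
                       seed = 1) {
  mode <- match.arg(mode)
  assert_that(is_number(train_fraction) && train_fraction > 0 && train_fraction <= 1,
              "train_fraction must lie in (0, 1]",
              class = "fatiguecg_config_error")
  structure(list(train_fraction = train_fraction, mode = mode, seed = seed),
            class = "split_spec")
}

#' Split a dataset into train and test partitions
#'
#' In example-random mode `round(train_fraction * n)` examples are sampled for
#' training. In subject-grouped mode whole subjects are assigned to one
#' partition until the training fraction is reached, so no subject's examples
#' appear on both sides.
#'
#' @param data A `fatigue_dataset` (>= 2 rows).
#' @param spec A [split_spec()].
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, spec = split_spec()) {
  assert_that(inherits(spec, "split_spec"), "spec must be a split_spec",
              class = "fatiguecg_config_error")
  n <- nrow(data)
  assert_that(n >= 2, "need at least 2 examples to split",
              class = "fatiguecg_invalid_input")
  if (spec$mode == "example-random") {
    n_train <- round(spec$train_fraction * n)
    idx <- with_seed(spec$seed, sample.int(n, n_train))
  } else {
    subjects <- unique(data$record_id)
    ord <- with_seed(spec$seed, sample(subjects))
    target <- round(spec$train_fraction * n)
    counts <- cumsum(table(data$record_id)[ord])
    k <- which(counts >= target)[1]
    if (is.na(k)) k <- length(ord)
    train_subj <- ord[seq_len(k)]
    if (k == length(ord) && spec$train_fraction < 1) {
      train_subj <- ord[seq_len(length(ord) - 1L)]   # keep test non-empty
    }
    idx <- which(data$record_id %in% train_subj)
  }
  list(train = data[sort(idx), ], test = data[setdiff(seq_len(n), idx), ])
}

#' Evaluate predictions against labels
#'
#' Accuracy (percent) and F1 with the fatigue class (F) as positive, plus the
#' confusion counts and macro-F1. `accuracy = (TP + TN) / n * 100`;
#' `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param predictions Factor/character vector of predicted labels (F/N).
#' @param labels True labels, same length.
#' @return A one-row tibble of class `fatigue_eval`: `accuracy`, `f1`,
#'   `macro_f1`, `tp`, `fp`, `fn`, `tn`, `n`.
#' @examples
#' evaluate(factor(c("F", "N", "F")), factor(c("F", "N", "N")))
#' @export
evaluate <- function(predictions, labels) {
  assert_that(length(predictions) == length(labels) && length(labels) >= 1,
              "predictions and labels must have equal positive length",
              class = "fatiguecg_shape_error")
  p <- factor(as.character(predictions), levels = c("F", "N"))
  y <- factor(as.character(labels), levels = c("F", "N"))
  assert_that(!anyNA(p) && !anyNA(y), "labels must be F or N",
              class = "fatiguecg_invalid_input")
  tp <- sum(p == "F" & y == "F"); fp <- sum(p == "F" & y == "N")
  fn <- sum(p == "N" & y == "F"); tn <- sum(p == "N" & y == "N")
  f1_pos <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1_neg <- if (2 * tn + fn + fp == 0) 0 else 2 * tn / (2 * tn + fn + fp)
  out <- tibble(accuracy = (tp + tn) / length(y) * 100,
                f1 = f1_pos, macro_f1 = (f1_pos + f1_neg) / 2,
                tp = tp, fp = fp, fn = fn, tn = tn, n = length(y))
  class(out) <- c("fatigue_eval", class(out))
  out
}

# Snapshot / restore parameter environments (for early stopping).
snapshot_pars <- function(ctx) as.list(ctx$pars)
restore_pars <- function(ctx, snap) {
  for (nm in names(snap)) assign(nm, snap[[nm]], envir = ctx$pars)
}

#' Fit the hybrid fatigue classifier
#'
#' Minimizes the cross-entropy loss with Adam over minibatches (defaults:
#' learning rate 2e-3, batch 32, up to 12 epochs). A fraction of the training
#' examples is held out for early stopping on validation loss; the
#' best-validation parameters are restored at the end. Training is
#' deterministic for a fixed config seed.
#'
#' @param data A `fatigue_dataset` containing both classes.
#' @param config A [model_config()].
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_fraction Fraction of `data` held out for early stopping (0
#'   disables).
#' @param patience Epochs without validation-loss improvement before stopping.
#' @param verbose Print per-epoch progress.
#' @return A `fatigue_model` with a `history` tibble (epoch, train_loss,
#'   val_loss, val_accuracy).
#' @export
fit_fatigue_model <- function(data, config = model_config(), epochs = 12,
                              batch_size = 32, lr = 2e-3, val_fraction = 0.1,
                              patience = 3, verbose = FALSE) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  assert_that(nrow(data) >= 2, "training data must be non-empty (>= 2 examples)",
              class = "fatiguecg_invalid_input")
  assert_that(length(unique(data$label)) == 2,
              "training data must contain both classes",
              class = "fatiguecg_invalid_input")
  spec_dim <- dim(data$spectrograms[[1]])[2:3]
  model <- init_fatigue_model(config, spec_dim = spec_dim)
  ctx <- model$ctx
  n <- nrow(data)
  n_val <- if (val_fraction > 0 && n >= 12) max(2L, floor(val_fraction * n)) else 0L
  val_idx <- if (n_val > 0) {
    with_seed(derive_seed(config$seed, "valsplit"), sample.int(n, n_val))
  } else integer(0)
  tr <- if (n_val > 0) data[-val_idx, ] else data
  va <- if (n_val > 0) data[val_idx, ] else NULL
  state <- adam_state()
  history <- list()
  best <- list(loss = Inf, snap = NULL, epoch = 0L)
  stall <- 0L
  with_seed(derive_seed(config$seed, "trainloop"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(tr))
      losses <- c()
      for (b0 in seq(1, nrow(tr), by = batch_size)) {
        rows <- ord[b0:min(b0 + batch_size - 1, nrow(tr))]
        batch <- make_batch(tr[rows, ], config)
        nn_zero_grads(ctx)
        res <- forward_fatigue(ctx, config, batch, training = TRUE)
        res$backward()
        adam_step(ctx, state, lr = lr)
        losses <- c(losses, res$loss)
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(va)) {
        vb <- make_batch(va, config)
        vres <- forward_fatigue(ctx, config, vb, training = FALSE)
        val_loss <- vres$loss
        val_acc <- mean(max.col(vres$probs) == vb$y)
      }
      history[[ep]] <- tibble(epoch = ep, train_loss = mean(losses),
                              val_loss = val_loss, val_accuracy = val_acc)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                        ep, mean(losses), val_loss, val_acc))
      }
      if (!is.null(va)) {
        if (val_loss < best$loss - 1e-4) {
          best <- list(loss = val_loss, snap = snapshot_pars(ctx), epoch = ep)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
  })
  if (!is.null(best$snap)) restore_pars(ctx, best$snap)
  model$history <- bind_rows(history)
  model$best_epoch <- if (!is.null(best$snap)) best$epoch else nrow(model$history)
  model
}

#' Predict fatigue state for new examples
#'
#' @param object A fitted `fatigue_model`.
#' @param newdata A `fatigue_dataset`.
#' @param type `"prob"` (default; class probabilities plus the hard class) or
#'   `"class"`.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return A tibble with `.pred_F`, `.pred_N` and `.pred_class` (for
#'   `type = "prob"`), or a factor of predicted classes.
#' @export
predict.fatigue_model <- function(object, newdata, type = c("prob", "class"),
                                  batch_size = 64, ...) {
  type <- match.arg(type)
  probs <- matrix(0, nrow(newdata), 2)
  for (b0 in seq(1, nrow(newdata), by = batch_size)) {
    rows <- b0:min(b0 + batch_size - 1, nrow(newdata))
    batch <- make_batch(newdata[rows, ], object$config, with_labels = FALSE)
    res <- forward_fatigue(object$ctx, object$config, batch, training = FALSE)
    probs[rows, ] <- res$probs
  }
  cls <- factor(object$classes[max.col(probs)], levels = object$classes)
  if (type == "class") return(cls)
  tibble(.pred_F = probs[, 1], .pred_N = probs[, 2], .pred_class = cls)
}

# Parse an ablation configuration name like "T+S+P" into branch flags.
parse_ablation_flags <- function(name) {
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  assert_that(all(parts %in% c("T", "S", "P")) && length(parts) >= 1,
              sprintf("unknown ablation configuration '%s'", name),
              class = "fatiguecg_config_error")
  list(use_T = "T" %in% parts, use_S = "S" %in% parts, use_P = "P" %in% parts)
}

#' Run the six-configuration feature-branch ablation
#'
#' Trains the hybrid model under each feature-branch configuration (S, S+P, T,
#' T+S, T+P, T+S+P by default) on a shared train/test split, so the rows are
#' paired comparisons. Disabled branches provably do not influence a
#' configuration's output: their inputs are never read.
#'
#' @param data A `fatigue_dataset` with all three modalities.
#' @param configs Character vector of configuration names built from T, S, P
#'   joined by `+`.
#' @param split A [split_spec()] shared by every configuration.
#' @param config Base [model_config()]; ablation flags are overridden per row.
#' @param epochs,batch_size,lr Passed to [fit_fatigue_model()].
#' @param seed Seed controlling model init and training for every
#'   configuration.
#' @return A tibble of class `fatigue_ablation`: one row per configuration
#'   with the [evaluate()] metrics on the shared test set.
#' @export
run_ablation <- function(data,
                         configs = c("S", "S+P", "T", "T+S", "T+P", "T+S+P"),
                         split = split_spec(),
                         config = model_config(),
                         epochs = 12, batch_size = 32, lr = 2e-3,
                         seed = config$seed) {
  parts <- split_dataset(data, split)
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    flags <- parse_ablation_flags(configs[i])
    cfg <- config
    cfg$use_T <- flags$use_T; cfg$use_S <- flags$use_S; cfg$use_P <- flags$use_P
    cfg$seed <- seed
    fit <- fit_fatigue_model(parts$train, cfg, epochs = epochs,
                             batch_size = batch_size, lr = lr)
    preds <- predict(fit, parts$test, type = "class")
    ev <- evaluate(preds, parts$test$label)
    rows[[i]] <- mutate(ev, model = configs[i], seed = seed, .before = 1)
  }
  out <- bind_rows(rows)
  class(out) <- c("fatigue_ablation", class(out))
  out
}

#' Build the default synthetic benchmark dataset
#'
#' Generates a seeded cohort with the default class-separated RR parameters,
#' preprocesses it, and featurizes it into the labeled example dataset. This
#' is the standing benchmark used throughout the package's tests and examples.
#'
#' @param seed Cohort seed.
#' @param n_subjects,duration_s Cohort size and per-record duration (the
#'   default 300 s mirrors a five-minute resting ECG collection window).
#' @param ... Passed on to [generate_cohort()].
#' @return A `fatigue_dataset`.
#' @export
synthetic_benchmark <- function(seed = 1, n_subjects = 20, duration_s = 300, ...) {
  cohort <- generate_cohort(n_subjects = n_subjects, duration_s = duration_s,
                            seed = seed, ...)
  build_dataset(preprocess_cohort(cohort))
}
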