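# The five comparison models, runnable on the same featurized dataset as the
# hybrid classifier. SVM and random forest consume flattened 4x-decimated
# group time series; the CNN consumes the stacked spectrogram images; the
# LSTM/BiLSTM consume the group signal framed into 64-sample steps (matching
# their input dimension of 64).

#' Baseline configuration
#'
#' Returns the per-method hyperparameters, defaulting to the printed reference
#' settings: SVM with penalty C = 0.1, kernel influence gamma = 10 and a
#' sigmoid kernel; random forest with 100 trees, random seed 40 and maximum
#' depth 100; an 18-layer CNN with 3x3 kernels on spectrograms; LSTM/BiLSTM
#' with depth 6 and input/hidden dimension 64.
#'
#' @param method One of `"svm"`, `"rf"`, `"cnn"`, `"lstm"`, `"bilstm"`.
#' @param feature_source `"time"` (flattened, 4x-decimated group series),
#'   `"spec"` (flattened spectrograms), `"spec_image"` (stacked spectrogram
#'   images; CNN) or `"frames"` (64-sample frames; recurrent models).
#'   Defaults per method.
#' @param seed Training seed for the neural baselines.
#' @param ... Hyperparameter overrides (e.g. `kernel = "radial"`,
#'   `epochs = 10`).
#' @return A list of class `baseline_config`.
#' @examples
#' baseline_config("svm")[c("cost", "gamma", "kernel")]
#' @export
baseline_config <- function(method = c("svm", "rf", "cnn", "lstm", "bilstm"),
                            feature_source = NULL, seed = 1, ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    svm = list(cost = 0.1, gamma = 10, kernel = "sigmoid",
               feature_source = "time"),
    rf = list(num_trees = 100, rf_seed = 40, max_depth = 100,
              feature_source = "time"),
    cnn = list(n_layers = 18, kernel = 3, channels = c(8, 16),
               epochs = 12, batch_size = 32, lr = 1e-3,
               feature_source = "spec_image"),
    lstm = list(depth = 6, hidden = 64, input_dim = 64, bidirectional = FALSE,
                epochs = 20, batch_size = 32, lr = 1e-3,
                feature_source = "frames"),
    bilstm = list(depth = 6, hidden = 64, input_dim = 64, bidirectional = TRUE,
                  epochs = 20, batch_size = 32, lr = 1e-3,
                  feature_source = "frames"))
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  if (!is.null(feature_source)) defaults$feature_source <- feature_source
  structure(c(list(method = method, seed = seed), defaults),
            class = "baseline_config")
}

# Extract the configured feature representation from a dataset.
baseline_features <- function(data, config) {
  switch(config$feature_source,
    time = do.call(rbind, map(data$signal, function(x) x[seq(1, length(x), by = 4)])),
    spec = do.call(rbind, map(data$spectrograms, as.vector)),
    spec_image = {
      dm <- dim(data$spectrograms[[1]])
      arr <- array(0, dim = c(nrow(data), dm))
      for (i in seq_len(nrow(data))) arr[i, , , ] <- data$spectrograms[[i]]
      arr
    },
    frames = {
      Tn <- 1300 %/% config$input_dim
      arr <- array(0, dim = c(nrow(data), Tn, config$input_dim))
      for (i in seq_len(nrow(data))) {
        arr[i, , ] <- matrix(data$signal[[i]][seq_len(Tn * config$input_dim)],
                             Tn, config$input_dim, byrow = TRUE)
      }
      arr
    },
    abort(sprintf("unknown feature source '%s'", config$feature_source),
          class = "fatiguecg_config_error"))
}

# 18 weighted layers: 17 ELU convolutions (3x3) with two 2x2 max-pool stages,
# then global average pooling and a final linear layer.
fwd_cnn18 <- function(ctx, config, x) {
  x <- aperm(x, c(1, 3, 4, 2))      # (B, 10, F, T) -> channels-last (B, F, T, 10)
  ch <- config$channels
  plan <- c(rep(ch[1], 5), rep(ch[2], 12))
  pools <- c(5, 9)
  steps <- vector("list", 0)
  for (l in seq_len(config$n_layers - 1L)) {
    cv <- nn_conv2d_elu(ctx, sprintf("cnn.c%d", l), x, plan[l], config$kernel,
                        stride = 1, pad = config$kernel %/% 2)
    x <- cv$out
    steps[[length(steps) + 1]] <- list(type = "conv", cv = cv)
    if (l %in% pools) {
      pl <- nn_maxpool2(x)
      x <- pl$out
      steps[[length(steps) + 1]] <- list(type = "pool", pl = pl)
    }
  }
  gap <- nn_gap2d(x)
  head <- nn_linear(ctx, "cnn.head", gap$out, 2)
  list(logits = head$out, bwd = function(dlogits) {
    d <- gap$bwd(head$bwd(dlogits))
    for (s in rev(steps)) {
      d <- if (s$type == "pool") s$pl$bwd(d) else s$cv$bwd(d)
    }
    d
  })
}

# Stacked (bi)directional LSTM; depth 6, hidden 64 by default.
fwd_rnn_baseline <- function(ctx, config, x) {
  if (config$bidirectional) {
    lstm <- nn_bilstm(ctx, "rnn", x, config$hidden, layers = config$depth)
    feat <- lstm$final
    head <- nn_linear(ctx, "rnn.head", feat, 2)
    list(logits = head$out, bwd = function(dlogits) {
      dfinal <- head$bwd(dlogits)
      lstm$bwd(array(0, dim = dim(lstm$out)), dfinal)
    })
  } else {
    layers <- vector("list", config$depth)
    cur <- x
    for (l in seq_len(config$depth)) {
      layers[[l]] <- nn_lstm(ctx, sprintf("rnn.l%d", l), cur, config$hidden)
      cur <- layers[[l]]$out
    }
    Tn <- dim(cur)[2]
    feat <- matrix(cur[, Tn, ], dim(cur)[1], config$hidden)
    head <- nn_linear(ctx, "rnn.head", feat, 2)
    list(logits = head$out, bwd = function(dlogits) {
      dfinal <- head$bwd(dlogits)
      dseq <- array(0, dim = dim(cur))
      dseq[, Tn, ] <- dfinal
      for (l in rev(seq_len(config$depth))) dseq <- layers[[l]]$bwd(dseq)
      dseq
    })
  }
}

train_nn_baseline <- function(data, config, forward_fn, features) {
  ctx <- nn_ctx()
  y <- as.integer(data$label)
  with_seed(derive_seed(config$seed, "init"), {
    if (config$method == "cnn") {
      dummy <- features[1, , , , drop = FALSE]
    } else {
      dummy <- features[1, , , drop = FALSE]
    }
    forward_fn(ctx, config, dummy)
  })
  state <- adam_state()
  n <- nrow(data)
  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = config$batch_size)) {
        rows <- ord[b0:min(b0 + config$batch_size - 1, n)]
        xb <- if (config$method == "cnn") {
          features[rows, , , , drop = FALSE]
        } else {
          features[rows, , , drop = FALSE]
        }
        nn_zero_grads(ctx)
        res <- forward_fn(ctx, config, xb)
        ce <- nn_softmax_ce(res$logits, y[rows])
        res$bwd(ce$bwd())
        adam_step(ctx, state, lr = config$lr)
      }
    }
  })
  ctx
}

#' Fit a baseline classifier
#'
#' @param data A `fatigue_dataset` containing both classes.
#' @param config A [baseline_config()] (or a method name, which is promoted
#'   with default hyperparameters).
#' @return A fitted object of class `fatigue_baseline`.
#' @export
fit_baseline <- function(data, config = baseline_config("svm")) {
  if (is.character(config)) config <- baseline_config(config)
  assert_that(inherits(config, "baseline_config"), "config must be a baseline_config")
  assert_that(length(unique(data$label)) == 2,
              "training data must contain both classes",
              class = "fatiguecg_invalid_input")
  fitted <- switch(config$method,
    svm = {
      X <- baseline_features(data, config)
      e1071::svm(x = X, y = data$label, cost = config$cost,
                 gamma = config$gamma, kernel = config$kernel, scale = FALSE)
    },
    rf = {
      X <- baseline_features(data, config)
      df <- as.data.frame(X)
      df$.label <- data$label
      ranger::ranger(dependent.variable.name = ".label", data = df,
                     num.trees = config$num_trees, max.depth = config$max_depth,
                     seed = config$rf_seed)
    },
    cnn = train_nn_baseline(data, config, fwd_cnn18, baseline_features(data, config)),
    lstm = train_nn_baseline(data, config, fwd_rnn_baseline,
                             baseline_features(data, config)),
    bilstm = train_nn_baseline(data, config, fwd_rnn_baseline,
                               baseline_features(data, config)))
  structure(list(method = config$method, config = config, fitted = fitted,
                 classes = c("F", "N")),
            class = "fatigue_baseline")
}

#' Predict with a fitted baseline
#'
#' @param object A `fatigue_baseline`.
#' @param newdata A `fatigue_dataset`.
#' @param ... Unused.
#' @return Factor of predicted classes (levels F, N).
#' @export
predict.fatigue_baseline <- function(object, newdata, ...) {
  config <- object$config
  X <- baseline_features(newdata, config)
  cls <- switch(object$method,
    svm = predict(object$fitted, X),
    rf = predict(object$fitted, data = as.data.frame(X))$predictions,
    {
      ctx <- object$fitted
      fwd <- if (object$method == "cnn") fwd_cnn18 else fwd_rnn_baseline
      logits <- fwd(ctx, config, X)$logits
      factor(object$classes[max.col(nn_softmax(logits))], levels = object$classes)
    })
  factor(as.character(cls), levels = object$classes)
}

#' Train and evaluate every baseline on a shared split
#'
#' @param data A `fatigue_dataset`.
#' @param methods Baseline methods to run.
#' @param split A [split_spec()]; the same split is used for every method (and
#'   can be shared with the hybrid model for paired comparison).
#' @param seed Seed for the neural baselines.
#' @param ... Per-method overrides passed to [baseline_config()].
#' @return Tibble, one row per method, with [evaluate()] metrics.
#' @export
run_baselines <- function(data, methods = c("svm", "rf", "cnn", "lstm", "bilstm"),
                          split = split_spec(), seed = 1, ...) {
  parts <- split_dataset(data, split)
  rows <- map(methods, function(m) {
    cfg <- baseline_config(m, seed = seed, ...)
    fit <- fit_baseline(parts$train, cfg)
    ev <- evaluate(predict(fit, parts$test), parts$test$label)
    mutate(ev, method = m, .before = 1)
  })
  bind_rows(rows)
}
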