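# The hybrid fatigue classifier: a 1D ResNet+BiLSTM branch for the 1300-sample
# time series, a 2D ResNet+BiLSTM branch for the ten per-segment spectrogram
# images, a physiological encoder (100-dim age one-hot + learned gender
# embedding through a 6-layer fully connected net), and transformer-encoder
# fusion of the resulting d-dimensional tokens into a 2-class softmax.

#' Hybrid model configuration
#'
#' Architecture sizes and ablation flags. Defaults are deliberately small so
#' that full training runs complete in minutes on a single CPU core: time
#' branch of 4 residual blocks (two ELU convolutions each, stride-2
#' downsampling, channels 8-16-32-32, kernel 7 then 3) feeding a 2-layer
#' BiLSTM of hidden size 32; spectrogram branch of 3 residual blocks (channels
#' 4-8-16, 3x3 kernels) and the same BiLSTM shape; shared token dimension
#' d = 64; 2 transformer layers with 4 heads and feed-forward width 128; a
#' 6-layer fully connected physiological encoder of width 64. Every size is
#' configurable for larger budgets.
#'
#' @param d Shared token dimension (divisible by `n_heads`).
#' @param time_channels,time_kernels Channels and kernel sizes of the four 1D
#'   residual blocks.
#' @param spec_channels Channels of the three 2D residual blocks (3x3 kernels).
#' @param lstm_hidden,lstm_layers BiLSTM hidden size and depth per branch.
#' @param tf_layers,n_heads,d_ff Transformer encoder depth, head count and
#'   feed-forward width.
#' @param physio_width Width of the hidden fully connected physiological
#'   layers (depth is fixed at 6).
#' @param gender_dim Learned gender embedding dimension.
#' @param gender_vocab Recognized gender tokens.
#' @param dropout Dropout rate applied inside the transformer (0 disables).
#' @param use_T,use_S,use_P Ablation flags enabling the time-series,
#'   spectrogram and physiological branches; at least one must be on.
#' @param use_type_embedding Add a learned per-branch type embedding to each
#'   fusion token (the 3-token sequence carries no positional encoding
#'   otherwise, making fusion permutation-invariant).
#' @param seed Seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(d = 64,
                         time_channels = c(8, 16, 32, 32),
                         time_kernels = c(7, 3, 3, 3),
                         spec_channels = c(4, 8, 16),
                         lstm_hidden = 32, lstm_layers = 2,
                         tf_layers = 2, n_heads = 4, d_ff = 128,
                         physio_width = 64, gender_dim = 8,
                         gender_vocab = c("male", "female"),
                         dropout = 0,
                         use_T = TRUE, use_S = TRUE, use_P = TRUE,
                         use_type_embedding = TRUE,
                         seed = 42) {
  assert_that(use_T || use_S || use_P,
              "at least one of use_T, use_S, use_P must be enabled",
              class = "fatiguecg_config_error")
  assert_that(d %% n_heads == 0, "d must be divisible by n_heads",
              class = "fatiguecg_config_error")
  assert_that(length(time_channels) == length(time_kernels),
              "time_channels and time_kernels must have equal length",
              class = "fatiguecg_config_error")
  structure(list(d = d, time_channels = time_channels, time_kernels = time_kernels,
                 spec_channels = spec_channels, lstm_hidden = lstm_hidden,
                 lstm_layers = lstm_layers, tf_layers = tf_layers,
                 n_heads = n_heads, d_ff = d_ff, physio_width = physio_width,
                 gender_dim = gender_dim, gender_vocab = gender_vocab,
                 dropout = dropout, use_T = use_T, use_S = use_S, use_P = use_P,
                 use_type_embedding = use_type_embedding, seed = seed),
            class = "model_config")
}

# ---- residual blocks --------------------------------------------------------

rb1d <- function(ctx, name, x, c_out, k, stride) {
  pad <- k %/% 2
  c1 <- nn_conv1d_elu(ctx, paste0(name, ".c1"), x, c_out, k, stride = stride, pad = pad)
  c2 <- nn_conv1d(ctx, paste0(name, ".c2"), c1$out, c_out, k, stride = 1, pad = pad)
  proj <- dim(x)[3] != c_out || stride != 1
  sk <- if (proj) nn_conv1d(ctx, paste0(name, ".sk"), x, c_out, 1, stride = stride, pad = 0)
  merged <- c2$out + (if (proj) sk$out else x)
  e2 <- nn_elu(merged)
  list(out = e2$out, bwd = function(dout) {
    dm <- e2$bwd(dout)
    dx <- c1$bwd(c2$bwd(dm))
    dx + (if (proj) sk$bwd(dm) else dm)
  })
}

rb2d <- function(ctx, name, x, c_out, k, stride) {
  pad <- k %/% 2
  c1 <- nn_conv2d_elu(ctx, paste0(name, ".c1"), x, c_out, k, stride = stride, pad = pad)
  c2 <- nn_conv2d(ctx, paste0(name, ".c2"), c1$out, c_out, k, stride = 1, pad = pad)
  proj <- dim(x)[4] != c_out || stride != 1
  sk <- if (proj) nn_conv2d(ctx, paste0(name, ".sk"), x, c_out, 1, stride = stride, pad = 0)
  merged <- c2$out + (if (proj) sk$out else x)
  e2 <- nn_elu(merged)
  list(out = e2$out, bwd = function(dout) {
    dm <- e2$bwd(dout)
    dx <- c1$bwd(c2$bwd(dm))
    dx + (if (proj) sk$bwd(dm) else dm)
  })
}

# ---- branch encoders (internal forward passes) ------------------------------

fwd_time_branch <- function(ctx, config, x_time) {
  B <- nrow(x_time)
  assert_that(ncol(x_time) == 1300,
              sprintf("time branch expects 1300-sample inputs, got %d", ncol(x_time)),
              class = "fatiguecg_shape_error")
  x <- array(x_time, dim = c(B, 1300, 1))
  blocks <- vector("list", length(config$time_channels))
  for (i in seq_along(config$time_channels)) {
    blocks[[i]] <- rb1d(ctx, sprintf("time.b%d", i), x,
                        config$time_channels[i], config$time_kernels[i], stride = 2)
    x <- blocks[[i]]$out
  }
  lstm <- nn_bilstm(ctx, "time.lstm", x, config$lstm_hidden, config$lstm_layers)
  proj <- nn_linear(ctx, "time.proj", lstm$final, config$d)
  list(out = proj$out, bwd = function(dtok) {
    dfinal <- proj$bwd(dtok)
    dx <- lstm$bwd(array(0, dim = dim(lstm$out)), dfinal)
    for (i in rev(seq_along(blocks))) dx <- blocks[[i]]$bwd(dx)
    NULL
  })
}

fwd_spec_branch <- function(ctx, config, x_spec) {
  dm <- dim(x_spec)
  assert_that(length(dm) == 4 && dm[2] == 10,
              "spectrogram branch expects an array (batch, 10, n_freq, n_time)",
              class = "fatiguecg_shape_error")
  B <- dm[1]; Fq <- dm[3]; Tt <- dm[4]
  x <- x_spec
  dim(x) <- c(B * 10, Fq, Tt, 1)
  blocks <- vector("list", length(config$spec_channels))
  for (i in seq_along(config$spec_channels)) {
    blocks[[i]] <- rb2d(ctx, sprintf("spec.b%d", i), x,
                        config$spec_channels[i], 3, stride = 2)
    x <- blocks[[i]]$out
  }
  gap <- nn_gap2d(x)                                  # (B*10, C)
  Cc <- ncol(gap$out)
  seqx <- gap$out
  dim(seqx) <- c(B, 10, Cc)
  lstm <- nn_bilstm(ctx, "spec.lstm", seqx, config$lstm_hidden, config$lstm_layers)
  proj <- nn_linear(ctx, "spec.proj", lstm$final, config$d)
  list(out = proj$out, bwd = function(dtok) {
    dfinal <- proj$bwd(dtok)
    dseq <- lstm$bwd(array(0, dim = dim(lstm$out)), dfinal)
    dim(dseq) <- c(B * 10, Cc)
    dx <- gap$bwd(dseq)
    for (i in rev(seq_along(blocks))) dx <- blocks[[i]]$bwd(dx)
    NULL
  })
}

#' Encode an age as a 100-dimensional one-hot vector
#'
#' Dimension `age + 1` (0-based index equal to the age in years) is 1, all
#' others 0.
#'
#' @param age Integer vector of ages in \[0, 99\].
#' @return Binary matrix `length(age) x 100`.
#' @export
age_onehot <- function(age) {
  assert_that(all(is.finite(age)) && all(age == floor(age)) &&
                all(age >= 0 & age <= 99),
              "age must be an integer in [0, 99]",
              class = "fatiguecg_invalid_input")
  out <- matrix(0, length(age), 100)
  out[cbind(seq_along(age), as.integer(age) + 1L)] <- 1
  out
}

fwd_physio_branch <- function(ctx, config, age, gender) {
  gi <- match(gender, config$gender_vocab)
  assert_that(!anyNA(gi),
              paste0("unknown gender token; expected one of: ",
                     paste(config$gender_vocab, collapse = ", ")),
              class = "fatiguecg_invalid_input")
  onehot <- age_onehot(age)
  emb <- nn_embedding(ctx, "physio.gender", gi, length(config$gender_vocab),
                      config$gender_dim)
  x <- cbind(onehot, emb$out)
  widths <- c(rep(config$physio_width, 5), config$d)
  layers <- vector("list", 6)
  acts <- vector("list", 5)
  for (l in 1:6) {
    layers[[l]] <- nn_linear(ctx, sprintf("physio.fc%d", l), x, widths[l])
    x <- layers[[l]]$out
    if (l < 6) {
      acts[[l]] <- nn_elu(x)
      x <- acts[[l]]$out
    }
  }
  list(out = x, bwd = function(dtok) {
    d <- dtok
    for (l in 6:1) {
      if (l < 6) d <- acts[[l]]$bwd(d)
      d <- layers[[l]]$bwd(d)
    }
    emb$bwd(d[, 101:(100 + config$gender_dim), drop = FALSE])
    NULL
  })
}

# ---- fusion + full forward --------------------------------------------------

fwd_fuse <- function(ctx, config, tokens, branch_ids) {
  B <- nrow(tokens[[1]])
  Tn <- length(tokens)
  d <- config$d
  X <- array(0, dim = c(B, Tn, d))
  for (i in seq_len(Tn)) X[, i, ] <- tokens[[i]]
  if (config$use_type_embedding) {
    TE <- nn_param(ctx, "fuse.type", c(3, d), init = "normal")
    for (i in seq_len(Tn)) X[, i, ] <- X[, i, ] +
      matrix(TE[branch_ids[i], ], B, d, byrow = TRUE)
  }
  layers <- vector("list", config$tf_layers)
  for (l in seq_len(config$tf_layers)) {
    layers[[l]] <- nn_transformer_layer(ctx, sprintf("fuse.t%d", l), X,
                                        config$n_heads, config$d_ff, config$dropout)
    X <- layers[[l]]$out
  }
  pooled <- apply(X, c(1, 3), mean)
  if (Tn == 1) pooled <- matrix(X[, 1, ], B, d)
  head <- nn_linear(ctx, "fuse.head", pooled, 2)
  list(logits = head$out, bwd = function(dlogits) {
    dpool <- head$bwd(dlogits)
    dX <- array(0, dim = c(B, Tn, d))
    for (i in seq_len(Tn)) dX[, i, ] <- dpool / Tn
    for (l in rev(seq_len(config$tf_layers))) dX <- layers[[l]]$bwd(dX)
    if (config$use_type_embedding) {
      TE <- nn_param(ctx, "fuse.type", c(3, d))
      dTE <- array(0, dim = c(3, d))
      for (i in seq_len(Tn)) {
        dTE[branch_ids[i], ] <- dTE[branch_ids[i], ] + colSums(matrix(dX[, i, ], B, d))
      }
      g_add(ctx, "fuse.type", dTE)
    }
    lapply(seq_len(Tn), function(i) matrix(dX[, i, ], B, d))
  })
}

# Full forward pass over a batch list(x_time, x_spec, age, gender, y).
# Disabled branches never touch their inputs (ablation isolation).
forward_fatigue <- function(ctx, config, batch, training = FALSE) {
  ctx$training <- training
  branches <- list()
  ids <- integer(0)
  if (config$use_T) {
    branches <- c(branches, list(fwd_time_branch(ctx, config, batch$x_time)))
    ids <- c(ids, 1L)
  }
  if (config$use_S) {
    branches <- c(branches, list(fwd_spec_branch(ctx, config, batch$x_spec)))
    ids <- c(ids, 2L)
  }
  if (config$use_P) {
    branches <- c(branches, list(fwd_physio_branch(ctx, config, batch$age, batch$gender)))
    ids <- c(ids, 3L)
  }
  tokens <- map(branches, "out")
  fuse <- fwd_fuse(ctx, config, tokens, ids)
  probs <- nn_softmax(fuse$logits)
  res <- list(logits = fuse$logits, probs = probs)
  if (!is.null(batch$y)) {
    ce <- nn_softmax_ce(fuse$logits, batch$y)
    res$loss <- ce$loss
    res$backward <- function() {
      dtok <- fuse$bwd(ce$bwd())
      for (i in seq_along(branches)) branches[[i]]$bwd(dtok[[i]])
      invisible(NULL)
    }
  }
  res
}

#' Cross-entropy loss for class probabilities
#'
#' `L = -(1/N) * sum_q sum_r S_qr * log(P_qr)` with probabilities clipped at
#' 1e-12 before the log (the loss is undefined at an exact zero).
#'
#' @param probs Numeric matrix, one row of class probabilities per sample
#'   (rows must sum to 1 within 1e-6).
#' @param truth Ground truth: a one-hot indicator matrix of the same shape, or
#'   a vector of 1-based class indices / factor levels matching the columns.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy(matrix(c(0.5, 0.5), 1), 1)  # log(2)
#' @export
cross_entropy <- function(probs, truth) {
  assert_that(is.matrix(probs) && is.numeric(probs), "probs must be a numeric matrix",
              class = "fatiguecg_shape_error")
  assert_that(all(abs(rowSums(probs) - 1) < 1e-6),
              "each probability row must sum to 1 (within 1e-6)")
  if (is.matrix(truth)) {
    assert_that(all(dim(truth) == dim(probs)),
                "truth matrix must match the shape of probs",
                class = "fatiguecg_shape_error")
    assert_that(all(truth %in% c(0, 1)) && all(rowSums(truth) == 1),
                "truth rows must be one-hot")
    S <- truth
  } else {
    y <- if (is.factor(truth)) as.integer(truth) else as.integer(truth)
    assert_that(length(y) == nrow(probs), "truth length must equal nrow(probs)",
                class = "fatiguecg_shape_error")
    assert_that(all(y >= 1 & y <= ncol(probs)), "class indices out of range")
    S <- matrix(0, nrow(probs), ncol(probs))
    S[cbind(seq_along(y), y)] <- 1
  }
  # `+ 0` normalizes IEEE negative zero for the perfect-prediction case
  -mean(rowSums(S * log(pmax(probs, 1e-12)))) + 0
}

# ---- model object -----------------------------------------------------------

# Assemble batch arrays from dataset rows.
make_batch <- function(data, config, with_labels = TRUE) {
  B <- nrow(data)
  batch <- list()
  if (config$use_T) {
    batch$x_time <- do.call(rbind, data$signal)
  }
  if (config$use_S) {
    dm <- dim(data$spectrograms[[1]])
    arr <- array(0, dim = c(B, dm))
    for (i in seq_len(B)) arr[i, , , ] <- data$spectrograms[[i]]
    batch$x_spec <- arr
  }
  if (config$use_P) {
    batch$age <- data$age
    batch$gender <- data$gender
  }
  if (with_labels && "label" %in% names(data)) {
    batch$y <- as.integer(data$label)   # F = 1, N = 2
  }
  batch
}

# Initialize all parameters deterministically via a seeded dummy forward pass.
init_fatigue_model <- function(config, spec_dim = c(17, 25)) {
  ctx <- nn_ctx()
  dummy <- list(
    x_time = matrix(0, 1, 1300),
    x_spec = array(0, dim = c(1, 10, spec_dim[1], spec_dim[2])),
    age = 25L, gender = config$gender_vocab[1]
  )
  with_seed(config$seed, forward_fatigue(ctx, config, dummy, training = FALSE))
  structure(list(ctx = ctx, config = config, classes = c("F", "N"),
                 spec_dim = spec_dim, history = NULL),
            class = "fatigue_model")
}

#' Encode the time-series branch of a model
#'
#' @param model A `fatigue_model`.
#' @param signals Matrix (batch x 1300) or a list of 1300-sample vectors.
#' @return Token matrix (batch x d).
#' @export
encode_time_branch <- function(model, signals) {
  if (is.list(signals)) signals <- do.call(rbind, signals)
  if (is.null(dim(signals))) signals <- matrix(signals, 1)
  fwd_time_branch(model$ctx, model$config, signals)$out
}

#' Encode the spectrogram branch of a model
#'
#' @param model A `fatigue_model`.
#' @param images Array (batch x 10 x n_freq x n_time), or (10 x n_freq x
#'   n_time) for a single example.
#' @return Token matrix (batch x d).
#' @export
encode_spec_branch <- function(model, images) {
  if (length(dim(images)) == 3) {
    images <- array(images, dim = c(1, dim(images)))
  }
  fwd_spec_branch(model$ctx, model$config, images)$out
}

#' Encode the physiological branch of a model
#'
#' @param model A `fatigue_model`.
#' @param age Integer vector of ages in \[0, 99\].
#' @param gender Character vector of gender tokens.
#' @return Token matrix (batch x d).
#' @export
encode_physio <- function(model, age, gender) {
  fwd_physio_branch(model$ctx, model$config, age, gender)$out
}

#' Fuse branch tokens and classify
#'
#' Runs the transformer-encoder fusion over the supplied tokens (one per
#' enabled branch, in T, S, P order) and returns 2-class probabilities.
#'
#' @param model A `fatigue_model`.
#' @param tokens List of token matrices (batch x d), one per enabled branch.
#' @return Matrix (batch x 2) of class probabilities (columns F, N), each row
#'   summing to 1.
#' @export
fuse_and_classify <- function(model, tokens) {
  config <- model$config
  ids <- which(c(config$use_T, config$use_S, config$use_P))
  assert_that(length(tokens) == length(ids),
              sprintf("expected %d tokens for the enabled branches, got %d",
                      length(ids), length(tokens)),
              class = "fatiguecg_config_error")
  res <- fwd_fuse(model$ctx, config, tokens, ids)
  probs <- nn_softmax(res$logits)
  colnames(probs) <- model$classes
  probs
}
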