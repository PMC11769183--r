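# Minimal neural-network engine: dense/convolutional/recurrent/attention
# layers with explicit forward and backward passes over base-R arrays, plus
# Adam. Every forward primitive takes a context `ctx` (parameter and gradient
# environments, training flag) and returns `list(out, bwd)`, where `bwd(dout)`
# returns the input gradient and accumulates parameter gradients into
# `ctx$grads`. Parameters are created lazily on first use under the caller's
# RNG, so a seeded dummy forward pass initializes a model deterministically.

nn_ctx <- function() {
  list(pars = new.env(parent = emptyenv()),
       grads = new.env(parent = emptyenv()),
       training = FALSE)
}

nn_param <- function(ctx, name, dim, init = c("glorot", "zeros", "ones", "normal"),
                     gain = 1) {
  if (!exists(name, envir = ctx$pars, inherits = FALSE)) {
    init <- match.arg(init)
    n <- prod(dim)
    v <- switch(init,
      zeros = numeric(n),
      ones = rep(1, n),
      normal = rnorm(n, 0, 0.02 * gain),
      glorot = {
        fan_in <- dim[1]
        fan_out <- dim[length(dim)]
        r <- gain * sqrt(6 / (fan_in + fan_out))
        runif(n, -r, r)
      })
    assign(name, array(v, dim = dim), envir = ctx$pars)
  }
  get(name, envir = ctx$pars, inherits = FALSE)
}

g_add <- function(ctx, name, val) {
  if (exists(name, envir = ctx$grads, inherits = FALSE)) {
    assign(name, get(name, envir = ctx$grads) + val, envir = ctx$grads)
  } else {
    assign(name, val, envir = ctx$grads)
  }
  invisible(NULL)
}

nn_zero_grads <- function(ctx) {
  rm(list = ls(ctx$grads), envir = ctx$grads)
  invisible(NULL)
}

# ---- dense / pointwise ------------------------------------------------------

nn_linear <- function(ctx, name, x, d_out, use_bias = TRUE) {
  d_in <- ncol(x)
  W <- nn_param(ctx, paste0(name, ".W"), c(d_in, d_out))
  out <- x %*% W
  if (use_bias) {
    b <- nn_param(ctx, paste0(name, ".b"), c(1, d_out), init = "zeros")
    out <- sweep(out, 2, b, "+")
  }
  list(out = out, bwd = function(dout) {
    g_add(ctx, paste0(name, ".W"), crossprod(x, dout))
    if (use_bias) g_add(ctx, paste0(name, ".b"), matrix(colSums(dout), 1))
    dout %*% t(W)
  })
}

nn_elu <- function(x) {
  y <- cpp_elu_fwd(x)
  list(out = y, bwd = function(dout) cpp_elu_bwd_y(y, dout))
}

nn_dropout <- function(ctx, x, rate) {
  if (!ctx$training || rate <= 0) {
    return(list(out = x, bwd = function(dout) dout))
  }
  keep <- 1 - rate
  mask <- array((runif(length(x)) < keep) / keep, dim = dim(x) %||% length(x))
  list(out = x * mask, bwd = function(dout) dout * mask)
}

nn_embedding <- function(ctx, name, idx, vocab, dim) {
  W <- nn_param(ctx, paste0(name, ".W"), c(vocab, dim), init = "normal")
  out <- W[idx, , drop = FALSE]
  list(out = out, bwd = function(dout) {
    dW <- array(0, dim = c(vocab, dim))
    for (i in seq_along(idx)) dW[idx[i], ] <- dW[idx[i], ] + dout[i, ]
    g_add(ctx, paste0(name, ".W"), dW)
    NULL
  })
}

# ---- convolutions (im2col) --------------------------------------------------

# Cache of im2col index matrices keyed by geometry; an index of 0 marks a
# zero-padding tap handled inside the compiled gather/scatter.
.idx_cache <- new.env(parent = emptyenv())

conv1d_idx <- function(L, C, k, stride, pad) {
  key <- paste("1d", L, C, k, stride, pad)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  L_out <- (L + 2L * pad - k) %/% stride + 1L
  starts <- (0:(L_out - 1)) * stride
  idx <- matrix(0L, L_out, C * k)
  for (c in 0:(C - 1)) for (kk in 1:k) {
    t <- starts + kk - pad
    idx[, c * k + kk] <- ifelse(t >= 1 & t <= L, t + c * L, 0L)
  }
  .idx_cache[[key]] <- idx
  idx
}

# x: array (B, L, C), channels last. Weight (C*K, C_out), tap order: k
# fastest within channel. Padding is implicit (zero taps in the index).
nn_conv1d <- function(ctx, name, x, c_out, k, stride = 1, pad = 0) {
  dm <- dim(x); B <- dm[1]; L <- dm[2]; C <- dm[3]
  L_out <- (L + 2L * pad - k) %/% stride + 1L
  W <- nn_param(ctx, paste0(name, ".W"), c(C * k, c_out))
  b <- nn_param(ctx, paste0(name, ".b"), c(1, c_out), init = "zeros")
  dim(x) <- c(B, L * C)
  idx <- conv1d_idx(L, C, k, stride, pad)
  cols <- cpp_gather_cols(x, idx)
  Y <- cols %*% W
  out <- Y + rep(b, each = B * L_out)
  dim(out) <- c(B, L_out, c_out)
  list(out = out, bwd = function(dout) {
    dY <- dout
    dim(dY) <- c(B * L_out, c_out)
    g_add(ctx, paste0(name, ".W"), crossprod(cols, dY))
    g_add(ctx, paste0(name, ".b"), matrix(colSums(dY), 1))
    dx <- cpp_scatter_cols(dY %*% t(W), idx, L * C)
    dim(dx) <- c(B, L, C)
    dx
  })
}

# Fused convolution + bias + ELU (saves two full passes per residual-block
# convolution). bwd expects the gradient at the activation output.
nn_conv1d_elu <- function(ctx, name, x, c_out, k, stride = 1, pad = 0) {
  dm <- dim(x); B <- dm[1]; L <- dm[2]; C <- dm[3]
  L_out <- (L + 2L * pad - k) %/% stride + 1L
  W <- nn_param(ctx, paste0(name, ".W"), c(C * k, c_out))
  b <- nn_param(ctx, paste0(name, ".b"), c(1, c_out), init = "zeros")
  dim(x) <- c(B, L * C)
  idx <- conv1d_idx(L, C, k, stride, pad)
  cols <- cpp_gather_cols(x, idx)
  y <- cpp_bias_elu(cols %*% W, as.vector(b))
  out <- y
  dim(out) <- c(B, L_out, c_out)
  list(out = out, bwd = function(dout) {
    dim(dout) <- c(B * L_out, c_out)
    dY <- cpp_elu_bwd_y(y, dout)
    g_add(ctx, paste0(name, ".W"), crossprod(cols, dY))
    g_add(ctx, paste0(name, ".b"), matrix(colSums(dY), 1))
    dx <- cpp_scatter_cols(dY %*% t(W), idx, L * C)
    dim(dx) <- c(B, L, C)
    dx
  })
}

conv2d_idx <- function(H, W_in, C, k, stride, pad) {
  key <- paste("2d", H, W_in, C, k, stride, pad)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  H_out <- (H + 2L * pad - k) %/% stride + 1L
  W_out <- (W_in + 2L * pad - k) %/% stride + 1L
  oh <- rep(0:(H_out - 1), times = W_out) * stride
  ow <- rep(0:(W_out - 1), each = H_out) * stride
  idx <- matrix(0L, H_out * W_out, C * k * k)
  col <- 0L
  for (c in 0:(C - 1)) for (kw in 1:k) for (kh in 1:k) {
    col <- col + 1L
    h <- oh + kh - pad
    w <- ow + kw - pad
    ok <- h >= 1 & h <= H & w >= 1 & w <= W_in
    idx[, col] <- ifelse(ok, h + (w - 1L) * H + c * H * W_in, 0L)
  }
  .idx_cache[[key]] <- idx
  idx
}

# x: array (B, H, W, C), channels last. Weight ((kh*kw*C), C_out), order kh
# fastest, then kw, then channel. Padding is implicit.
nn_conv2d <- function(ctx, name, x, c_out, k, stride = 1, pad = 0) {
  dm <- dim(x); B <- dm[1]; H <- dm[2]; W_in <- dm[3]; C <- dm[4]
  H_out <- (H + 2L * pad - k) %/% stride + 1L
  W_out <- (W_in + 2L * pad - k) %/% stride + 1L
  CKK <- C * k * k
  Wt <- nn_param(ctx, paste0(name, ".W"), c(CKK, c_out))
  b <- nn_param(ctx, paste0(name, ".b"), c(1, c_out), init = "zeros")
  dim(x) <- c(B, H * W_in * C)
  idx <- conv2d_idx(H, W_in, C, k, stride, pad)
  P <- H_out * W_out
  cols <- cpp_gather_cols(x, idx)
  out <- cols %*% Wt + rep(b, each = B * P)
  dim(out) <- c(B, H_out, W_out, c_out)
  list(out = out, bwd = function(dout) {
    dY <- dout
    dim(dY) <- c(B * P, c_out)
    g_add(ctx, paste0(name, ".W"), crossprod(cols, dY))
    g_add(ctx, paste0(name, ".b"), matrix(colSums(dY), 1))
    dx <- cpp_scatter_cols(dY %*% t(Wt), idx, H * W_in * C)
    dim(dx) <- c(B, H, W_in, C)
    dx
  })
}

# Fused 2D convolution + bias + ELU.
nn_conv2d_elu <- function(ctx, name, x, c_out, k, stride = 1, pad = 0) {
  dm <- dim(x); B <- dm[1]; H <- dm[2]; W_in <- dm[3]; C <- dm[4]
  H_out <- (H + 2L * pad - k) %/% stride + 1L
  W_out <- (W_in + 2L * pad - k) %/% stride + 1L
  CKK <- C * k * k
  Wt <- nn_param(ctx, paste0(name, ".W"), c(CKK, c_out))
  b <- nn_param(ctx, paste0(name, ".b"), c(1, c_out), init = "zeros")
  dim(x) <- c(B, H * W_in * C)
  idx <- conv2d_idx(H, W_in, C, k, stride, pad)
  P <- H_out * W_out
  cols <- cpp_gather_cols(x, idx)
  y <- cpp_bias_elu(cols %*% Wt, as.vector(b))
  out <- y
  dim(out) <- c(B, H_out, W_out, c_out)
  list(out = out, bwd = function(dout) {
    dim(dout) <- c(B * P, c_out)
    dY <- cpp_elu_bwd_y(y, dout)
    g_add(ctx, paste0(name, ".W"), crossprod(cols, dY))
    g_add(ctx, paste0(name, ".b"), matrix(colSums(dY), 1))
    dx <- cpp_scatter_cols(dY %*% t(Wt), idx, H * W_in * C)
    dim(dx) <- c(B, H, W_in, C)
    dx
  })
}

# 2x2 max pooling, stride 2; odd trailing rows/cols are dropped.
# x: (B, H, W, C) channels last.
nn_maxpool2 <- function(x) {
  dm <- dim(x); B <- dm[1]; H <- dm[2]; W <- dm[3]; C <- dm[4]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  rows <- list(seq(1, 2 * H2, 2), seq(2, 2 * H2, 2))
  cols <- list(seq(1, 2 * W2, 2), seq(2, 2 * W2, 2))
  ord <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  cand <- lapply(ord, function(o) x[, rows[[o[1]]], cols[[o[2]]], , drop = FALSE])
  out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  taken <- array(FALSE, dim = dim(out))
  masks <- vector("list", 4)
  for (i in 1:4) {
    m <- (cand[[i]] == out) & !taken
    taken <- taken | m
    masks[[i]] <- m
  }
  list(out = out, bwd = function(dout) {
    dx <- array(0, dim = dm)
    for (i in 1:4) {
      r <- rows[[ord[[i]][1]]]; cc <- cols[[ord[[i]][2]]]
      dx[, r, cc, ] <- dx[, r, cc, ] + dout * masks[[i]]
    }
    dx
  })
}

# global average pool over spatial dims: (B, H, W, C) -> (B, C)
nn_gap2d <- function(x) {
  dm <- dim(x); B <- dm[1]; hw <- dm[2] * dm[3]; C <- dm[4]
  xf <- x; dim(xf) <- c(B, hw, C)
  out <- matrix(0, B, C)
  for (cidx in seq_len(C)) out[, cidx] <- rowMeans(xf[, , cidx, drop = FALSE])
  list(out = out, bwd = function(dout) {
    dx <- array(0, dim = c(B, hw, C))
    for (cidx in seq_len(C)) dx[, , cidx] <- dout[, cidx] / hw
    dim(dx) <- dm
    dx
  })
}

# ---- layer norm -------------------------------------------------------------

nn_layernorm <- function(ctx, name, x, eps = 1e-5) {
  d <- ncol(x)
  gamma <- nn_param(ctx, paste0(name, ".g"), c(1, d), init = "ones")
  beta <- nn_param(ctx, paste0(name, ".b"), c(1, d), init = "zeros")
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(xhat, 2, as.vector(gamma), "*")
  out <- sweep(out, 2, as.vector(beta), "+")
  list(out = out, bwd = function(dout) {
    g_add(ctx, paste0(name, ".g"), matrix(colSums(dout * xhat), 1))
    g_add(ctx, paste0(name, ".b"), matrix(colSums(dout), 1))
    dxhat <- sweep(dout, 2, as.vector(gamma), "*")
    # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) rowwise
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    (dxhat - m1 - xhat * m2) * istd
  })
}

# ---- softmax cross-entropy --------------------------------------------------

nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# logits (B, g); y integer class indices in 1..g. Loss is the mean negative
# log-probability of the true class; bwd returns dlogits.
nn_softmax_ce <- function(logits, y) {
  B <- nrow(logits)
  P <- nn_softmax(logits)
  pt <- P[cbind(seq_len(B), y)]
  loss <- -mean(log(pmax(pt, 1e-12)))
  list(loss = loss, probs = P, bwd = function() {
    Yh <- matrix(0, B, ncol(logits))
    Yh[cbind(seq_len(B), y)] <- 1
    (P - Yh) / B
  })
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- new.env(parent = emptyenv())
  e$v <- new.env(parent = emptyenv())
  e
}

adam_step <- function(ctx, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in ls(ctx$grads)) {
    g <- get(nm, envir = ctx$grads)
    p <- get(nm, envir = ctx$pars)
    m <- if (exists(nm, envir = state$m, inherits = FALSE)) get(nm, envir = state$m) else 0
    v <- if (exists(nm, envir = state$v, inherits = FALSE)) get(nm, envir = state$v) else 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    assign(nm, m, envir = state$m)
    assign(nm, v, envir = state$v)
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    assign(nm, p - lr * mhat / (sqrt(vhat) + eps), envir = ctx$pars)
  }
  invisible(NULL)
}
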