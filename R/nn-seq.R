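# Recurrent (LSTM / BiLSTM) and transformer-encoder layers built on nn-core.

# Single-direction LSTM over x (B, T, D) -> hidden sequence (B, T, H).
# Gate order in the 4H-wide projections: input, forget, cell, output.
nn_lstm <- function(ctx, name, x, hidden) {
  dm <- dim(x); B <- dm[1]; Tn <- dm[2]; D <- dm[3]
  Wx <- nn_param(ctx, paste0(name, ".Wx"), c(D, 4 * hidden))
  Wh <- nn_param(ctx, paste0(name, ".Wh"), c(hidden, 4 * hidden))
  b <- nn_param(ctx, paste0(name, ".b"), c(1, 4 * hidden), init = "zeros")
  # input projections for every timestep in one BLAS product; the recurrence
  # itself runs in compiled code
  Xf <- x; dim(Xf) <- c(B * Tn, D)
  XW <- Xf %*% Wx
  dim(XW) <- c(B, Tn, 4 * hidden)
  st <- cpp_lstm_fwd(XW, matrix(Wh, hidden, 4 * hidden), as.vector(b), B, Tn, hidden)
  list(out = st$hs, bwd = function(dhs) {
    dA <- cpp_lstm_bwd(dhs, matrix(Wh, hidden, 4 * hidden),
                       st$GI, st$GF, st$GG, st$GO, st$CS, st$TC, B, Tn, hidden)
    dim(dA) <- c(B * Tn, 4 * hidden)
    Hf <- st$Hprev; dim(Hf) <- c(B * Tn, hidden)
    g_add(ctx, paste0(name, ".Wx"), crossprod(Xf, dA))
    g_add(ctx, paste0(name, ".Wh"), crossprod(Hf, dA))
    g_add(ctx, paste0(name, ".b"), matrix(colSums(dA), 1))
    dx <- dA %*% t(Wx)
    dim(dx) <- c(B, Tn, D)
    dx
  })
}

# Bidirectional LSTM stack. Returns the full sequence (B, T, 2H) and the
# concatenated final states of the top layer (forward h_T, backward h_1).
nn_bilstm <- function(ctx, name, x, hidden, layers = 2) {
  B <- dim(x)[1]; Tn <- dim(x)[2]
  bwds <- vector("list", layers)
  cur <- x
  for (l in seq_len(layers)) {
    fw <- nn_lstm(ctx, sprintf("%s.l%d.f", name, l), cur, hidden)
    xr <- cur[, Tn:1, , drop = FALSE]
    bw <- nn_lstm(ctx, sprintf("%s.l%d.b", name, l), xr, hidden)
    br <- bw$out[, Tn:1, , drop = FALSE]
    nxt <- array(0, dim = c(B, Tn, 2 * hidden))
    nxt[, , 1:hidden] <- fw$out
    nxt[, , hidden + 1:hidden] <- br
    bwds[[l]] <- list(fw = fw, bw = bw)
    cur <- nxt
  }
  final <- cbind(matrix(cur[, Tn, 1:hidden], B, hidden),
                 matrix(cur[, 1, hidden + 1:hidden], B, hidden))
  list(out = cur, final = final,
       bwd = function(dseq, dfinal = NULL) {
         if (!is.null(dfinal)) {
           dseq[, Tn, 1:hidden] <- dseq[, Tn, 1:hidden] + dfinal[, 1:hidden]
           dseq[, 1, hidden + 1:hidden] <- dseq[, 1, hidden + 1:hidden] +
             dfinal[, hidden + 1:hidden]
         }
         for (l in layers:1) {
           dfw <- dseq[, , 1:hidden, drop = FALSE]
           dbr <- dseq[, , hidden + 1:hidden, drop = FALSE]
           dx_f <- bwds[[l]]$fw$bwd(dfw)
           dx_b <- bwds[[l]]$bw$bwd(dbr[, Tn:1, , drop = FALSE])
           dseq <- dx_f + dx_b[, Tn:1, , drop = FALSE]
         }
         dseq
       })
}

# Multi-head self-attention over x (B, T, d); d must divide by n_heads.
nn_mha <- function(ctx, name, x, n_heads) {
  dm <- dim(x); B <- dm[1]; Tn <- dm[2]; d <- dm[3]
  dh <- d %/% n_heads
  x2 <- x; dim(x2) <- c(B * Tn, d)
  lq <- nn_linear(ctx, paste0(name, ".q"), x2, d)
  lk <- nn_linear(ctx, paste0(name, ".k"), x2, d)
  lv <- nn_linear(ctx, paste0(name, ".v"), x2, d)
  tohead <- function(m) array(m, dim = c(B, Tn, dh, n_heads))
  Q <- tohead(lq$out); K <- tohead(lk$out); V <- tohead(lv$out)
  scale <- 1 / sqrt(dh)
  A <- array(0, dim = c(B, n_heads, Tn, Tn))        # attention weights
  O <- array(0, dim = c(B, Tn, dh, n_heads))
  for (h in seq_len(n_heads)) {
    S <- array(0, dim = c(B, Tn, Tn))
    for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
      S[, i, j] <- rowSums(matrix(Q[, i, , h], B, dh) * matrix(K[, j, , h], B, dh)) * scale
    }
    for (i in seq_len(Tn)) {
      z <- matrix(S[, i, ], B, Tn)
      z <- z - apply(z, 1, max)
      e <- exp(z)
      A[, h, i, ] <- e / rowSums(e)
    }
    for (i in seq_len(Tn)) {
      acc <- matrix(0, B, dh)
      for (j in seq_len(Tn)) {
        acc <- acc + A[, h, i, j] * matrix(V[, j, , h], B, dh)
      }
      O[, i, , h] <- acc
    }
  }
  O2 <- O; dim(O2) <- c(B * Tn, d)
  lo <- nn_linear(ctx, paste0(name, ".o"), O2, d)
  out <- lo$out; dim(out) <- c(B, Tn, d)
  list(out = out, bwd = function(dout) {
    dout2 <- dout; dim(dout2) <- c(B * Tn, d)
    dO2 <- lo$bwd(dout2)
    dO <- array(dO2, dim = c(B, Tn, dh, n_heads))
    dQ <- array(0, dim = dim(Q)); dK <- array(0, dim = dim(K)); dV <- array(0, dim = dim(V))
    for (h in seq_len(n_heads)) {
      dS <- array(0, dim = c(B, Tn, Tn))
      for (i in seq_len(Tn)) {
        dOi <- matrix(dO[, i, , h], B, dh)
        dA_i <- matrix(0, B, Tn)
        for (j in seq_len(Tn)) {
          dA_i[, j] <- rowSums(dOi * matrix(V[, j, , h], B, dh))
          dV[, j, , h] <- dV[, j, , h] + A[, h, i, j] * dOi
        }
        Ai <- matrix(A[, h, i, ], B, Tn)
        dS[, i, ] <- Ai * (dA_i - rowSums(Ai * dA_i))
      }
      for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
        dQ[, i, , h] <- dQ[, i, , h] + dS[, i, j] * matrix(K[, j, , h], B, dh) * scale
        dK[, j, , h] <- dK[, j, , h] + dS[, i, j] * matrix(Q[, i, , h], B, dh) * scale
      }
    }
    flat <- function(a) { dim(a) <- c(B * Tn, d); a }
    dx2 <- lq$bwd(flat(dQ)) + lk$bwd(flat(dK)) + lv$bwd(flat(dV))
    dim(dx2) <- c(B, Tn, d)
    dx2
  })
}

# One post-norm transformer encoder layer (self-attention + ELU feed-forward).
nn_transformer_layer <- function(ctx, name, x, n_heads, d_ff, dropout = 0) {
  dm <- dim(x); B <- dm[1]; Tn <- dm[2]; d <- dm[3]
  att <- nn_mha(ctx, paste0(name, ".mha"), x, n_heads)
  dr1 <- nn_dropout(ctx, att$out, dropout)
  r1 <- x + dr1$out
  r1m <- r1; dim(r1m) <- c(B * Tn, d)
  ln1 <- nn_layernorm(ctx, paste0(name, ".ln1"), r1m)
  f1 <- nn_linear(ctx, paste0(name, ".ff1"), ln1$out, d_ff)
  a1 <- nn_elu(f1$out)
  f2 <- nn_linear(ctx, paste0(name, ".ff2"), a1$out, d)
  dr2 <- nn_dropout(ctx, f2$out, dropout)
  r2 <- ln1$out + dr2$out
  ln2 <- nn_layernorm(ctx, paste0(name, ".ln2"), r2)
  out <- ln2$out; dim(out) <- c(B, Tn, d)
  list(out = out, bwd = function(dout) {
    d2 <- dout; dim(d2) <- c(B * Tn, d)
    dr2m <- ln2$bwd(d2)
    dff <- f1$bwd(a1$bwd(f2$bwd(dr2$bwd(dr2m))))
    dln1 <- ln1$bwd(dr2m + dff)
    dim(dln1) <- c(B, Tn, d)
    datt <- att$bwd(dr1$bwd(dln1))
    dln1 + datt
  })
}
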