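# Shared test fixtures and oracles. Heavy benchmark artifacts are computed
# lazily once and cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# Tiny model configuration for fast structural/gradient tests.
tiny_config <- function(...) {
  args <- list(d = 8, time_channels = c(2, 3), time_kernels = c(7, 3),
               spec_channels = c(2, 3), lstm_hidden = 3, lstm_layers = 1,
               tf_layers = 1, n_heads = 2, d_ff = 8, physio_width = 6,
               gender_dim = 2, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

# Small labeled dataset built through the real pipeline.
tiny_dataset <- function(seed = 1, n_subjects = 4, duration_s = 20) {
  cached(paste("tiny", seed, n_subjects, duration_s), {
    build_dataset(preprocess_cohort(
      generate_cohort(n_subjects = n_subjects, duration_s = duration_s, seed = seed)))
  })
}

# Literal evaluation of the STFT magnitude at window position n0 (0-based)
# and frequency k: |sum_m x_m g_{n0-m} exp(-i 2 pi k m / N)|, summing over the
# whole signal with the window taken as zero outside its support.
stft_oracle <- function(x, g, n0, k) {
  N <- length(g)
  m <- seq_along(x) - 1
  j <- n0 - m
  gv <- ifelse(j >= 0 & j <= N - 1, g[pmin(pmax(j, 0), N - 1) + 1], 0)
  Mod(sum(x * gv * exp(-2i * pi * k * m / N)))
}

# Full oracle spectrogram for one signal/spec pair.
stft_oracle_matrix <- function(x, spec) {
  g <- fatiguecg:::stft_window(spec)
  N <- spec$window_length
  positions <- seq(N - 1, length(x) - 1, by = spec$hop)
  out <- matrix(0, length(positions), N)
  for (r in seq_along(positions)) {
    for (k in 0:(N - 1)) out[r, k + 1] <- stft_oracle(x, g, positions[r], k)
  }
  out
}

# Finite-difference gradient check over a sampled subset of parameters.
# fwd(backward) must run the forward (and backward when asked) and return the
# scalar loss; gradients accumulate in ctx$grads.
gradcheck_worst <- function(fwd, ctx, n_per_param = 3, eps = 1e-5) {
  fatiguecg:::nn_zero_grads(ctx)
  fwd(backward = TRUE)
  worst <- 0
  for (nm in ls(ctx$grads)) {
    p <- get(nm, envir = ctx$pars)
    g <- get(nm, envir = ctx$grads)
    for (i in sample(length(p), min(n_per_param, length(p)))) {
      orig <- p[i]
      p[i] <- orig + eps; assign(nm, p, envir = ctx$pars)
      lp <- fwd(backward = FALSE)
      p[i] <- orig - eps; assign(nm, p, envir = ctx$pars)
      lm <- fwd(backward = FALSE)
      p[i] <- orig; assign(nm, p, envir = ctx$pars)
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) / max(1, abs(num), abs(g[i])))
    }
  }
  worst
}

# Mean RR interval recovered by the threshold-and-local-max peak oracle.
oracle_mean_rr <- function(x, fs = 130) {
  pk <- detect_rpeaks(x, fs = fs, threshold = 0.4)
  if (length(pk) < 2) return(NA_real_)
  mean(diff(pk)) / fs
}
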