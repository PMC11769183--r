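ns <- asNamespace("fatiguecg")

test_that("cross-entropy reproduces its closed forms", {
  # perfect one-hot prediction -> 0
  expect_equal(cross_entropy(matrix(c(1, 0), 1), 1), 0, tolerance = 1e-9)
  # uniform two-class prediction -> log 2
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), 1), log(2), tolerance = 1e-9)
  # two samples: -(log 0.9 + log 0.8) / 2
  P <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(cross_entropy(P, c(1, 2)), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-9)
  # one-hot matrix form agrees with index form
  S <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy(P, S), cross_entropy(P, c(1, 2)))
  # non-negative, and finite even at clipped zeros
  expect_gte(cross_entropy(matrix(c(0.3, 0.7), 1), 1), 0)
  expect_true(is.finite(cross_entropy(matrix(c(0, 1), 1), 1)))
  expect_error(cross_entropy(matrix(c(0.7, 0.7), 1), 1))
  expect_error(cross_entropy(P, c(1, 2, 1)), class = "fatiguecg_shape_error")
})

test_that("age one-hot encoding puts the single 1 at the age index", {
  oh <- age_onehot(25)
  expect_equal(dim(oh), c(1, 100))
  expect_equal(sum(oh), 1)
  expect_equal(which(oh == 1), 26)   # 0-based index equals the age
  expect_error(age_onehot(100), class = "fatiguecg_invalid_input")
  expect_error(age_onehot(-1), class = "fatiguecg_invalid_input")
})

test_that("branch encoders are deterministic, finite and input-sensitive", {
  cfg <- tiny_config()
  mdl <- ns$init_fatigue_model(cfg)
  x <- matrix(rnorm(1300), 1)
  t1 <- encode_time_branch(mdl, x)
  expect_equal(dim(t1), c(1, cfg$d))
  expect_true(all(is.finite(t1)))
  expect_identical(t1, encode_time_branch(mdl, x))      # fixed weights
  expect_true(all(is.finite(encode_time_branch(mdl, matrix(0, 1, 1300)))))
  # perturbing one sample near the record end changes the token (an untrained
  # LSTM's ~0.5 forget gates decay mid-sequence perturbations below double
  # precision before the final state, so the probe sits inside its memory
  # horizon)
  x2 <- x; x2[1, 1290] <- x2[1, 1290] + 1e-3
  expect_false(identical(t1, encode_time_branch(mdl, x2)))
  expect_error(encode_time_branch(mdl, matrix(0, 1, 1000)),
               class = "fatiguecg_shape_error")
})

test_that("the spectrogram branch needs exactly 10 images and is order-sensitive", {
  cfg <- tiny_config()
  mdl <- ns$init_fatigue_model(cfg)
  set.seed(31)
  imgs <- array(rnorm(10 * 17 * 25), c(10, 17, 25))
  tok <- encode_spec_branch(mdl, imgs)
  expect_true(all(is.finite(tok)))
  expect_true(all(is.finite(encode_spec_branch(mdl, array(0, c(10, 17, 25))))))
  # reversing the image sequence changes the token
  expect_false(identical(tok, encode_spec_branch(mdl, imgs[10:1, , ])))
  expect_error(encode_spec_branch(mdl, array(0, c(1, 9, 17, 25))),
               class = "fatiguecg_shape_error")
})

test_that("the physiological encoder distinguishes gender and rejects bad input", {
  cfg <- tiny_config()
  mdl <- ns$init_fatigue_model(cfg)
  tm <- encode_physio(mdl, 25, "male")
  tf_ <- encode_physio(mdl, 25, "female")
  expect_false(identical(tm, tf_))
  expect_error(encode_physio(mdl, 100, "male"), class = "fatiguecg_invalid_input")
  expect_error(encode_physio(mdl, 25, "unknown"), class = "fatiguecg_invalid_input")
})

test_that("fusion produces normalized probabilities and respects token counts", {
  cfg <- tiny_config()
  mdl <- ns$init_fatigue_model(cfg)
  set.seed(32)
  toks <- replicate(3, matrix(rnorm(2 * cfg$d), 2), simplify = FALSE)
  probs <- fuse_and_classify(mdl, toks)
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_error(fuse_and_classify(mdl, toks[1:2]), class = "fatiguecg_config_error")
  expect_error(model_config(use_T = FALSE, use_S = FALSE, use_P = FALSE),
               class = "fatiguecg_config_error")
})

test_that("disabled branches cannot influence the output (ablation isolation)", {
  cfg <- tiny_config(use_P = FALSE)
  mdl <- ns$init_fatigue_model(cfg)
  set.seed(33)
  batch1 <- list(x_time = matrix(rnorm(2 * 1300), 2),
                 x_spec = array(rnorm(2 * 10 * 17 * 25), c(2, 10, 17, 25)),
                 age = c(20L, 25L), gender = c("male", "male"))
  batch2 <- batch1
  batch2$age <- c(85L, 3L)                       # physio inputs randomized
  batch2$gender <- c("female", "female")
  r1 <- ns$forward_fatigue(mdl$ctx, cfg, batch1)
  r2 <- ns$forward_fatigue(mdl$ctx, cfg, batch2)
  expect_identical(r1$probs, r2$probs)
  # and an S-only model ignores the time series entirely
  cfgS <- tiny_config(use_T = FALSE, use_P = FALSE)
  mdlS <- ns$init_fatigue_model(cfgS)
  b1 <- list(x_spec = batch1$x_spec, x_time = batch1$x_time)
  b2 <- list(x_spec = batch1$x_spec, x_time = matrix(rnorm(2 * 1300), 2))
  expect_identical(ns$forward_fatigue(mdlS$ctx, cfgS, b1)$probs,
                   ns$forward_fatigue(mdlS$ctx, cfgS, b2)$probs)
})

test_that("without type embeddings the fused output is token-order invariant", {
  cfg <- tiny_config(use_type_embedding = FALSE)
  mdl <- ns$init_fatigue_model(cfg)
  set.seed(34)
  toks <- replicate(3, matrix(rnorm(2 * cfg$d), 2), simplify = FALSE)
  p1 <- fuse_and_classify(mdl, toks)
  p2 <- fuse_and_classify(mdl, toks[c(3, 1, 2)])
  expect_equal(p1, p2, tolerance = 1e-10)
  # with type embeddings the order carries information
  cfg2 <- tiny_config(use_type_embedding = TRUE)
  mdl2 <- ns$init_fatigue_model(cfg2)
  q1 <- fuse_and_classify(mdl2, toks)
  q2 <- fuse_and_classify(mdl2, toks[c(3, 1, 2)])
  expect_false(isTRUE(all.equal(q1, q2, tolerance = 1e-10)))
})

test_that("gradients flow into every enabled branch", {
  cfg <- tiny_config()
  mdl <- ns$init_fatigue_model(cfg)
  set.seed(35)
  batch <- list(x_time = matrix(rnorm(4 * 1300), 4),
                x_spec = array(rnorm(4 * 10 * 17 * 25), c(4, 10, 17, 25)),
                age = c(20L, 25L, 30L, 22L),
                gender = c("male", "female", "male", "female"),
                y = c(1L, 2L, 1L, 2L))
  ns$nn_zero_grads(mdl$ctx)
  res <- ns$forward_fatigue(mdl$ctx, cfg, batch, training = TRUE)
  res$backward()
  grads <- ls(mdl$ctx$grads)
  for (branch in c("time\\.", "spec\\.", "physio\\.", "fuse\\.")) {
    bg <- grep(branch, grads, value = TRUE)
    expect_gt(length(bg), 0)
    total <- sum(vapply(bg, function(nm) sum(abs(get(nm, envir = mdl$ctx$grads))),
                        numeric(1)))
    expect_gt(total, 0)
  }
})

test_that("a small hybrid model overfits one batch of 8 examples", {
  ds <- tiny_dataset(seed = 1, n_subjects = 4, duration_s = 20)
  rows <- ds[order(ds$label), ][c(1:4, 5:8), ]
  cfg <- tiny_config(d = 16, lstm_hidden = 8, seed = 2)
  batch <- ns$make_batch(rows, cfg)
  mdl <- ns$init_fatigue_model(cfg)
  st <- ns$adam_state()
  loss <- Inf
  for (i in 1:200) {
    ns$nn_zero_grads(mdl$ctx)
    res <- ns$forward_fatigue(mdl$ctx, cfg, batch, training = TRUE)
    res$backward()
    ns$adam_step(mdl$ctx, st, lr = 2e-3)
    loss <- res$loss
    if (loss < 0.05) break
  }
  expect_lt(loss, 0.05)
})
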