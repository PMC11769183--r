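test_that("segmentation follows the 130-sample floor arithmetic", {
  expect_equal(nrow(segment_signal(numeric(1300))), 10)
  segs <- segment_signal(numeric(1365))
  expect_equal(nrow(segs), 10)                      # 65-sample tail discarded
  expect_equal(segs$start, (0:9) * 130)
  expect_warning(empty <- segment_signal(numeric(129)),
                 class = "fatiguecg_empty_output")
  expect_equal(nrow(empty), 0)
})

test_that("grouping takes 10 consecutive segments and drops remainders", {
  segs <- segment_signal(seq_len(60 * 130))
  expect_equal(nrow(group_segments(segs)), 6)
  expect_equal(nrow(group_segments(segs[1:9, ])), 0)
  g <- group_segments(segs[1:25, ])
  expect_equal(nrow(g), 2)
  expect_length(g$signal[[1]], 1300)
  # group signal is the concatenation of its member segments
  expect_identical(g$signal[[1]], seq_len(1300))
  expect_identical(g$signal[[2]], 1300L + seq_len(1300))
})

test_that("the fatigue label is strictly above-80", {
  expect_equal(as.character(label_from_vas(c(85, 80, 0, 80.0001))),
               c("F", "N", "N", "F"))
  expect_equal(levels(label_from_vas(50)), c("F", "N"))
  expect_error(label_from_vas(101), class = "fatiguecg_invalid_input")
  expect_error(label_from_vas(-1), class = "fatiguecg_invalid_input")
})

test_that("STFT concentrates energy at the expected bins", {
  rect8 <- stft_spec(window_length = 8, hop = 1, window = "rect", scale = "linear")
  # constant signal: all energy at DC, bin magnitude = N
  sg <- stft(rep(1, 16), rect8)
  expect_lt(max(abs(sg[, 1] - 8)), 1e-10)
  expect_lt(max(sg[, 2:8]), 1e-10)
  # cosine at 2 cycles per 8 samples: magnitude 4 at k = 2 and k = 6
  x <- cos(2 * pi * 2 * (0:7) / 8)
  sg2 <- stft(x, rect8)
  expect_equal(sg2[1, 3], 4, tolerance = 1e-10)
  expect_equal(sg2[1, 7], 4, tolerance = 1e-10)
  expect_lt(max(sg2[1, c(1, 2, 4, 5, 6, 8)]), 1e-9)
  expect_error(stft(numeric(8), stft_spec(window_length = 16)),
               class = "fatiguecg_invalid_parameter")
})

test_that("STFT matches the literal double-sum oracle on random signals/specs", {
  set.seed(10)
  for (trial in 1:12) {
    L <- sample(32:256, 1)
    N <- sample(c(8, 16, 32), 1)
    if (N > L) N <- 8
    hop <- sample(1:N, 1)
    win <- sample(c("hann", "rect"), 1)
    x <- rnorm(L)
    spec <- stft_spec(window_length = N, hop = hop, window = win, scale = "linear")
    sg <- stft(x, spec)
    g <- fatiguecg:::stft_window(spec)
    pos <- attr(sg, "positions")
    # check a random subset of entries against the brute-force sum
    for (chk in 1:6) {
      r <- sample(length(pos), 1)
      k <- sample(0:(N - 1), 1)
      expect_lt(abs(sg[r, k + 1] - stft_oracle(x, g, pos[r], k)), 1e-10)
    }
  }
})

test_that("rectangular full tiling satisfies the Parseval identity", {
  set.seed(11)
  x <- rnorm(128)
  spec <- stft_spec(window_length = 16, hop = 16, window = "rect", scale = "linear")
  sg <- stft(x, spec)
  expect_equal(sum(sg^2), 16 * sum(x^2), tolerance = 1e-6)
})

test_that("spectrogram images keep non-redundant bins and honor scaling", {
  set.seed(12)
  spec16 <- stft_spec(window_length = 16, hop = 4, scale = "linear")
  img <- spectrogram_image(stft(rnorm(64), spec16))
  expect_equal(nrow(img), 9)                        # k = 0..8 for N = 16
  # all-zero signal -> all-zero linear image
  expect_true(all(spectrogram_image(stft(numeric(64), spec16)) == 0))
  # log scaling floors at log(eps)
  lspec <- stft_spec(window_length = 16, hop = 4, scale = "log", eps = 1e-8)
  limg <- spectrogram_image(stft(numeric(64), lspec))
  expect_true(all(limg >= log(1e-8) - 1e-12))
  # default spec on a 130-sample segment gives a 17 x 25 image
  dimg <- spectrogram_image(stft(rnorm(130), stft_spec()))
  expect_equal(dim(dimg), c(17, 25))
})

test_that("dataset assembly conserves counts and inherits record labels", {
  ds <- tiny_dataset(seed = 1, n_subjects = 4, duration_s = 20)
  co <- generate_cohort(n_subjects = 4, duration_s = 20, seed = 1)
  expected <- sum(floor(floor(vapply(co$ecg, length, numeric(1)) / 130) / 10))
  expect_equal(nrow(ds), expected)
  expect_true(all(vapply(ds$signal, length, numeric(1)) == 1300))
  expect_true(all(vapply(ds$spectrograms, function(a) all(dim(a) == c(10, 17, 25)),
                         logical(1))))
  # per-record label inheritance from the VAS rule
  for (i in seq_len(nrow(co))) {
    rows <- ds[ds$record_id == co$subject_id[i], ]
    expect_true(all(rows$label == label_from_vas(co$vas[i])))
  }
  # empty input -> empty dataset
  expect_equal(nrow(build_dataset(co[0, ])), 0)
})

test_that("counting conservation holds over random record lengths", {
  set.seed(13)
  lens <- sample(100:5000, 100, replace = TRUE)
  for (n in lens) {
    segs <- suppressWarnings(segment_signal(numeric(n)))
    expect_equal(nrow(segs), floor(n / 130))
    expect_equal(nrow(group_segments(segs)), floor(floor(n / 130) / 10))
  }
})
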