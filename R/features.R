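# Segmentation into 1-s windows and 10-s groups, VAS labeling, and STFT
# spectrograms.

#' Segment a signal into non-overlapping 130-sample windows
#'
#' One segment covers 1 s at the 130 Hz device rate. A trailing remainder
#' shorter than one segment is discarded; a signal shorter than one segment
#' yields zero segments with a warning (not an error).
#'
#' @param signal Numeric vector.
#' @param segment_length Samples per segment (default 130).
#' @return Tibble with columns `segment_index` (1-based), `start` (0-based
#'   sample offset) and list-column `signal`.
#' @examples
#' nrow(segment_signal(numeric(1365)))  # 10 segments, 65-sample tail dropped
#' @export
segment_signal <- function(signal, segment_length = 130) {
  assert_that(is.numeric(signal), "signal must be numeric")
  assert_that(is_count(segment_length), "segment_length must be a positive integer")
  n_seg <- floor(length(signal) / segment_length)
  if (n_seg == 0) {
    warn(sprintf("signal of length %d is shorter than one %d-sample segment; returning 0 segments",
                 length(signal), segment_length),
         class = "fatiguecg_empty_output")
    return(tibble(segment_index = integer(0), start = integer(0), signal = list()))
  }
  starts <- (seq_len(n_seg) - 1L) * segment_length
  tibble(
    segment_index = seq_len(n_seg),
    start = starts,
    signal = map(starts, function(s) signal[(s + 1):(s + segment_length)])
  )
}

#' Group consecutive segments into 10-segment (10-s) groups
#'
#' @param segments Tibble from [segment_signal()], ordered by `start`.
#' @param group_size Segments per group (default 10).
#' @return Tibble with `group_index`, `start` (offset of the first segment)
#'   and list-columns `segments` (the member rows) and `signal` (the
#'   concatenated group signal, `group_size * segment_length` samples).
#' @export
group_segments <- function(segments, group_size = 10) {
  assert_that(is.data.frame(segments) && all(c("start", "signal") %in% names(segments)),
              "segments must come from segment_signal()")
  assert_that(!is.unsorted(segments$start), "segments must be ordered by start index")
  n_groups <- floor(nrow(segments) / group_size)
  if (n_groups == 0) {
    return(tibble(group_index = integer(0), start = integer(0),
                  segments = list(), signal = list()))
  }
  seg_rows <- map(seq_len(n_groups), function(g) {
    segments[((g - 1L) * group_size + 1L):(g * group_size), ]
  })
  sig <- map(seg_rows, function(sr) unlist(sr$signal, use.names = FALSE))
  tibble(
    group_index = seq_len(n_groups),
    start = segments$start[(seq_len(n_groups) - 1L) * group_size + 1L],
    segments = seg_rows,
    signal = sig
  )
}

#' Label a VAS score as fatigue (F) or non-fatigue (N)
#'
#' The rule is strict: F if and only if the VAS score is above 80%; a score of
#' exactly 80 is non-fatigue.
#'
#' @param vas_percent Numeric vector of VAS scores in \[0, 100\].
#' @return Factor with levels `c("F", "N")`.
#' @examples
#' label_from_vas(c(85, 80, 0))
#' @export
label_from_vas <- function(vas_percent) {
  assert_that(is.numeric(vas_percent) && all(is.finite(vas_percent)) &&
                all(vas_percent >= 0 & vas_percent <= 100),
              "VAS scores must lie in [0, 100]",
              class = "fatiguecg_invalid_input")
  factor(ifelse(vas_percent > 80, "F", "N"), levels = c("F", "N"))
}

#' STFT specification
#'
#' Window length, hop, window shape and output scaling for the short-time
#' Fourier transform. The defaults (Hann window, N = 32, hop = 4,
#' log-magnitude) turn a 130-sample segment into a 17 x 25
#' (frequency x time) image.
#'
#' @param window_length Window sample count N.
#' @param hop Step between window positions (1 <= hop <= N).
#' @param window `"hann"`, `"rect"`, or a numeric vector of length N.
#' @param scale `"log"` or `"linear"` scaling for [spectrogram_image()].
#' @param eps Floor applied before the log (`min(image) >= log(eps)`).
#' @return A list of class `stft_spec`.
#' @export
stft_spec <- function(window_length = 32, hop = 4,
                      window = c("hann", "rect"), scale = c("log", "linear"),
                      eps = 1e-8) {
  scale <- match.arg(scale)
  assert_that(is_count(window_length), "window_length must be a positive integer")
  assert_that(is_count(hop) && hop <= window_length,
              "hop must satisfy 1 <= hop <= window_length")
  if (is.character(window)) {
    window <- match.arg(window)
  } else {
    assert_that(is.numeric(window) && length(window) == window_length,
                "a numeric window must have length window_length")
  }
  structure(list(window_length = as.integer(window_length), hop = as.integer(hop),
                 window = window, scale = scale, eps = eps),
            class = "stft_spec")
}

stft_window <- function(spec) {
  N <- spec$window_length
  if (is.numeric(spec$window)) return(spec$window)
  switch(spec$window,
         hann = if (N == 1) 1 else 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1))),
         rect = rep(1, N))
}

#' Short-time Fourier transform magnitude
#'
#' Computes `|S[n, k]| = |sum_m x_m g_{n-m} exp(-i 2 pi k m / N)|` for window
#' positions `n` stepped by the hop. Windows are placed entirely inside the
#' signal: the first position is `n = N - 1` (0-based), so a window's support
#' `m in [n - N + 1, n]` never overhangs either edge.
#'
#' @param signal Numeric vector (length >= window length).
#' @param spec An [stft_spec()].
#' @return A matrix of class `fatigue_spectrogram`: rows are window positions
#'   (attribute `positions`, 0-based `n`), columns are frequency bins
#'   `k = 0 .. N-1`; entries are magnitudes (>= 0). The spec is attached as
#'   attribute `spec`.
#' @export
stft <- function(signal, spec = stft_spec()) {
  assert_that(inherits(spec, "stft_spec"), "spec must be an stft_spec")
  N <- spec$window_length
  L <- length(signal)
  assert_that(N <= L, sprintf("window length %d exceeds signal length %d", N, L),
              class = "fatiguecg_invalid_parameter")
  g <- stft_window(spec)
  positions <- seq(N - 1L, L - 1L, by = spec$hop)   # 0-based n
  # y_j = x[n - j] * g_j, j = 0..N-1 ; |S[n, k]| = |DFT_k(y)|
  samp_idx <- outer(positions, 0:(N - 1L), function(n, j) n - j) + 1L
  Y <- matrix(signal[samp_idx], nrow = length(positions)) *
    matrix(g, nrow = length(positions), ncol = N, byrow = TRUE)
  jj <- 0:(N - 1L)
  E <- exp(-2i * pi * outer(jj, jj) / N)   # E[j+1, k+1]
  S <- Mod(Y %*% E)
  structure(S, positions = positions, spec = spec,
            class = c("fatigue_spectrogram", class(S)))
}

#' Model-ready spectrogram image
#'
#' For real input the spectrum is conjugate-symmetric, so only bins
#' `k = 0 .. floor(N/2)` are retained; the matrix is transposed to
#' frequency x time and scaled per the spec (`log` applies a floor of `eps`
#' first, so `min(image) >= log(eps)`).
#'
#' @param spectrogram A `fatigue_spectrogram` from [stft()].
#' @return Numeric matrix, `floor(N/2) + 1` frequency rows by one column per
#'   window position.
#' @export
spectrogram_image <- function(spectrogram) {
  assert_that(inherits(spectrogram, "fatigue_spectrogram"),
              "spectrogram must come from stft()")
  spec <- attr(spectrogram, "spec")
  N <- spec$window_length
  keep <- seq_len(floor(N / 2) + 1L)
  img <- t(unclass(spectrogram)[, keep, drop = FALSE])
  if (spec$scale == "log") img <- log(pmax(img, spec$eps))
  img
}

#' Build the labeled example dataset from a cohort
#'
#' Each example is one 10-s segment group: the 1300-sample group signal, ten
#' per-segment spectrogram images, the subject's physiological fields, and the
#' record's VAS-derived F/N label. Records lacking a `processed` column are
#' preprocessed first with `wavelet_spec`.
#'
#' @param cohort A `fatigue_cohort` (ideally after [preprocess_cohort()]).
#' @param wavelet_spec A [wavelet_spec()] used only if preprocessing is still
#'   needed.
#' @param stft_spec An [stft_spec()].
#' @param segment_length,group_size Segmentation parameters (130 samples, 10
#'   segments).
#' @return A tibble of class `fatigue_dataset`: one row per example with
#'   columns `example_id`, `record_id`, `group_index`, `label`, `vas`, `age`,
#'   `gender`, and list-columns `signal` (1300 samples) and `spectrograms`
#'   (array `10 x n_freq x n_time`).
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, duration_s = 20, seed = 1)
#' ds <- build_dataset(preprocess_cohort(cohort))
#' nrow(ds)  # floor(floor(20 * 130 / 130) / 10) per record
#' @export
build_dataset <- function(cohort,
                          wavelet_spec = fatiguecg::wavelet_spec(),
                          stft_spec = fatiguecg::stft_spec(),
                          segment_length = 130, group_size = 10) {
  assert_that(is.data.frame(cohort), "cohort must be a tibble of records")
  if (nrow(cohort) == 0) {
    out <- tibble(example_id = character(0), record_id = character(0),
                  group_index = integer(0),
                  label = factor(character(0), levels = c("F", "N")),
                  vas = numeric(0), age = integer(0), gender = character(0),
                  signal = list(), spectrograms = list())
    class(out) <- c("fatigue_dataset", class(out))
    return(out)
  }
  if (!"processed" %in% names(cohort)) {
    cohort <- preprocess_cohort(cohort, spec = wavelet_spec)
  }
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    segs <- segment_signal(cohort$processed[[i]], segment_length)
    groups <- group_segments(segs, group_size)
    if (nrow(groups) == 0) next
    label <- label_from_vas(cohort$vas[i])
    specs <- map(groups$segments, function(sg) {
      imgs <- map(sg$signal, function(x) spectrogram_image(stft(x, stft_spec)))
      arr <- array(0, dim = c(length(imgs), nrow(imgs[[1]]), ncol(imgs[[1]])))
      for (k in seq_along(imgs)) arr[k, , ] <- imgs[[k]]
      arr
    })
    rows[[i]] <- tibble(
      example_id = sprintf("%s_g%02d", cohort$subject_id[i], groups$group_index),
      record_id = cohort$subject_id[i],
      group_index = groups$group_index,
      label = rep(label, nrow(groups)),
      vas = cohort$vas[i],
      age = cohort$age[i],
      gender = cohort$gender[i],
      signal = groups$signal,
      spectrograms = specs
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("fatigue_dataset", class(out))
  out
}
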