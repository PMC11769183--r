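# Record-level preprocessing: wavelet denoising, DC removal, z-scoring.

#' Remove the DC component
#'
#' @param signal Non-empty numeric vector.
#' @return The signal minus its mean (output mean is 0 to within 1e-10).
#' @export
remove_dc <- function(signal) {
  assert_that(is.numeric(signal) && length(signal) >= 1,
              "signal must be a non-empty numeric vector",
              class = "fatiguecg_invalid_input")
  signal - mean(signal)
}

#' Standardize a signal to zero mean and unit population standard deviation
#'
#' Centers by the mean and divides by the population standard deviation
#' (denominator `n`, not `n - 1`), applied per record before segmentation.
#'
#' @param signal Non-constant numeric vector.
#' @return Standardized signal (mean 0, population SD 1 within 1e-8).
#' @export
standardize <- function(signal) {
  assert_that(is.numeric(signal) && length(signal) >= 1,
              "signal must be a non-empty numeric vector",
              class = "fatiguecg_invalid_input")
  m <- mean(signal)
  s <- sqrt(mean((signal - m)^2))
  assert_that(s > 0, "cannot standardize a constant (zero-variance) signal",
              class = "fatiguecg_degenerate_input")
  (signal - m) / s
}

#' Preprocess one signal: denoise, remove DC, standardize
#'
#' The three stages run in the fixed order wavelet denoising, then DC removal,
#' then z-scoring; the report records all three.
#'
#' @param signal Numeric signal (length >= `2^levels` of the wavelet spec).
#' @param spec A [wavelet_spec()].
#' @return List with `signal` (processed) and `report` (tibble, one row per
#'   stage).
#' @export
preprocess_signal <- function(signal, spec = wavelet_spec()) {
  den <- wavelet_denoise(signal, spec)
  x <- den$signal
  dc <- mean(x)
  x <- remove_dc(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  x <- standardize(x)
  report <- bind_rows(
    den$report,
    tibble(stage = "remove_dc", rule = NA_character_, threshold = NA_real_,
           pre_energy = NA_real_, post_energy = NA_real_, dc_offset = dc),
    tibble(stage = "standardize", rule = NA_character_, threshold = NA_real_,
           pre_energy = NA_real_, post_energy = NA_real_, dc_offset = NA_real_,
           center = m, scale = s)
  )
  class(report) <- c("preprocess_report", class(report))
  list(signal = x, report = report)
}

#' Preprocess a single ECG record
#'
#' @param record A one-row `fatigue_cohort` tibble (or any tibble with an
#'   `ecg` list-column).
#' @param spec A [wavelet_spec()].
#' @return The record with a `processed` list-column holding the denoised,
#'   DC-removed, standardized signal and a `report` list-column.
#' @export
preprocess_record <- function(record, spec = wavelet_spec()) {
  assert_that(is.data.frame(record) && nrow(record) == 1 && "ecg" %in% names(record),
              "record must be a one-row tibble with an `ecg` list-column")
  res <- preprocess_signal(record$ecg[[1]], spec)
  record$processed <- list(res$signal)
  record$report <- list(res$report)
  record
}

#' Preprocess every record in a cohort
#'
#' @param cohort A `fatigue_cohort` tibble (one row per record).
#' @param spec A [wavelet_spec()].
#' @return The cohort with `processed` and `report` list-columns added.
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, duration_s = 20, seed = 1)
#' cohort <- preprocess_cohort(cohort)
#' sapply(cohort$processed, function(x) round(c(mean = mean(x), sd = sd(x)), 3))
#' @export
preprocess_cohort <- function(cohort, spec = wavelet_spec()) {
  assert_that(is.data.frame(cohort) && "ecg" %in% names(cohort),
              "cohort must be a tibble with an `ecg` list-column")
  res <- map(cohort$ecg, preprocess_signal, spec = spec)
  cohort$processed <- map(res, "signal")
  cohort$report <- map(res, "report")
  cohort
}
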