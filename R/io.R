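# On-disk record layout: one CSV per record with columns (timestamp_s, ecg)
# plus a YAML sidecar holding the subject metadata. Real device exports (e.g.
# a timestamped single-lead CSV from a chest-strap recorder) can be adapted by
# renaming their columns to this layout and writing the sidecar by hand.

#' Write a cohort to a directory
#'
#' Each record becomes `<subject_id>.csv` (columns `timestamp_s`, `ecg`) and
#' `<subject_id>.yaml` (subject id, age, gender, VAS score, class label,
#' sampling rate).
#'
#' @param cohort A `fatigue_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(is.data.frame(cohort) && "ecg" %in% names(cohort),
              "cohort must be a fatigue_cohort tibble")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    sig <- cohort$ecg[[i]]
    df <- data.frame(timestamp_s = (seq_along(sig) - 1) / cohort$fs[i], ecg = sig)
    utils::write.csv(df, file.path(dir, paste0(id, ".csv")), row.names = FALSE)
    meta <- list(subject_id = id, age = cohort$age[i], gender = cohort$gender[i],
                 vas = cohort$vas[i], class = as.character(cohort$class[i]),
                 fs = cohort$fs[i])
    yaml::write_yaml(meta, file.path(dir, paste0(id, ".yaml")))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `<id>.csv` / `<id>.yaml` pairs.
#' @return A `fatigue_cohort` tibble (without the noise-free `clean` column,
#'   which is a property of simulation only).
#' @export
read_cohort <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  assert_that(length(metas) > 0, sprintf("no record metadata found in %s", dir),
              class = "fatiguecg_invalid_input")
  rows <- map(metas, function(mf) {
    meta <- yaml::read_yaml(mf)
    sig <- utils::read.csv(sub("\\.yaml$", ".csv", mf))
    tibble(subject_id = meta$subject_id, class = meta$class,
           age = as.integer(meta$age), gender = meta$gender,
           vas = as.numeric(meta$vas), vas_trajectory = list(NULL),
           fs = as.numeric(meta$fs), n_samples = nrow(sig),
           ecg = list(sig$ecg))
  })
  out <- bind_rows(rows)
  class(out) <- c("fatigue_cohort", class(out))
  out
}
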