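# ggplot2 views of the main result types.

#' Plot ECG traces from a cohort
#'
#' @param object A `fatigue_cohort`.
#' @param subjects Subject ids (or row indices) to show.
#' @param seconds Seconds of signal from the start of each record.
#' @param ... Unused.
#' @return A ggplot object (one facet per record, colored by class).
#' @export
autoplot.fatigue_cohort <- function(object, subjects = object$subject_id[1:2],
                                    seconds = 10, ...) {
  if (is.numeric(subjects)) subjects <- object$subject_id[subjects]
  rows <- object[object$subject_id %in% subjects, ]
  df <- bind_rows(map(seq_len(nrow(rows)), function(i) {
    n <- min(length(rows$ecg[[i]]), round(seconds * rows$fs[i]))
    tibble(subject_id = rows$subject_id[i], class = rows$class[i],
           time_s = (seq_len(n) - 1) / rows$fs[i], ecg = rows$ecg[[i]][seq_len(n)])
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$ecg, color = .data$class)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~subject_id, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "ECG (a.u.)", color = "class") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram image
#'
#' @param object A `fatigue_spectrogram` from [stft()].
#' @param ... Unused.
#' @return A ggplot raster of the model-ready (frequency x time) image.
#' @export
autoplot.fatigue_spectrogram <- function(object, ...) {
  img <- spectrogram_image(object)
  df <- expand.grid(freq_bin = seq_len(nrow(img)) - 1,
                    window = seq_len(ncol(img)) - 1)
  df$magnitude <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$freq_bin,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "window position", y = "frequency bin",
                  fill = attr(object, "spec")$scale) +
    ggplot2::theme_minimal()
}

#' Plot training curves of a fitted hybrid model
#'
#' @param object A `fatigue_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @export
autoplot.fatigue_model <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h[, c("epoch", "train_loss", "val_loss")],
                            -"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, color = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ablation table
#'
#' @param object A `fatigue_ablation`.
#' @param ... Unused.
#' @return A ggplot bar chart of held-out accuracy per feature configuration.
#' @export
autoplot.fatigue_ablation <- function(object, ...) {
  df <- as_tibble(object)
  df$model <- factor(df$model, levels = unique(df$model))
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$accuracy)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "feature configuration", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
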