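# broom-style accessors for fitted objects.

#' Tidy a fitted hybrid model's training history
#'
#' @param x A `fatigue_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`, `val_loss`,
#'   `val_accuracy`.
#' @export
tidy.fatigue_model <- function(x, ...) {
  x$history %||% tibble(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
}

#' One-row summary of a fitted hybrid model
#'
#' @param x A `fatigue_model`.
#' @param ... Unused.
#' @return One-row tibble: parameter count, epochs run, best epoch, final
#'   train loss and validation metrics, enabled branches.
#' @export
glance.fatigue_model <- function(x, ...) {
  nms <- ls(x$ctx$pars)
  n_par <- sum(vapply(nms, function(n) length(get(n, envir = x$ctx$pars)), numeric(1)))
  h <- x$history
  tibble(
    n_parameters = n_par,
    epochs = if (is.null(h)) 0L else nrow(h),
    best_epoch = x$best_epoch %||% NA_integer_,
    train_loss = if (is.null(h)) NA_real_ else tail(h$train_loss, 1),
    val_loss = if (is.null(h)) NA_real_ else tail(h$val_loss, 1),
    val_accuracy = if (is.null(h)) NA_real_ else tail(h$val_accuracy, 1),
    branches = paste(c("T", "S", "P")[c(x$config$use_T, x$config$use_S,
                                        x$config$use_P)], collapse = "+")
  )
}

#' Tidy an ablation table
#'
#' @param x A `fatigue_ablation`.
#' @param ... Unused.
#' @return The six-row tibble of per-configuration metrics (model, accuracy,
#'   F1, confusion counts).
#' @export
tidy.fatigue_ablation <- function(x, ...) {
  as_tibble(x)[, c("model", "accuracy", "f1", "macro_f1",
                   "tp", "fp", "fn", "tn", "seed")]
}

#' One-row summary of a fitted baseline
#'
#' @param x A `fatigue_baseline`.
#' @param ... Unused.
#' @return One-row tibble echoing the method and its hyperparameters.
#' @export
glance.fatigue_baseline <- function(x, ...) {
  cfg <- x$config
  base <- tibble(method = x$method, feature_source = cfg$feature_source)
  extra <- switch(x$method,
    svm = tibble(cost = cfg$cost, gamma = cfg$gamma, kernel = cfg$kernel),
    rf = tibble(num_trees = cfg$num_trees, rf_seed = cfg$rf_seed,
                max_depth = cfg$max_depth),
    cnn = tibble(n_layers = cfg$n_layers, kernel = cfg$kernel),
    tibble(depth = cfg$depth, hidden = cfg$hidden,
           bidirectional = cfg$bidirectional))
  dplyr::bind_cols(base, extra)
}
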