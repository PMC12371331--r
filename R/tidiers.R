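# broom-style verbs and ggplot2 autoplot methods for the fitted model and
# for attention maps.

#' Tidy the training history of a fitted model
#'
#' @param x An `attnddg_fit`.
#' @param ... Unused.
#' @return Per-epoch tibble: `epoch`, `train_mse`, `val_mse`, `best`.
#' @exportS3Method generics::tidy
tidy.attnddg_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x An `attnddg_fit`.
#' @param ... Unused.
#' @return Tibble with variant, sizes, epochs run, best epoch and best
#'   validation MSE.
#' @exportS3Method generics::glance
glance.attnddg_fit <- function(x, ...) {
  tibble(
    variant = x$config$variant, d_model = x$config$d_model,
    n_heads = x$config$n_heads, n_params = x$n_params,
    epochs = nrow(x$history), best_epoch = x$best_epoch,
    best_val_mse = x$best_val_mse,
    learning_rate = x$train$learning_rate
  )
}

#' Augment records with model predictions
#'
#' @param x An `attnddg_fit`.
#' @param data Record tibble.
#' @param ... Unused.
#' @return `data` with `.pred` (and `.resid` when `ddg` is present).
#' @exportS3Method generics::augment
augment.attnddg_fit <- function(x, data, ...) {
  out <- dplyr::mutate(data, .pred = predict(x, data))
  if ("ddg" %in% names(data)) out <- dplyr::mutate(out, .resid = .data$ddg - .data$.pred)
  out
}

#' Plot the training history
#'
#' @param object An `attnddg_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation MSE per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.attnddg_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                              names_to = "series", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "MSE (kcal/mol)^2", colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Tidy an attention map into long format
#'
#' @param x An `attnddg_attention_map`.
#' @param ... Unused.
#' @return Tibble: `query`, `key`, `weight` (head-averaged).
#' @exportS3Method generics::tidy
tidy.attnddg_attention_map <- function(x, ...) {
  m <- x$mean
  tibble(
    query = rep(rownames(m), times = ncol(m)),
    key = rep(colnames(m), each = nrow(m)),
    weight = as.vector(m)
  )
}

#' Heatmap of a head-averaged attention map
#'
#' @param object An `attnddg_attention_map`.
#' @param ... Unused.
#' @return A ggplot tile heatmap (queries on the y axis).
#' @exportS3Method ggplot2::autoplot
autoplot.attnddg_attention_map <- function(object, ...) {
  long <- tidy(object)
  long$query <- factor(long$query, levels = rev(rownames(object$mean)))
  long$key <- factor(long$key, levels = colnames(object$mean))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$key, y = .data$query,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "key residue", y = "query residue",
                  fill = "attention",
                  title = glue("{object$direction} ({object$variant})")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Observed versus predicted ddG scatter plot
#'
#' @param data Tibble with `ddg` and `.pred` columns (e.g. from
#'   [augment.attnddg_fit()]).
#' @return A ggplot.
#' @export
plot_ddg_scatter <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$ddg, y = .data$.pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "observed ddG (kcal/mol)",
                  y = "predicted ddG (kcal/mol)") +
    ggplot2::theme_minimal()
}
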