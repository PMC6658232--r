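#' Tidy a fitted CRF model
#'
#' @param x A `crf_model`.
#' @param type `"emission"` for label-feature weights or `"transition"`
#'   for label-pair weights.
#' @param n_top For emissions, keep the `n_top` largest-magnitude weights
#'   per label (`Inf` for all).
#' @param ... Unused.
#' @return A tibble: `label`, `feature`, `weight` (emission) or `from`,
#'   `to`, `weight` (transition).
#' @export
tidy.crf_model <- function(x, type = c("emission", "transition"),
                           n_top = 10, ...) {
  type <- match.arg(type)
  labs <- x$schema$labels
  if (type == "transition") {
    return(tidyr::expand_grid(from = labs, to = labs) |>
             dplyr::mutate(weight = as.vector(t(x$W_g))))
  }
  feats <- c(feature_names(x$index),
             if (x$d_dense > 0) sprintf("E[%d]", seq_len(x$d_dense)))
  tibble::tibble(label = rep(labs, times = ncol(x$W_f)),
                 feature = rep(feats, each = length(labs)),
                 weight = as.vector(x$W_f)) |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_max(abs(.data$weight), n = n_top, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Glance at a fitted CRF model
#'
#' @param x A `crf_model`.
#' @param ... Unused.
#' @return One-row tibble with model and training-summary columns.
#' @export
glance.crf_model <- function(x, ...) {
  tibble::tibble(n_labels = length(x$schema$labels),
                 n_features = ncol(x$W_f),
                 n_sparse = x$n_sparse, d_dense = x$d_dense,
                 epochs_trained = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_dev_macro_f1 = if (nrow(x$history) > 0 &&
                                         x$best_epoch > 0)
                   x$history$dev_macro_f1[x$best_epoch] else NA_real_,
                 final_loss = if (nrow(x$history) > 0)
                   x$history$loss[nrow(x$history)] else NA_real_)
}

#' Transition-weight heatmap of a CRF
#'
#' @param object A `crf_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crf_model <- function(object, ...) {
  d <- tidy(object, type = "transition")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = "Transition weights", x = "to label",
                  y = "from label") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Tidy a transfer bridge
#'
#' @param x A `transfer_bridge`.
#' @param ... Unused.
#' @return Tibble `target_label`, `source_label`, `weight` — the learned
#'   label-correlation matrix `W_t`.
#' @export
tidy.transfer_bridge <- function(x, ...) {
  tidyr::expand_grid(target_label = x$target_schema$labels,
                     source_label = x$source_schema$labels) |>
    dplyr::mutate(weight = as.vector(t(x$bridge_weights)))
}

#' Bridge-weight heatmap: which source label backs each target label
#'
#' @param object A `transfer_bridge`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transfer_bridge <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$source_label,
                               y = .data$target_label,
                               fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = "Label-correlation bridge weights",
                  x = "source label", y = "target label") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Tidy an embedding model
#'
#' @param x An `embedding_model`.
#' @param ... Unused.
#' @return Tibble `word`, `dimension`, `value` of the input vectors.
#' @export
tidy.embedding_model <- function(x, ...) {
  tibble::tibble(word = rep(x$vocab, times = x$dim),
                 dimension = rep(seq_len(x$dim), each = length(x$vocab)),
                 value = as.vector(x$input))
}

#' Two-component projection of an embedding vocabulary
#'
#' Plots the first two principal components of the input vectors, labeled
#' by word.
#'
#' @param object An `embedding_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding_model <- function(object, ...) {
  pc <- stats::prcomp(object$input, rank. = 2)
  d <- tibble::tibble(word = object$vocab, pc1 = pc$x[, 1], pc2 = pc$x[, 2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                  label = .data$word)) +
    ggplot2::geom_text(size = 3) +
    ggplot2::labs(title = "Embedding space (first two PCs)",
                  x = "PC1", y = "PC2")
}
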