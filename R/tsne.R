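#' Two-dimensional t-SNE embedding of the feature table
#'
#' Visualization only: the embedding is never used for clustering or
#' statistics. Runs Barnes-Hut t-SNE on the standardized 19-feature matrix
#' with a fixed seed so that the map is reproducible.
#'
#' @param ft A `hab_features` table (>= 10 neurons).
#' @param seed Integer seed (default 1).
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return Tibble with `neuron_id`, `tsne1`, `tsne2`.
#' @export
embed_tsne <- function(ft, seed = 1, perplexity = 30, ...) {
  stopifnot(inherits(ft, "hab_features"))
  x <- standardize_features(ft)
  if (nrow(x) < 10) abort("need at least 10 neurons for a t-SNE map")
  perplexity <- min(perplexity, floor((nrow(x) - 1) / 3))
  emb <- withr::with_seed(seed,
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE, ...))
  tibble::tibble(neuron_id = ft$neuron_id,
                 tsne1 = emb$Y[, 1], tsne2 = emb$Y[, 2])
}

#' Plot a t-SNE map colored by cluster
#'
#' @param embedding Output of [embed_tsne()].
#' @param labels Optional vector (or tidy tibble from [tidy.hab_gmm()])
#'   of cluster labels in the embedding's neuron order.
#' @return A ggplot object.
#' @export
plot_tsne <- function(embedding, labels = NULL) {
  df <- embedding
  if (!is.null(labels)) {
    if (is.data.frame(labels)) labels <- labels$cluster[match(df$neuron_id, labels$neuron_id)]
    df$cluster <- factor(labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$tsne1, .data$tsne2,
                                          color = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$tsne1, .data$tsne2))
  }
  p + ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}
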