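#' Cosine similarity of two feature vectors
#'
#' `a . b / (||a|| ||b||)`; errors on zero vectors.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Match clusters across two datasets
#'
#' Computes the cosine similarity between every pair of cluster centroids
#' of two fitted mixtures (in their shared standardized 19-feature space),
#' finds the optimal one-to-one assignment minimizing the total
#' dissimilarity `sum(1 - SC)` via the Hungarian algorithm, and accepts the
#' pairs whose similarity reaches the threshold (inclusive: 0.60 is kept).
#' Unequal cluster counts are handled by padding with dummy clusters at
#' dissimilarity 1; dummy pairs are dropped from the assignment.
#'
#' @param model_a,model_b `hab_gmm` fits whose feature tables share one
#'   standardization (fit the sparse PCA on the pooled data, then subset).
#' @param threshold Acceptance threshold on the similarity (default 0.6).
#' @return Object of class `hab_match`: list with `similarity`
#'   (k_a x k_b matrix), `assignment` (tibble `cluster_a`, `cluster_b`,
#'   `similarity`), `accepted` (subset with similarity >= threshold) and
#'   `threshold`.
#' @export
match_clusters <- function(model_a, model_b,
                           threshold = hab_defaults()$similarity_threshold) {
  stopifnot(inherits(model_a, "hab_gmm"), inherits(model_b, "hab_gmm"))
  sim <- centroid_similarity(model_a$means, model_b$means)
  assignment <- assign_pairs(sim)
  accepted <- assignment[assignment$similarity >= threshold, ]
  structure(list(similarity = sim, assignment = assignment,
                 accepted = accepted, threshold = threshold),
            class = "hab_match")
}

centroid_similarity <- function(ma, mb) {
  sim <- matrix(NA_real_, nrow(ma), nrow(mb))
  for (i in seq_len(nrow(ma)))
    for (j in seq_len(nrow(mb)))
      sim[i, j] <- cosine_similarity(ma[i, ], mb[j, ])
  sim
}

# Hungarian assignment on cost 1 - similarity, with dummy padding for the
# rectangular case
assign_pairs <- function(sim) {
  ka <- nrow(sim); kb <- ncol(sim)
  k <- max(ka, kb)
  cost <- matrix(1, k, k)
  cost[seq_len(ka), seq_len(kb)] <- pmax(1 - sim, 0)
  sol <- clue::solve_LSAP(cost)
  pairs <- tibble::tibble(cluster_a = seq_len(k), cluster_b = as.integer(sol))
  pairs <- pairs[pairs$cluster_a <= ka & pairs$cluster_b <= kb, ]
  pairs$similarity <- sim[cbind(pairs$cluster_a, pairs$cluster_b)]
  pairs[order(pairs$cluster_a), ]
}

#' Exhaustive assignment oracle
#'
#' Enumerates all permutations (k <= 8) and returns an assignment
#' minimizing the total dissimilarity `sum(1 - SC)`. Ties are broken by
#' lexicographic order of the permutation, deterministically. Used as the
#' independent oracle for [match_clusters()].
#'
#' @param sim Similarity matrix (square, k <= 8).
#' @return Tibble `cluster_a`, `cluster_b`, `similarity`, with attribute
#'   `"cost"`.
#' @export
brute_force_match <- function(sim) {
  k <- nrow(sim)
  stopifnot(k == ncol(sim), k <= 8)
  perms <- all_permutations(k)
  best <- NULL; best_cost <- Inf
  for (p in perms) {
    cost <- sum(1 - sim[cbind(seq_len(k), p)])
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- p }
  }
  out <- tibble::tibble(cluster_a = seq_len(k), cluster_b = best,
                        similarity = sim[cbind(seq_len(k), best)])
  attr(out, "cost") <- best_cost
  out
}

# permutations of 1..k in lexicographic order
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_permutations(k - 1)
    for (r in rest) out[[length(out) + 1]] <- c(i, setdiff(seq_len(k), i)[r])
  }
  out
}

#' @export
print.hab_match <- function(x, ...) {
  cat(sprintf("cluster matching: %d x %d, threshold %.2f\n",
              nrow(x$similarity), ncol(x$similarity), x$threshold))
  print(as.data.frame(x$assignment))
  cat(sprintf("%d of %d assigned pairs accepted\n",
              nrow(x$accepted), nrow(x$assignment)))
  invisible(x)
}

#' Tidy the accepted cluster pairs
#'
#' @param x A `hab_match`.
#' @param ... Unused.
#' @return The assignment tibble with an `accepted` flag.
#' @export
tidy.hab_match <- function(x, ...) {
  out <- x$assignment
  out$accepted <- out$similarity >= x$threshold
  out
}

#' Similarity-matrix heatmap
#'
#' @param object A `hab_match`.
#' @param ... Unused.
#' @return A ggplot heatmap of the cosine similarities with the assignment
#'   marked.
#' @export
autoplot.hab_match <- function(object, ...) {
  df <- tidyr::expand_grid(cluster_a = seq_len(nrow(object$similarity)),
                           cluster_b = seq_len(ncol(object$similarity)))
  df$similarity <- object$similarity[cbind(df$cluster_a, df$cluster_b)]
  df$assigned <- paste(df$cluster_a, df$cluster_b) %in%
    paste(object$assignment$cluster_a, object$assignment$cluster_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster_b, .data$cluster_a,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$assigned, ], shape = 1, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "cluster (dataset B)", y = "cluster (dataset A)") +
    ggplot2::theme_minimal()
}
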