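#' Sparse principal components of a histogram bank
#'
#' Extracts temporal components from a neurons-by-bins histogram matrix.
#' Each bin column is z-scored across neurons (constant columns are dropped
#' with a warning), then sparse PCA with `keep` non-zero loadings per
#' component is fitted. With `keep` equal to the number of bins the result
#' coincides with ordinary PCA.
#'
#' @param bank Numeric matrix, neurons x bins.
#' @param n_components Number of components (default 8).
#' @param keep Non-zero loadings per component; `Inf` means no sparsity.
#' @return Object of class `hab_spca`: list with `scores`
#'   (neurons x components), `loadings` (bins x components, zeros for
#'   dropped bins), `center`, `scale`, `kept_cols`, `explained_var`.
#' @export
fit_sparse_pca <- function(bank, n_components = hab_defaults()$n_components,
                           keep = hab_defaults()$spca_keep) {
  if (nrow(bank) <= n_components)
    abort("need more neurons than components for sparse PCA")
  sds <- apply(bank, 2, sd)
  kept <- sds > 0
  if (any(!kept))
    warn(sprintf("dropping %d constant histogram bins before z-scoring", sum(!kept)))
  if (sum(kept) < n_components) abort("too few non-constant bins")
  x <- scale(bank[, kept, drop = FALSE])
  kx <- min(keep, sum(kept))
  fit <- mixOmics::spca(x, ncomp = n_components, keepX = rep(kx, n_components),
                        center = TRUE, scale = FALSE)
  scores <- unname(fit$variates$X)
  load_kept <- unname(fit$loadings$X)
  loadings <- matrix(0, ncol(bank), n_components)
  loadings[kept, ] <- load_kept
  structure(list(
    scores = scores,
    loadings = loadings,
    center = attr(x, "scaled:center"),
    scale = attr(x, "scaled:scale"),
    kept_cols = kept,
    explained_var = apply(scores, 2, var)
  ), class = "hab_spca")
}

#' Project a histogram bank onto fitted sparse-PCA axes
#'
#' Applies the stored z-scoring and loadings of a [fit_sparse_pca()] result
#' to new data, so that two datasets can share one feature space.
#'
#' @param object A `hab_spca` fit.
#' @param bank New neurons-x-bins matrix with the same bin layout.
#' @return Scores matrix (neurons x components).
#' @export
predict_spca <- function(object, bank) {
  stopifnot(inherits(object, "hab_spca"))
  x <- bank[, object$kept_cols, drop = FALSE]
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  x %*% object$loadings[object$kept_cols, , drop = FALSE]
}
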