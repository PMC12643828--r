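#' Build the 19-feature table for clustering
#'
#' Combines the three scalar features (rate, CV, burst index) with the
#' first `n_components` sparse principal components of the ISI distribution
#' and of the autocorrelogram into the per-neuron feature matrix used for
#' mixture clustering. Histogram banks are optionally square-root
#' transformed (variance stabilization for the multinomial bin counts)
#' before per-bin z-scoring and sparse PCA; see the methods vignette.
#'
#' The per-column standardization parameters and the sparse-PCA fits are
#' stored so that the transform is reproducible and two datasets can be
#' embedded in a shared space (fit on the pooled data, then subset).
#'
#' @param features Output of [compute_features()]; only `included` neurons
#'   are used.
#' @param n_components Sparse-PCA rank per bank (default 8).
#' @param keep Non-zero loadings per component (default 25).
#' @param stabilize Square-root transform the banks first (default TRUE).
#' @return Object of class `hab_features`: tibble of `neuron_id` plus 19
#'   feature columns, with attributes `scaling` (means/sds used by
#'   [standardize_features()]), `spca_isi`, `spca_acg`.
#' @export
#' @examples
#' pop <- simulate_population(n_per_type = 5, duration = 60, seed = 1)
#' ft <- build_feature_table(compute_features(pop$neurons))
#' dim(ft)
build_feature_table <- function(features,
                                n_components = hab_defaults()$n_components,
                                keep = hab_defaults()$spca_keep,
                                stabilize = hab_defaults()$stabilize_banks) {
  f <- features[features$included, ]
  if (nrow(f) < 2) abort("cannot standardize a feature table with < 2 neurons")
  bi <- feature_bank(features, "isi")
  ba <- feature_bank(features, "acg")
  if (stabilize) { bi <- sqrt(bi); ba <- sqrt(ba) }
  sp_isi <- fit_sparse_pca(bi, n_components, keep)
  sp_acg <- fit_sparse_pca(ba, n_components, keep)
  tab <- tibble::tibble(neuron_id = f$neuron_id, rate = f$rate, cv = f$cv,
                        burst_index = f$burst_index)
  colnames(sp_isi$scores) <- paste0("isi_pc", seq_len(n_components))
  colnames(sp_acg$scores) <- paste0("acg_pc", seq_len(n_components))
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(sp_isi$scores),
                          tibble::as_tibble(sp_acg$scores))
  m <- as.matrix(tab[, -1])
  structure(tab,
            scaling = list(center = colMeans(m), scale = apply(m, 2, sd)),
            spca_isi = sp_isi, spca_acg = sp_acg, stabilize = stabilize,
            class = c("hab_features", class(tab)))
}

#' Standardized feature matrix of a feature table
#'
#' Returns the neurons-x-19 matrix with every column z-scored using the
#' scaling stored in the table (so subsets of a pooled table stay in the
#' pooled space).
#'
#' @param ft A `hab_features` table.
#' @param rows Optional logical or integer row subset.
#' @return Numeric matrix with rownames set to the neuron ids.
#' @export
standardize_features <- function(ft, rows = NULL) {
  stopifnot(inherits(ft, "hab_features"))
  sc <- attr(ft, "scaling")
  m <- as.matrix(ft[, -1])
  if (any(sc$scale <= 0)) abort("constant feature column; cannot standardize")
  m <- sweep(sweep(m, 2, sc$center), 2, sc$scale, "/")
  rownames(m) <- ft$neuron_id
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

#' Subset a feature table, keeping the shared scaling
#'
#' @param ft A `hab_features` table.
#' @param idx Logical or integer row index.
#' @return A `hab_features` table with the parent's scaling and sPCA fits.
#' @export
subset_features <- function(ft, idx) {
  stopifnot(inherits(ft, "hab_features"))
  out <- ft[idx, ]
  for (a in c("scaling", "spca_isi", "spca_acg", "stabilize"))
    attr(out, a) <- attr(ft, a)
  class(out) <- class(ft)
  out
}
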