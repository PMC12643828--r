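#' Bayesian information criterion
#'
#' `BIC = -2 log L + M log N` with natural logarithms; smaller is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters M.
#' @param n_obs Number of observations N (>= 1).
#' @return The BIC value.
#' @export
#' @examples
#' compute_bic(-100, 10, 50)  # 200 + 10 * log(50)
compute_bic <- function(loglik, n_params, n_obs) {
  stopifnot(n_obs >= 1)
  -2 * loglik + n_params * log(n_obs)
}

# free-parameter count of a k-component mixture in d dimensions
gmm_n_params <- function(k, d, covariance = c("full", "diagonal")) {
  covariance <- match.arg(covariance)
  (k - 1) + k * d + switch(covariance, full = k * d * (d + 1) / 2, diagonal = k * d)
}

# EM for a Gaussian mixture from an initial responsibility matrix.
# A small ridge keeps component covariances invertible; fits whose
# Cholesky still fails are reported as non-converged (NULL).
em_gmm <- function(x, z, reg = 1e-6, covariance = "full",
                   max_iter = 200L, tol = 1e-5) {
  n <- nrow(x); d <- ncol(x); k <- ncol(z)
  ll_old <- -Inf; ll <- -Inf
  w <- NULL; mu <- NULL; sig <- NULL
  for (it in seq_len(max_iter)) {
    nk <- pmax(colSums(z), 1e-8)
    w <- nk / n
    mu <- crossprod(z, x) / nk
    logdens <- matrix(0, n, k)
    sig <- vector("list", k)
    for (j in seq_len(k)) {
      xc <- sweep(x, 2, mu[j, ])
      s <- crossprod(xc * z[, j], xc) / nk[j]
      if (covariance == "diagonal") s <- diag(diag(s), d)
      s <- s + diag(reg, d)
      ch <- tryCatch(chol(s), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      sig[[j]] <- s
      v <- backsolve(ch, t(xc), transpose = TRUE)
      logdens[, j] <- -0.5 * colSums(v^2) - sum(log(diag(ch))) -
        0.5 * d * log(2 * pi) + log(w[j])
    }
    mx <- apply(logdens, 1, max)
    ll <- sum(mx + log(rowSums(exp(logdens - mx))))
    z <- exp(logdens - mx - log(rowSums(exp(logdens - mx))))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(loglik = ll, z = z, weights = w, means = mu, covariances = sig,
       iterations = it)
}

one_hot <- function(cl, k) {
  z <- matrix(0, length(cl), k)
  z[cbind(seq_along(cl), cl)] <- 1
  z
}

#' Fit a Gaussian mixture at fixed k with random restarts
#'
#' Runs `n_restarts` EM fits from k-means initializations of the
#' standardized 19-feature matrix and keeps the best-BIC solution. The
#' per-restart BIC values are retained for the model-selection curve.
#'
#' @param ft A `hab_features` table.
#' @param k Number of mixture components.
#' @param n_restarts Restarts (default 100).
#' @param seed Optional integer seed controlling all initializations.
#' @param reg Ridge added to component covariances (default 1e-6).
#' @param covariance `"full"` (default) or `"diagonal"`.
#' @return A `hab_gmm` object; see [select_k()] for the fields.
#' @export
fit_gmm <- function(ft, k, n_restarts = hab_defaults()$n_restarts, seed = NULL,
                    reg = hab_defaults()$gmm_reg,
                    covariance = c("full", "diagonal")) {
  covariance <- match.arg(covariance)
  x <- standardize_features(ft)
  run <- function() fit_gmm_matrix(x, k, n_restarts, reg, covariance)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (is.null(res)) abort(sprintf("no EM restart converged at k = %d", k))
  new_hab_gmm(res, ft, k, covariance)
}

fit_gmm_matrix <- function(x, k, n_restarts, reg, covariance) {
  n <- nrow(x); d <- ncol(x)
  m_par <- gmm_n_params(k, d, covariance)
  bics <- rep(NA_real_, n_restarts)
  best <- NULL; best_ll <- -Inf
  for (r in seq_len(n_restarts)) {
    cl <- if (k == 1) rep(1L, n) else
      tryCatch(kmeans(x, k, iter.max = 30)$cluster,
               error = function(e) sample.int(k, n, replace = TRUE))
    fit <- em_gmm(x, one_hot(cl, k), reg, covariance)
    if (is.null(fit) || !is.finite(fit$loglik)) next
    bics[r] <- compute_bic(fit$loglik, m_par, n)
    if (fit$loglik > best_ll) { best_ll <- fit$loglik; best <- fit }
  }
  if (is.null(best)) return(NULL)
  list(fit = best, bics = bics[!is.na(bics)], n_params = m_par)
}

new_hab_gmm <- function(res, ft, k, covariance,
                        bic_table = NULL, k_grid = NULL) {
  fit <- res$fit
  labels <- apply(fit$z, 1, which.max)
  structure(list(
    k = k,
    covariance = covariance,
    weights = fit$weights,
    means = fit$means,                  # standardized feature space
    covariances = fit$covariances,
    loglik = fit$loglik,
    bic = compute_bic(fit$loglik, res$n_params, nrow(fit$z)),
    responsibilities = fit$z,
    labels = labels,
    neuron_id = ft$neuron_id,
    feature_names = colnames(ft)[-1],
    features = ft,
    bic_table = bic_table,
    k_grid = k_grid
  ), class = "hab_gmm")
}

#' Select the number of clusters by mean BIC and gradient saturation
#'
#' For every candidate k, fits `n_restarts` mixtures from random k-means
#' initializations and records each restart's BIC. The selected k is the
#' smallest candidate whose mean BIC is either the grid minimum or whose
#' gradient has saturated: `|mean BIC(k) - mean BIC(k+1)|` below
#' `saturation` times the initial drop `|mean BIC(1) - mean BIC(2)|`.
#' Final labels come from the best-BIC restart at the selected k.
#'
#' @param ft A `hab_features` table.
#' @param k_grid Candidate cluster numbers (default 1:6); must stay within
#'   `n_neurons / 10`.
#' @param n_restarts Restarts per candidate (default 100).
#' @param seed Integer seed for the whole procedure.
#' @param saturation Gradient-saturation fraction (default 0.1).
#' @param reg,covariance Passed to the EM fits.
#' @return A `hab_gmm` with the selected-k fit plus `bic_table` (mean BIC
#'   and normal-theory 95% CI per k) and `k_grid`.
#' @export
#' @examples
#' \donttest{
#' pop <- simulate_population(n_per_type = 25, duration = 60, seed = 1)
#' ft <- build_feature_table(compute_features(pop$neurons))
#' mod <- select_k(ft, k_grid = 1:5, n_restarts = 20, seed = 1)
#' mod$k
#' }
select_k <- function(ft, k_grid = hab_defaults()$k_grid,
                     n_restarts = hab_defaults()$n_restarts, seed = NULL,
                     saturation = hab_defaults()$bic_saturation,
                     reg = hab_defaults()$gmm_reg,
                     covariance = c("full", "diagonal")) {
  covariance <- match.arg(covariance)
  x <- standardize_features(ft)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (max(k_grid) > nrow(x) / 10)
    abort("k_grid must stay within n_neurons / 10")
  run <- function() {
    fits <- vector("list", length(k_grid))
    for (i in seq_along(k_grid)) {
      fits[[i]] <- fit_gmm_matrix(x, k_grid[i], n_restarts, reg, covariance)
      if (is.null(fits[[i]]))
        warn(sprintf("no restart converged at k = %d; skipping", k_grid[i]))
    }
    fits
  }
  fits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("no candidate k produced a converged fit")
  bic_mean <- vapply(fits, function(f)
    if (is.null(f)) NA_real_ else mean(f$bics), numeric(1))
  bic_ci <- t(vapply(fits, function(f) {
    if (is.null(f)) return(c(NA_real_, NA_real_))
    m <- mean(f$bics); s <- sd(f$bics) / sqrt(length(f$bics))
    c(m - 1.96 * s, m + 1.96 * s)
  }, numeric(2)))
  sel_idx <- pick_saturated_k(bic_mean, saturation)
  bic_table <- tibble::tibble(
    k = k_grid, bic_mean = bic_mean,
    bic_lo = bic_ci[, 1], bic_hi = bic_ci[, 2],
    n_converged = vapply(fits, function(f)
      if (is.null(f)) 0L else length(f$bics), integer(1))
  )
  new_hab_gmm(fits[[sel_idx]], ft, k_grid[sel_idx], covariance,
              bic_table = bic_table, k_grid = k_grid)
}

# smallest k that is the grid minimum or whose forward gradient has
# saturated relative to the initial drop
pick_saturated_k <- function(bic_mean, saturation) {
  ok <- which(!is.na(bic_mean))
  kmin <- ok[which.min(bic_mean[ok])]
  d <- diff(bic_mean)
  ref <- abs(d[which(!is.na(d))[1]])
  for (i in seq_along(bic_mean)) {
    if (is.na(bic_mean[i])) next
    if (i == kmin) return(i)
    if (i < length(bic_mean) && !is.na(d[i]) && abs(d[i]) < saturation * ref)
      return(i)
  }
  kmin
}

#' Per-feature cluster importance
#'
#' Importance of feature j for cluster c is the absolute difference between
#' the cluster mean and the global mean of that feature, in standardized
#' units. Empty clusters get a zero row with a warning.
#'
#' @param model A `hab_gmm`.
#' @return A k x 19 matrix (clusters x features).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "hab_gmm"))
  x <- standardize_features(model$features)
  g <- colMeans(x)
  imp <- matrix(0, model$k, ncol(x),
                dimnames = list(NULL, model$feature_names))
  for (c in seq_len(model$k)) {
    idx <- model$labels == c
    if (!any(idx)) { warn(sprintf("cluster %d is empty", c)); next }
    imp[c, ] <- abs(colMeans(x[idx, , drop = FALSE]) - g)
  }
  imp
}

#' Relabel clusters by ascending mean firing rate
#'
#' Renames cluster labels so that label 1 is the lowest-rate cluster
#' (matching the Type-1..4 convention); ties are broken by ascending burst
#' index.
#'
#' @param model A `hab_gmm`.
#' @return The relabeled `hab_gmm`.
#' @export
order_clusters <- function(model) {
  stopifnot(inherits(model, "hab_gmm"))
  ft <- model$features
  rate <- vapply(seq_len(model$k), function(c) {
    idx <- model$labels == c
    if (!any(idx)) Inf else mean(ft$rate[idx])
  }, numeric(1))
  burst <- vapply(seq_len(model$k), function(c) {
    idx <- model$labels == c
    if (!any(idx)) Inf else mean(ft$burst_index[idx])
  }, numeric(1))
  ord <- order(rate, burst)
  relab <- match(seq_len(model$k), ord)
  model$labels <- relab[model$labels]
  model$weights <- model$weights[ord]
  model$means <- model$means[ord, , drop = FALSE]
  model$covariances <- model$covariances[ord]
  model$responsibilities <- model$responsibilities[, ord, drop = FALSE]
  model
}

#' @export
print.hab_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d (%s covariance), n = %d neurons\n",
              x$k, x$covariance, length(x$labels)))
  cat(sprintf("log-likelihood %.1f, BIC %.1f\n", x$loglik, x$bic))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Tidy per-neuron cluster assignments
#'
#' @param x A `hab_gmm`.
#' @param ... Unused.
#' @return Tibble with `neuron_id`, `cluster`, `posterior` (probability of
#'   the assigned cluster).
#' @export
tidy.hab_gmm <- function(x, ...) {
  tibble::tibble(
    neuron_id = x$neuron_id,
    cluster = x$labels,
    posterior = x$responsibilities[cbind(seq_along(x$labels), x$labels)]
  )
}

#' One-row model summary
#'
#' @param x A `hab_gmm`.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `loglik`, `bic`, `covariance`.
#' @export
glance.hab_gmm <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels), loglik = x$loglik,
                 bic = x$bic, covariance = x$covariance)
}

#' BIC model-selection curve
#'
#' @param object A `hab_gmm` produced by [select_k()].
#' @param ... Unused.
#' @return A ggplot of mean BIC (with restart CIs) against k.
#' @export
autoplot.hab_gmm <- function(object, ...) {
  if (is.null(object$bic_table)) abort("model has no BIC table; use select_k()")
  ggplot2::ggplot(object$bic_table, ggplot2::aes(x = .data$k, y = .data$bic_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$bic_lo, ymax = .data$bic_hi),
                           width = 0.15) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(x = "number of clusters", y = "mean BIC over restarts") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
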