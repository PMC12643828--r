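#' Compare a per-neuron quantity across cluster types
#'
#' One-way ANOVA followed by Tukey's HSD over all unordered type pairs.
#' Groups with a single member are dropped with a warning.
#'
#' @param values Numeric per-neuron vector.
#' @param labels Cluster/type labels, same length.
#' @param conf_level Confidence level for the Tukey intervals.
#' @return Object of class `hab_comparison`: list with `anova_p`, `groups`
#'   (per-group n/mean/sd) and `pairwise` (tibble of mean differences,
#'   CIs and adjusted p per pair).
#' @export
#' @examples
#' compare_across_types(c(rnorm(20), rnorm(20, 2)), rep(1:2, each = 20))
compare_across_types <- function(values, labels, conf_level = 0.95) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  cnt <- table(labels)
  single <- names(cnt)[cnt < 2]
  if (length(single)) {
    warn(paste0("dropping single-member group(s): ", paste(single, collapse = ", ")))
    sel <- !labels %in% single
    values <- values[sel]; labels <- labels[sel]
  }
  if (length(unique(labels)) < 2) abort("need >= 2 groups with n >= 2")
  g <- factor(labels)
  fit <- aov(values ~ g)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = conf_level)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- tibble::tibble(
    group_1 = pairs[, 2], group_2 = pairs[, 1],
    diff = tk[, "diff"], conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    adj_p = tk[, "p adj"]
  )
  groups <- tibble::tibble(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(values, g, mean)),
    sd = as.numeric(tapply(values, g, sd))
  )
  structure(list(anova_p = p, groups = groups, pairwise = pairwise),
            class = "hab_comparison")
}

#' @export
print.hab_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: p = %.3g\n", x$anova_p))
  print(as.data.frame(x$pairwise), digits = 3)
  invisible(x)
}

#' Tidy the pairwise Tukey comparisons
#'
#' @param x A `hab_comparison`.
#' @param ... Unused.
#' @return The pairwise tibble.
#' @export
tidy.hab_comparison <- function(x, ...) x$pairwise

#' @export
glance.hab_comparison <- function(x, ...) {
  tibble::tibble(anova_p = x$anova_p, n_groups = nrow(x$groups),
                 n = sum(x$groups$n))
}

#' Pearson correlation between two per-neuron quantities
#'
#' @param x,y Numeric vectors (n >= 3 finite pairs).
#' @return Tibble with `estimate`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Population-level state effect
#'
#' Paired signed-rank test across neurons on (active, quiet) firing rates,
#' reporting both means.
#'
#' @param records Tibble from [state_modulation()] (needs `fr_active`,
#'   `fr_quiet`).
#' @return Tibble with `p_value`, `mean_active`, `mean_quiet`, `n`.
#' @export
population_state_test <- function(records) {
  keep <- is.finite(records$fr_active) & is.finite(records$fr_quiet)
  a <- records$fr_active[keep]; q <- records$fr_quiet[keep]
  if (!length(a)) abort("no neurons with both state rates")
  p <- if (isTRUE(all.equal(a, q))) 1 else
    suppressWarnings(wilcox.test(a, q, paired = TRUE,
                                 exact = length(a) < 6)$p.value)
  tibble::tibble(p_value = p, mean_active = mean(a), mean_quiet = mean(q),
                 n = length(a))
}

#' Per-type summary tables and mean curves
#'
#' Mean and SD of the scalar features per cluster type, the per-type counts
#' and the per-type mean ISI histogram and autocorrelogram.
#'
#' @param features Output of [compute_features()].
#' @param labels Tidy label tibble ([tidy.hab_gmm()]) or a vector in the
#'   feature-row order of included neurons.
#' @return List with `scalars` (per-type mean+-SD tibble), `isi` and `acg`
#'   (per-type mean curves, long tibbles).
#' @export
summarize_types <- function(features, labels) {
  f <- features[features$included, ]
  lab <- if (is.data.frame(labels))
    labels$cluster[match(f$neuron_id, labels$neuron_id)] else labels
  stopifnot(length(lab) == nrow(f))
  scalars <- f |>
    dplyr::mutate(type = lab) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(c("rate", "cv", "burst_index"),
                    list(mean = mean, sd = sd)),
      .groups = "drop")
  curve <- function(which, valcol) {
    purrr::map_dfr(sort(unique(lab)), function(ty) {
      hs <- f[[which]][lab == ty]
      m <- rowMeans(do.call(cbind, lapply(hs, function(h) h[[valcol]])))
      tibble::tibble(type = ty, x = hs[[1]][[1]], mean = m)
    })
  }
  list(scalars = scalars,
       isi = curve("isi", "mass"),
       acg = curve("acg", "count_per_spike"))
}
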