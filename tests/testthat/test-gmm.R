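test_that("BIC follows the definition with natural logs", {
  expect_equal(compute_bic(-100, 10, 50), 200 + 10 * log(50))
  expect_equal(compute_bic(-55.5, 0, 50), 111)
  expect_equal(compute_bic(-55.5, 10, 1), 111)
})

test_that("feature tables have 19 columns and shared standardization", {
  pop <- simulate_population(n_per_type = 8, duration = 60, seed = 2)
  ft <- build_feature_table(compute_features(pop$neurons))
  expect_equal(ncol(ft) - 1, 19)
  x <- standardize_features(ft)
  expect_equal(unname(colMeans(x)), rep(0, 19), tolerance = 1e-10)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 19), tolerance = 1e-10)
  # a subset keeps the parent scaling: its columns are not re-centered
  sub <- subset_features(ft, 1:10)
  xs <- standardize_features(sub)
  expect_equal(xs, x[1:10, ])
  # single neuron cannot be standardized
  fe1 <- compute_features(pop$neurons[1, ])
  expect_error(build_feature_table(fe1), "< 2 neurons")
})

test_that("the EM engine agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(11, {
    x <- rbind(matrix(rnorm(60 * 3), 60, 3),
               matrix(rnorm(60 * 3, mean = 4), 60, 3))
    cl <- kmeans(x, 2)$cluster
  })
  z0 <- habclust:::one_hot(cl, 2)
  ours <- habclust:::em_gmm(x, z0, reg = 0, tol = 1e-9)
  theirs <- mclust::meVVV(data = x, z = z0)
  expect_equal(ours$loglik, theirs$loglik, tolerance = 1e-4)
  expect_equal(apply(ours$z, 1, which.max), apply(theirs$z, 1, which.max))
})

test_that("model selection finds the planted component count on Gaussian blobs", {
  # two blobs separated by 10 SD along the diagonal; the diagonal-covariance
  # variant is used because a full 19-d covariance can absorb a split along
  # a single direction more cheaply than the 210-parameter penalty
  withr::with_seed(12, {
    x <- rbind(matrix(rnorm(100 * 19), 100, 19),
               matrix(rnorm(100 * 19, mean = 10 / sqrt(19)), 100, 19))
  })
  ft <- fake_feature_table(x)
  mod2 <- select_k(ft, k_grid = 1:4, n_restarts = 15, seed = 13,
                   covariance = "diagonal")
  expect_equal(mod2$k, 2)
  lab <- rep(1:2, each = 100)
  expect_gt(adjusted_rand_index(mod2$labels, lab), 0.95)
  # a single blob stays one component (both covariance structures)
  withr::with_seed(14, x1 <- matrix(rnorm(150 * 19), 150, 19))
  mod1 <- select_k(fake_feature_table(x1), k_grid = 1:3, n_restarts = 15, seed = 15)
  expect_equal(mod1$k, 1)
  mod1d <- select_k(fake_feature_table(x1), k_grid = 1:3, n_restarts = 15,
                    seed = 16, covariance = "diagonal")
  expect_equal(mod1d$k, 1)
})

test_that("cluster labels and BIC table are reproducible from the seed", {
  pop <- simulate_population(n_per_type = 10, duration = 60, seed = 3)
  ft <- build_feature_table(compute_features(pop$neurons))
  a <- select_k(ft, k_grid = 1:3, n_restarts = 8, seed = 42)
  b <- select_k(ft, k_grid = 1:3, n_restarts = 8, seed = 42)
  expect_identical(a$labels, b$labels)
  expect_equal(a$bic_table, b$bic_table)
})

test_that("feature importance is |cluster mean - global mean| with symmetry", {
  # two groups differing on one feature only; the model is assembled
  # directly so the property of the importance computation is isolated
  # from the mixture fit
  withr::with_seed(16, {
    x <- matrix(rnorm(120 * 19), 120, 19)
    x[1:60, 5] <- x[1:60, 5] + 8
  })
  ft <- fake_feature_table(x)
  lab <- rep(1:2, each = 60)
  mod <- structure(list(k = 2, labels = lab, features = ft,
                        feature_names = colnames(ft)[-1]),
                   class = "hab_gmm")
  imp <- feature_importance(mod)
  expect_equal(dim(imp), c(2, 19))
  expect_true(all(imp >= 0))
  expect_true(all(apply(imp, 1, which.max) == 5))
  # relabeling permutes the rows, nothing else
  mod_swap <- mod
  mod_swap$labels <- 3 - lab
  expect_equal(feature_importance(mod_swap), imp[2:1, ], tolerance = 1e-12)
  # cluster mean equal to the global mean -> importance ~ 0 for that feature
  expect_lt(max(imp[, 10]), 0.5)
  # empty cluster -> zero row with a warning
  mod_empty <- mod
  mod_empty$k <- 3
  expect_warning(imp3 <- feature_importance(mod_empty), "empty")
  expect_equal(imp3[3, ], setNames(rep(0, 19), colnames(ft)[-1]))
})

test_that("clusters are relabeled by ascending firing rate", {
  pop <- simulate_population(n_per_type = 12, duration = 60, seed = 5)
  ft <- build_feature_table(compute_features(pop$neurons))
  mod <- order_clusters(fit_gmm(ft, 4, n_restarts = 20, seed = 6))
  rate_by <- tapply(ft$rate, mod$labels, mean)
  expect_true(all(diff(rate_by) > 0))
  # idempotent
  expect_identical(order_clusters(mod)$labels, mod$labels)
})

test_that("tidy and glance expose assignments and fit summary", {
  pop <- simulate_population(n_per_type = 8, duration = 60, seed = 7)
  ft <- build_feature_table(compute_features(pop$neurons))
  mod <- fit_gmm(ft, 2, n_restarts = 5, seed = 8)
  td <- tidy(mod)
  expect_equal(nrow(td), nrow(ft))
  expect_true(all(td$cluster %in% 1:2))
  expect_true(all(td$posterior > 0.5 - 1e-9))
  gl <- glance(mod)
  expect_equal(gl$k, 2)
  expect_s3_class(autoplot(select_k(ft, k_grid = 1:2, n_restarts = 4, seed = 9)),
                  "ggplot")
})

test_that("t-SNE maps are deterministic, 2-d, and keep duplicates together", {
  pop <- simulate_population(n_per_type = 10, duration = 60, seed = 10)
  ft <- build_feature_table(compute_features(pop$neurons))
  e1 <- embed_tsne(ft, seed = 1)
  e2 <- embed_tsne(ft, seed = 1)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(nrow(ft), 3L))
  # duplicated feature rows land closer than typical point pairs
  ftd <- subset_features(ft, c(seq_len(nrow(ft)), 1L))
  ftd$neuron_id[nrow(ftd)] <- "dup"
  ed <- embed_tsne(ftd, seed = 2)
  d_dup <- sqrt(sum((ed[nrow(ed), 2:3] - ed[1, 2:3])^2))
  xy <- as.matrix(ed[, 2:3])
  d_med <- stats::median(dist(xy))
  expect_lt(d_dup, d_med / 4)
})
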