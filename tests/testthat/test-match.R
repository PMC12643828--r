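test_that("cosine similarity matches hand arithmetic and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), sqrt(2) / 2)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("matching a model against its own relabeling recovers the permutation", {
  pop <- simulate_population(n_per_type = 12, duration = 60, seed = 20)
  ft <- build_feature_table(compute_features(pop$neurons))
  mod <- fit_gmm(ft, 4, n_restarts = 20, seed = 21)
  perm <- c(3, 1, 4, 2)
  shuf <- mod
  shuf$means <- mod$means[perm, , drop = FALSE]
  shuf$covariances <- mod$covariances[perm]
  shuf$weights <- mod$weights[perm]
  mt <- match_clusters(mod, shuf)
  # pair (a, b) must satisfy perm[b] == a
  expect_true(all(perm[mt$assignment$cluster_b] == mt$assignment$cluster_a))
  expect_true(all(mt$assignment$similarity > 1 - 1e-9))
  # self-match is the identity with all similarities 1
  self <- match_clusters(mod, mod)
  expect_equal(self$assignment$cluster_b, self$assignment$cluster_a)
  expect_true(all(abs(self$assignment$similarity - 1) < 1e-12))
})

test_that("the acceptance threshold is inclusive and filters, not reassigns", {
  mod <- structure(list(means = diag(3), k = 3), class = "hab_gmm")
  other <- structure(list(means = diag(3) * 2, k = 3), class = "hab_gmm")
  mt <- match_clusters(mod, other, threshold = 1)  # SC exactly 1 kept
  expect_equal(nrow(mt$accepted), 3)
  # orthogonal centroids: assignment still complete, nothing accepted
  rot <- structure(list(means = diag(3)[c(2, 3, 1), ], k = 3), class = "hab_gmm")
  mt2 <- match_clusters(mod, structure(list(means = 0.5 * diag(3) + 0.1,
                                            k = 3), class = "hab_gmm"),
                        threshold = 0.999)
  expect_equal(nrow(mt2$assignment), 3)
  expect_lt(nrow(mt2$accepted), 3)
  expect_true(all(mt2$accepted$similarity >= 0.999))
  rm(rot)
})

test_that("scale invariance: rescaling one model's centroids leaves similarities unchanged", {
  withr::with_seed(22, m <- matrix(rnorm(4 * 19), 4, 19))
  a <- structure(list(means = m, k = 4), class = "hab_gmm")
  b <- structure(list(means = m[c(2, 1, 4, 3), ] * 7.3, k = 4), class = "hab_gmm")
  b0 <- structure(list(means = m[c(2, 1, 4, 3), ], k = 4), class = "hab_gmm")
  expect_equal(match_clusters(a, b)$similarity, match_clusters(a, b0)$similarity,
               tolerance = 1e-12)
})

test_that("rectangular matching leaves surplus clusters unmatched", {
  withr::with_seed(23, {
    ma <- matrix(rnorm(5 * 19), 5, 19)
  })
  a <- structure(list(means = ma, k = 5), class = "hab_gmm")
  b <- structure(list(means = ma[c(4, 2, 5), ], k = 3), class = "hab_gmm")
  mt <- match_clusters(a, b)
  expect_equal(nrow(mt$assignment), 3)
  expect_true(all(mt$assignment$cluster_a == c(4, 2, 5)[mt$assignment$cluster_b]))
})

test_that("Hungarian assignment cost equals the brute-force permutation oracle", {
  withr::with_seed(24, {
    for (i in 1:200) {
      k <- sample(1:6, 1)
      sim <- matrix(runif(k * k, -1, 1), k, k)
      a <- structure(list(means = diag(k), k = k), class = "hab_gmm")
      pairs <- habclust:::assign_pairs(sim)
      oracle <- brute_force_match(sim)
      expect_equal(sum(1 - pairs$similarity), attr(oracle, "cost"),
                   tolerance = 1e-10)
    }
  })
  # 1 x 1 trivially pairs the single clusters
  o <- brute_force_match(matrix(0.4, 1, 1))
  expect_equal(o$cluster_b, 1L)
  # exact tie: deterministic lexicographic winner
  tie <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  o2 <- brute_force_match(tie)
  expect_equal(o2$cluster_b, c(1L, 2L))
})
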