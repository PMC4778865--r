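test_that("monotone regression pools violators and keeps sorted input", {
  expect_equal(monotone_regression(c(1, 2, 3), c(0.1, 0.2, 0.3)), c(1, 2, 3))
  expect_equal(monotone_regression(c(3, 1), c(0.2, 0.7)), c(2, 2))
  expect_error(monotone_regression(1:3, 1:2), "length")
})

test_that("monotone regression agrees with the isotonic-regression oracle", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    delta <- sort(stats::runif(k)) # strictly increasing: no tie handling
    d <- stats::runif(k, 0, 3)
    fit <- monotone_regression(d, delta)
    oracle <- stats::isoreg(seq_len(k), d)$yf
    expect_equal(fit, oracle, tolerance = 1e-9)
  }
})

test_that("stress1 is zero for rank-consistent configurations", {
  set.seed(11)
  X <- matrix(stats::runif(40), 20, 2)
  d <- euclidean_dissim(X)
  expect_lt(stress1(X, d), 1e-6)
  expect_error(stress1(matrix(0, 20, 2), d), "degenerate")
})

test_that("stress1 is invariant to similarity transforms of the configuration", {
  set.seed(12)
  X <- matrix(stats::runif(30), 15, 2)
  d <- jaccard_dissimilarity(random_occurrence(15, 25))
  s0 <- stress1(X, d)
  for (k in 1:5) {
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    if (k %% 2 == 0) R[, 1] <- -R[, 1] # reflection
    Y <- sweep(X %*% R * stats::runif(1, 0.1, 5), 2, stats::rnorm(2), "+")
    expect_equal(stress1(Y, d), s0, tolerance = 1e-9)
  }
})

test_that("nmds recovers a planted two-dimensional configuration", {
  set.seed(21)
  X <- matrix(stats::runif(40), 20, 2)
  d <- euclidean_dissim(X)
  fit <- nmds(d, ordination_config("nmds", seed = 3))
  expect_lt(fit$stress, 0.01)
  diam <- max(stats::dist(X))
  expect_lt(procrustes_rmse(X, fit$coordinates), 0.05 * diam)
})

test_that("nmds honours its determinism and minimum-stress contracts", {
  set.seed(31)
  d <- jaccard_dissimilarity(random_occurrence(18, 30))
  cfg <- ordination_config("nmds", seed = 99)
  a <- nmds(d, cfg)
  b <- nmds(d, cfg)
  expect_identical(a$coordinates, b$coordinates)
  expect_identical(a$stress, b$stress)
  expect_equal(a$stress, min(a$start_stresses))
  expect_equal(unname(colMeans(a$coordinates)), c(0, 0), tolerance = 1e-8)
  # per-start stress traces are non-increasing (up to tolerance)
  for (tr in a$traces) {
    tr <- tr[is.finite(tr)]
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("three sites always embed almost perfectly", {
  set.seed(41)
  for (rep in 1:5) {
    m <- random_occurrence(3, 12)
    d <- jaccard_dissimilarity(m)
    fit <- nmds(d, ordination_config("nmds", seed = rep))
    expect_lt(fit$stress, 1e-3)
  }
})

test_that("hmds reduces to nmds when the metric term is switched off", {
  set.seed(51)
  d <- jaccard_dissimilarity(random_occurrence(15, 25))
  cfg_n <- ordination_config("nmds", seed = 7)
  cfg_h <- ordination_config("hmds", seed = 7, hybrid_threshold = 1,
                             metric_weight = 0)
  expect_identical(hmds(d, cfg_h)$coordinates, nmds(d, cfg_n)$coordinates)
})

test_that("hmds handles euclidean and saturated dissimilarities", {
  set.seed(61)
  X <- matrix(stats::runif(40), 20, 2)
  fit <- hmds(euclidean_dissim(X), ordination_config("hmds", seed = 5))
  expect_lt(fit$stress, 0.01)
  # ~30% of pairs exactly at 1 (disjoint assemblages)
  m <- random_occurrence(20, 40, fill = 0.15)
  d <- jaccard_dissimilarity(m)
  expect_gt(mean(as.numeric(d) == 1), 0.1)
  fit2 <- hmds(d, ordination_config("hmds", seed = 5))
  expect_true(is.finite(fit2$stress))
  # threshold below every dissimilarity: warns and behaves as pure nmds
  d1 <- d
  d1[] <- pmax(as.numeric(d), 0.95)
  expect_warning(hmds(d1, ordination_config("hmds", seed = 5,
                                            hybrid_threshold = 0.2)),
                 "reduces to nmds")
})

test_that("best_ordination returns the lower-stress method, ties to nmds", {
  set.seed(71)
  d <- jaccard_dissimilarity(random_occurrence(20, 35, fill = 0.25))
  res <- best_ordination(d, seed = 13)
  cs <- res$candidate_stresses
  expect_identical(res$method,
                   if (cs[["hmds"]] < cs[["nmds"]]) "hmds" else "nmds")
  expect_equal(stress1(res$coordinates, d), min(cs), tolerance = 1e-12)
})

test_that("stress agrees with an independent NMDS implementation", {
  set.seed(81)
  m <- random_occurrence(40, 60, fill = 0.3)
  d <- jaccard_dissimilarity(m)
  mine <- nmds(d, ordination_config("nmds", seed = 17))
  ref <- vegan::monoMDS(d, k = 2, model = "global", maxit = 1000)
  expect_lt(abs(mine$stress - ref$stress), 0.02)
})

test_that("ordination configs validate their domains", {
  expect_error(ordination_config("nmds", n_dims = 3), "2-dimensional")
  expect_error(ordination_config("nmds", n_starts = 0))
  expect_error(ordination_config("hmds", hybrid_threshold = 0))
})
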