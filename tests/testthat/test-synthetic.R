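test_that("occurrence probability follows the Gaussian niche surface", {
  truth <- list(mu = matrix(0.4, 1, 2), sigma = matrix(0.1, 1, 2), h = 0.5)
  env <- rbind(c(0.4, 0.4), c(0.5, 0.4))
  pi_mat <- betasai:::occurrence_probability(env, truth)
  expect_equal(pi_mat[1, 1], 0.5) # at the optimum the peak value h
  expect_equal(pi_mat[2, 1], 0.5 * exp(-0.5), tolerance = 1e-12)
  # enormous tolerance and h = 1: presence everywhere
  com <- generate_unimodal(20, 10, niche = niche_spec(sigma_range = c(1e6, 1e6),
                                                      h_range = c(1, 1)),
                           seed = 4)
  expect_true(all(com$occurrences))
})

test_that("unimodality: a single probability maximum at the niche optimum", {
  truth <- list(mu = matrix(c(0.3, 0.6), 1, 2),
                sigma = matrix(c(0.1, 0.2), 1, 2), h = 0.8)
  gr <- as.matrix(expand.grid(seq(0, 1, length.out = 21),
                              seq(0, 1, length.out = 21)))
  pi_g <- betasai:::occurrence_probability(gr, truth)[, 1]
  top <- gr[which.max(pi_g), ]
  expect_lt(max(abs(top - c(0.3, 0.6))), 0.03)
  expect_equal(sum(pi_g > 0.99 * max(pi_g)), 1)
})

test_that("Monte-Carlo occupancy matches the analytic niche mass", {
  com <- generate_unimodal(10000, 3, seed = 77)
  q <- niche_occupancy(com$truth)
  occ <- colMeans(com$occurrences)
  se <- sqrt(q * (1 - q) / 10000)
  expect_true(all(abs(occ - q) < 3 * se + 1e-6))
})

test_that("null communities hit their occupancy targets independently of environment", {
  occ <- c(0.1, 0.5, 0.9)
  com <- generate_null(10000, 3, occupancy = occ, seed = 5)
  se <- sqrt(occ * (1 - occ) / 10000)
  expect_true(all(abs(colMeans(com$occurrences) - occ) < 3 * se))
  expect_error(generate_null(10, 2, occupancy = c(0, 0.5)), "occupancy")
  com2 <- generate_null(50, 20, occupancy = rep(1, 20), seed = 1)
  expect_true(all(com2$occurrences))
})

test_that("generation is seed-deterministic and regenerable from truth", {
  a <- generate_unimodal(40, 25, seed = 11)
  b <- generate_unimodal(40, 25, seed = 11)
  expect_identical(a$occurrences, b$occurrences)
  expect_identical(regenerate_community(a)$occurrences, a$occurrences)
  n0 <- generate_null(40, 25, seed = 12)
  expect_identical(regenerate_community(n0)$occurrences, n0$occurrences)
  expect_false(identical(generate_unimodal(40, 25, seed = 13)$occurrences,
                         a$occurrences))
})

test_that("beta diversity tracks environmental distance only under unimodal niches", {
  rs <- vapply(1:10, function(s) {
    com <- generate_unimodal(300, 150, seed = s)
    m <- suppressWarnings(clean_occurrences(com$occurrences))
    d <- jaccard_dissimilarity(m)
    de <- stats::dist(com$environment[rownames(m), ])
    stats::cor(as.numeric(d), as.numeric(de))
  }, numeric(1))
  expect_true(all(rs > 0))
  rs0 <- vapply(1:10, function(s) {
    com <- generate_null(300, 150, seed = s)
    m <- suppressWarnings(clean_occurrences(com$occurrences))
    d <- jaccard_dissimilarity(m)
    de <- stats::dist(com$environment[rownames(m), ])
    stats::cor(as.numeric(d), as.numeric(de))
  }, numeric(1))
  expect_lt(mean(rs0) - 3 * stats::sd(rs0) / sqrt(10), 0)
  expect_gt(mean(rs0) + 3 * stats::sd(rs0) / sqrt(10), 0)
})

test_that("fixtures round-trip and stay small", {
  com <- generate_unimodal(80, 50, seed = 21)
  dir <- withr::local_tempdir()
  paths <- write_fixture(com, dir, "fx")
  expect_true(all(file.exists(paths)))
  expect_lt(sum(file.size(paths)), 300e3)
  back <- read_fixture(dir, "fx")
  expect_identical(back$occurrences, com$occurrences)
  expect_equal(back$environment, com$environment, tolerance = 1e-15)
  expect_identical(regenerate_community(back)$occurrences, com$occurrences)
  n0 <- generate_null(30, 20, seed = 22)
  write_fixture(n0, dir, "nx")
  backn <- read_fixture(dir, "nx")
  expect_identical(regenerate_community(backn)$occurrences, n0$occurrences)
})

test_that("atlas coarsening unions member assemblages per grid cell", {
  com <- generate_unimodal(200, 60, seed = 31)
  atl <- coarsen_to_grid(com, cells = 5)
  expect_lte(nrow(atl$occurrences), 25)
  # pick one cell and verify its assemblage is the member union
  env <- com$environment
  cx <- pmin(pmax(ceiling(env[, 1] * 5), 1), 5)
  cy <- pmin(pmax(ceiling(env[, 2] * 5), 1), 5)
  key <- (cx - 1) * 5 + cy
  k <- as.integer(sub("cell_", "", rownames(atl$occurrences)[1]))
  members <- which(key == k)
  expect_identical(unname(atl$occurrences[1, ]),
                   unname(colSums(com$occurrences[members, , drop = FALSE]) > 0))
})

test_that("correlated gradients are correlated, uniform ones are not", {
  a <- generate_unimodal(2000, 1, env_model = "gradient-correlated",
                         seed = 8, rho = 0.6)
  expect_gt(stats::cor(a$environment[, 1], a$environment[, 2]), 0.5)
  b <- generate_unimodal(2000, 1, env_model = "uniform", seed = 8)
  expect_lt(abs(stats::cor(b$environment[, 1], b$environment[, 2])), 0.1)
})

test_that("niche specifications validate their ranges", {
  expect_error(niche_spec(sigma_range = c(0, 0.1)), "positive")
  expect_error(niche_spec(h_range = c(0.5, 1.2)), "h must")
  expect_error(generate_unimodal(2, 5, seed = 1), "n_sites")
})
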