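test_that("demand grids span the site bounding box exactly", {
  g <- make_demand_grid(rbind(c(0, 0), c(1, 1)), 2)
  expect_equal(nrow(g$points), 4)
  expect_setequal(apply(g$points, 1, paste, collapse = ","),
                  c("0,0", "0,1", "1,0", "1,1"))
  set.seed(3)
  co <- matrix(stats::rnorm(20), 10, 2)
  g2 <- make_demand_grid(co, 100)
  expect_equal(nrow(g2$points), 10000)
  expect_equal(range(g2$points[, 1]), range(co[, 1]))
  expect_equal(range(g2$points[, 2]), range(co[, 2]))
  degenerate <- cbind(c(0, 0, 0), c(1, 2, 3))
  expect_error(make_demand_grid(degenerate, 10), "zero extent")
})

test_that("the p-median objective matches a nested-loop oracle", {
  co <- rbind(c(0.3, 0.7))
  g <- make_demand_grid(rbind(c(0, 0), c(1, 1)), 5)
  one <- structure(list(points = matrix(c(0.3, 0.7), 1), resolution = 1L),
                   class = "demand_grid")
  expect_equal(pmedian_objective(1, one, co), 0)
  set.seed(14)
  co2 <- matrix(stats::runif(16), 8, 2)
  g2 <- make_demand_grid(co2, 5)
  sel <- c(2L, 5L, 7L)
  expect_equal(pmedian_objective(sel, g2, co2),
               pmedian_objective_oracle(sel, g2$points, co2),
               tolerance = 1e-9)
  # superset dominance: adding sites can only reduce the objective
  expect_lte(pmedian_objective(1:8, g2, co2), pmedian_objective(sel, g2, co2))
  expect_error(pmedian_objective(integer(0), g2, co2), "empty")
})

test_that("heuristic selection satisfies its boundary contracts", {
  set.seed(21)
  co <- matrix(stats::runif(12), 6, 2)
  g <- make_demand_grid(co, 8)
  all_sites <- select_pmedian(co, g, 6, seed = 1)
  expect_identical(all_sites$selected, 1:6)
  expect_error(select_pmedian(co, g, 0), "at least 1")
  expect_error(select_pmedian(co, g, 7), "exceeds")
  # center of a cross of 5 sites serves a symmetric grid best
  co2 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  g2 <- make_demand_grid(co2, 21)
  expect_identical(select_pmedian(co2, g2, 1, seed = 2)$selected, 5L)
  expect_identical(select_pmedian_exact(co2, g2, 1)$selected, 5L)
})

test_that("heuristic equals exhaustive enumeration on small instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    p <- sample(2:4, 1)
    co <- matrix(stats::runif(2 * n), n, 2)
    g <- make_demand_grid(co, 5)
    heur <- select_pmedian(co, g, p, seed = rep)
    exact <- select_pmedian_exact(co, g, p)
    expect_equal(heur$objective, exact$objective, tolerance = 1e-9)
  }
})

test_that("exact enumeration matches an independent oracle and is monotone", {
  set.seed(41)
  co <- matrix(stats::runif(12), 6, 2)
  g <- make_demand_grid(co, 5)
  expect_equal(select_pmedian_exact(co, g, 2)$objective,
               pmedian_exact_oracle(g$points, co, 2), tolerance = 1e-9)
  objs <- vapply(1:6, function(p) select_pmedian_exact(co, g, p)$objective,
                 numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
  expect_error(select_pmedian_exact(matrix(stats::runif(60), 30), g, 15),
               "enumeration")
})

test_that("the heuristic never does worse than pure greedy construction", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(8:25, 1)
    p <- sample(2:6, 1)
    co <- matrix(stats::runif(2 * n), n, 2)
    g <- make_demand_grid(co, 10)
    D <- betasai:::cpp_cross_dist(g$points, co)
    greedy <- betasai:::cpp_greedy_pmedian(D, p)
    heur <- select_pmedian(co, g, p, seed = rep)
    expect_lte(heur$objective, greedy$objective + 1e-12)
    # reported objective is exactly the recomputed objective
    expect_identical(heur$objective,
                     pmedian_objective(heur$selected, g, co))
    # final result at least as good as every start's local optimum
    expect_lte(heur$objective, min(heur$start_objectives) + 1e-12)
  }
})

test_that("instance dumps can rebuild the objective externally", {
  set.seed(71)
  co <- matrix(stats::runif(10), 5, 2)
  g <- make_demand_grid(co, 4)
  dir <- withr::local_tempdir()
  paths <- dump_pmedian_instance(co, g, dir, "inst")
  sites <- utils::read.table(paths[1], header = TRUE, sep = "\t")
  dem <- utils::read.table(paths[2], header = TRUE, sep = "\t")
  co2 <- as.matrix(sites[, c("x", "y")])
  expect_equal(unname(co2), unname(co), tolerance = 1e-15)
  expect_equal(pmedian_objective_oracle(c(1, 3), as.matrix(dem), co2),
               pmedian_objective(c(1, 3), g, co), tolerance = 1e-12)
})

test_that("selection is deterministic under a fixed seed and improves with starts", {
  set.seed(61)
  co <- matrix(stats::runif(60), 30, 2)
  g <- make_demand_grid(co, 12)
  a <- select_pmedian(co, g, 5, seed = 77)
  b <- select_pmedian(co, g, 5, seed = 77)
  expect_identical(a$selected, b$selected)
  expect_identical(a$objective, b$objective)
  few <- select_pmedian(co, g, 5, n_starts = 4, seed = 77)
  many <- select_pmedian(co, g, 5, n_starts = 16, seed = 77)
  # nested seed streams: the first 4 construction draws coincide
  expect_lte(min(many$start_objectives[1:4]) - 1e-12,
             min(few$start_objectives))
  expect_lte(many$objective, min(many$start_objectives) + 1e-12)
})
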