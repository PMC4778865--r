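test_that("the SAI formula behaves across its range", {
  expect_equal(sai(6, 0, 10), 0.6)
  expect_equal(sai(10, 4, 10), 1)
  expect_equal(sai(4, 4, 10), 0)
  expect_lt(sai(2, 4, 10), 0)
  set.seed(4)
  for (rep in 1:20) {
    R <- stats::runif(1, 0, 50)
    O <- R + stats::runif(1, 0.5, 30)
    S <- stats::runif(1, 0, O)
    expect_equal(sai(S, R, O), (S - R) / (O - R), tolerance = 1e-12)
  }
  expect_error(sai(5, 8, 6), "O < R")
  expect_warning(v <- sai(5, 6, 6), "saturated")
  expect_true(is.nan(v))
})

# a small unimodal community used by the pipeline-level tests
surrogacy_fixture <- local({
  com <- generate_unimodal(60, 40, seed = 2024)
  suppressWarnings(clean_occurrences(com$occurrences))
})

test_that("injecting the optimal selection gives SAI = 1 at every fraction", {
  m <- surrogacy_fixture
  oc <- optimal_curve(m)
  optimal_selector <- function(m2, p, seed) optimal_selection(oc, p)
  rep <- evaluate_surrogacy(m, n_reps = 400, seed = 9,
                            selector = optimal_selector)
  expect_true(all(abs(rep$table$SAI - 1) < 1e-9))
  expect_equal(rep$mean_sai, 1, tolerance = 1e-9)
  expect_identical(rep$method, "injected")
})

test_that("injecting random selections calibrates SAI near zero", {
  m <- surrogacy_fixture
  means <- vapply(1:8, function(s) {
    r <- evaluate_surrogacy(m, n_reps = 400, seed = s,
                            selector = function(m2, p, seed) {
                              set.seed(seed)
                              sample(nrow(m2), p)
                            })
    r$mean_sai
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.25) # coarse unit-level check; tight in acceptance
})

test_that("surrogacy reports are deterministic and internally consistent", {
  m <- surrogacy_fixture
  a <- evaluate_surrogacy(m, n_reps = 300, seed = 31)
  b <- evaluate_surrogacy(m, n_reps = 300, seed = 31)
  expect_identical(a$table, b$table)
  expect_identical(a$mean_sai, b$mean_sai)
  t <- a$table
  expect_identical(t$p, pmax(1L, as.integer(round(t$fraction * nrow(m)))))
  expect_true(all(t$S <= t$O))
  expect_true(all(t$R_lo <= t$R & t$R <= t$R_hi))
  expect_identical(t$significant, t$S > t$R_hi)
  expect_equal(a$mean_sai, mean(t$SAI, na.rm = TRUE))
  expect_true(is.finite(a$stress) && a$method %in% c("nmds", "hmds"))
  for (i in seq_along(a$selections))
    expect_equal(species_represented(m, a$selections[[i]]), t$S[i])
})

test_that("uncleaned matrices are rejected with stage-level errors", {
  m <- surrogacy_fixture
  m2 <- rbind(m, empty = rep(FALSE, ncol(m)))
  expect_error(evaluate_surrogacy(m2, seed = 1), "clean_occurrences")
  expect_error(evaluate_surrogacy(m, fractions = c(0, 0.5), seed = 1),
               "fraction")
  bad_selector <- function(m2, p, seed) integer(0)
  expect_error(evaluate_surrogacy(m, seed = 1, selector = bad_selector),
               "selector")
})

test_that("exported reports are complete, deterministic and re-parseable", {
  m <- surrogacy_fixture
  rep <- evaluate_surrogacy(m, n_reps = 300, seed = 8)
  dir <- withr::local_tempdir()
  paths <- export_report(rep, dir, "t")
  tab <- utils::read.table(file.path(dir, "t_sai_table.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(tab), 5)
  expect_equal(tab$S, rep$table$S)
  expect_equal(tab$O, rep$table$O)
  expect_equal(tab$SAI, rep$table$SAI, tolerance = 1e-6)
  js <- jsonlite::fromJSON(file.path(dir, "t_summary.json"))
  expect_equal(js$mean_sai, rep$mean_sai, tolerance = 1e-9)
  expect_equal(js$n_sites, nrow(m))
  acc <- utils::read.table(file.path(dir, "t_accumulation.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(acc), nrow(m))
  before <- lapply(paths, readBin, what = "raw", n = 1e6)
  export_report(rep, dir, "t")
  after <- lapply(paths, readBin, what = "raw", n = 1e6)
  expect_identical(before, after)
})
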