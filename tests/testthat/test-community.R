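test_that("wide tables parse to the written presences", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,a,b", "s1,1,0", "s2,0,1"), path)
  m <- read_occurrences(path, "wide")
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(sum(m), 2L)
  expect_true(m["s1", "a"] && m["s2", "b"])
})

test_that("long records collapse duplicates to one presence", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site\tspecies", "s1\ta", "s1\ta", "s2\tb"), path)
  m <- read_occurrences(path, "long")
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(sum(m), 2L)
  expect_true(m["s1", "a"] && m["s2", "b"])
})

test_that("write/read round-trips random matrices in both layouts", {
  set.seed(101)
  for (rep in 1:6) {
    m <- random_occurrence(sample(4:12, 1), sample(3:10, 1))
    for (layout in c("wide", "long")) {
      path <- withr::local_tempfile(fileext = ".tsv")
      write_occurrences(m, path, layout)
      m2 <- read_occurrences(path, layout)
      expect_identical(unname(m2[rownames(m), colnames(m)]), unname(m))
    }
  }
})

test_that("malformed cells and empty files are rejected with location info", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,a,b", "s1,1,0", "s2,2,1"), path)
  expect_error(read_occurrences(path, "wide"), "s2.*a.*2")
  writeLines(character(0), path)
  expect_error(read_occurrences(path, "wide"), "empty")
  expect_error(as_occurrence_matrix(matrix(c(0, 3), 1, 2)), "abundance")
})

test_that("cleaning removes exactly the empty sites and species", {
  set.seed(7)
  for (rep in 1:5) {
    m <- random_occurrence(10, 8)
    kill_r <- sample(10, 2)
    kill_c <- sample(8, 2)
    m[kill_r, ] <- FALSE
    m[, kill_c] <- FALSE
    # independent scan of what should go
    gone_r <- rownames(m)[rowSums(m) == 0]
    gone_c <- colnames(m)[colSums(m) == 0]
    expect_warning(mc <- clean_occurrences(m), "removed")
    expect_identical(attr(mc, "removed")$sites, gone_r)
    expect_identical(attr(mc, "removed")$species, gone_c)
    expect_true(all(rowSums(mc) > 0) && all(colSums(mc) > 0))
    expect_identical(rownames(mc), setdiff(rownames(m), gone_r))
  }
})

test_that("cleaning leaves full matrices untouched and enforces minimum size", {
  m <- random_occurrence(6, 5)
  mc <- clean_occurrences(m)
  expect_identical(unname(mc[, ]), unname(m)) # subset drops the removed attr
  tiny <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_error(suppressWarnings(clean_occurrences(tiny)), "sites")
})

test_that("jaccard dissimilarity matches the set-arithmetic definition", {
  m <- rbind(s1 = c(a = 1, b = 1, c = 1, d = 0),
             s2 = c(a = 0, b = 1, c = 1, d = 1))
  expect_equal(as.numeric(jaccard_dissimilarity(m)), 0.5)
  m2 <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0), s3 = c(0, 0, 1, 1))
  d2 <- as.matrix(jaccard_dissimilarity(m2))
  expect_equal(d2["s1", "s2"], 0) # identical assemblages
  expect_equal(d2["s1", "s3"], 1) # disjoint assemblages
  set.seed(42)
  m3 <- random_occurrence(50, 30)
  expect_equal(unname(as.matrix(jaccard_dissimilarity(m3))),
               jaccard_oracle(m3), tolerance = 1e-12)
})

test_that("jaccard distance is a metric and permutation-equivariant", {
  set.seed(9)
  m <- random_occurrence(30, 20)
  d <- as.matrix(jaccard_dissimilarity(m))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (k in 1:200) {
    ijk <- sample(30, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
  perm <- sample(30)
  dp <- as.matrix(jaccard_dissimilarity(m[perm, ]))
  expect_equal(unname(dp), unname(d[perm, perm]), tolerance = 1e-12)
})

test_that("empty sites are rejected until cleaned", {
  m <- random_occurrence(5, 4)
  m[2, ] <- FALSE
  expect_error(jaccard_dissimilarity(m), "clean_occurrences")
})
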