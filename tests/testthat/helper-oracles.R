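# Independent brute-force oracles and small generators used across tests.
# These deliberately re-derive quantities with the most naive algorithm
# available so they stay independent of the package implementation.

random_occurrence <- function(n, s, fill = 0.4) {
  m <- matrix(stats::runif(n * s) < fill, n, s,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("sp", seq_len(s))))
  # ensure no empty site/species so the matrix is analysis-ready
  for (i in which(rowSums(m) == 0)) m[i, sample(s, 1)] <- TRUE
  for (j in which(colSums(m) == 0)) m[sample(n, 1), j] <- TRUE
  m
}

# pairwise Jaccard dissimilarity by explicit set arithmetic
jaccard_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- which(m[i, ] > 0)
      b <- which(m[j, ] > 0)
      out[i, j] <- 1 - length(intersect(a, b)) / length(union(a, b))
    }
  }
  out
}

# total demand-to-nearest-selected distance by nested loops
pmedian_objective_oracle <- function(selected, grid_points, coords) {
  total <- 0
  for (i in seq_len(nrow(grid_points))) {
    best <- Inf
    for (f in selected) {
      d <- sqrt(sum((grid_points[i, ] - coords[f, ])^2))
      if (d < best) best <- d
    }
    total <- total + best
  }
  total
}

# exhaustive p-median optimum over all C(n, p) subsets
pmedian_exact_oracle <- function(grid_points, coords, p) {
  best <- Inf
  for (sel in utils::combn(nrow(coords), p, simplify = FALSE)) {
    obj <- pmedian_objective_oracle(sel, grid_points, coords)
    if (obj < best) best <- obj
  }
  best
}

# number of species covered by a selection, by explicit union
coverage_oracle <- function(m, selected) {
  covered <- integer(0)
  for (i in selected) covered <- union(covered, which(m[i, ] > 0))
  length(covered)
}

# exhaustive maximum coverage over all C(n, p) subsets
max_coverage_oracle <- function(m, p) {
  best <- 0
  for (sel in utils::combn(nrow(m), p, simplify = FALSE))
    best <- max(best, coverage_oracle(m, sel))
  best
}

# RMSE after full Procrustes superimposition (translation, rotation or
# reflection, uniform scaling) of Y onto X
procrustes_rmse <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  cc <- sum(s$d) / sum(Y^2)
  sqrt(mean(rowSums((X - cc * (Y %*% R))^2)))
}

# small euclidean configuration whose scaled distances act as
# rank-consistent dissimilarities
euclidean_dissim <- function(X) {
  d <- stats::dist(X)
  d / max(d)
}
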