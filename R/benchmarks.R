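#' Number of species represented by a site selection
#'
#' @param m occurrence matrix.
#' @param selected integer site indices or site names; may be empty.
#' @return Count of species present in at least one selected site.
#' @export
species_represented <- function(m, selected) {
  m <- as_occurrence_matrix(m)
  if (length(selected) == 0) return(0L)
  if (is.character(selected)) selected <- match(selected, rownames(m))
  selected <- as.integer(selected)
  if (anyNA(selected) || any(selected < 1 | selected > nrow(m)))
    stop("selected sites not found in the matrix")
  sum(colSums(m[selected, , drop = FALSE]) > 0)
}

#' Forward-greedy maximum species coverage
#'
#' Iteratively adds the site contributing the most uncovered species
#' (complementarity-based reserve selection); ties go to the lowest site
#' index. The per-step coverage path is returned, so the result serves every
#' p' <= p via its prefix.
#'
#' @param m occurrence matrix.
#' @param p number of sites to select.
#' @return A list with `selected` (indices in pick order) and `coverage`
#'   (cumulative species count after each step, non-decreasing).
#' @export
greedy_max_coverage <- function(m, p) {
  m <- as_occurrence_matrix(m)
  n <- nrow(m)
  p <- as.integer(p)
  if (p < 1 || p > n) stop("p must be in 1..n")
  uncovered <- rep(TRUE, ncol(m))
  selected <- integer(p)
  coverage <- integer(p)
  covered <- 0L
  for (step in seq_len(p)) {
    gains <- if (any(uncovered))
      rowSums(m[, uncovered, drop = FALSE]) else rep(0, n)
    gains[selected[seq_len(step - 1)]] <- -1
    pick <- which.max(gains) # ties: lowest index
    selected[step] <- pick
    newly <- uncovered & m[pick, ]
    covered <- covered + sum(newly)
    uncovered <- uncovered & !m[pick, ]
    coverage[step] <- covered
  }
  list(selected = selected, coverage = coverage)
}

#' Backward core-area removal ranking
#'
#' Emulates core-area cell removal as used in spatial conservation
#' prioritization: all sites start reserved; at each step every remaining
#' site i is valued \eqn{v_i = \max_j 1 / r_j} over the species j it holds,
#' where \eqn{r_j} is the number of remaining sites holding j, and the site
#' with the smallest value is removed (ties: lowest index). Sites holding a
#' species' last occurrence have \eqn{v_i = 1} and are removed last among
#' the candidates. The retained sets are nested: the best k-site reserve is
#' the last k sites of the order.
#'
#' @param m occurrence matrix (cleaned: no empty sites).
#' @return A list of class `removal_order` with `order` (site indices,
#'   first removed first) and `values` (the removal value \eqn{v_i} at each
#'   step).
#' @export
core_area_removal <- function(m) {
  m <- as_occurrence_matrix(m)
  res <- cpp_core_removal(m)
  structure(list(order = res$order, values = res$values),
            class = "removal_order")
}

#' Best-achievable species representation per number of sites
#'
#' The optimal benchmark O(p): the largest number of species representable
#' in p sites, estimated as the maximum over three selectors — forward
#' greedy ([greedy_max_coverage()]), the retained sets of the backward
#' core-area ranking ([core_area_removal()]), and, whenever
#' `choose(n, p) <= exact_limit`, exhaustive maximal coverage (which makes
#' O exact there). O is non-decreasing in p.
#'
#' @param m occurrence matrix.
#' @param p_list increasing vector of site counts; defaults to 1..n.
#' @param exact_limit largest subset count for which exhaustive search runs.
#' @return A list of class `optimal_curve`: `table` (data frame with `p`,
#'   `O`, `source`), plus the greedy path and removal order, and
#'   `selection(p)` support via [optimal_selection()].
#' @export
optimal_curve <- function(m, p_list = NULL, exact_limit = 1e5) {
  m <- as_occurrence_matrix(m)
  n <- nrow(m)
  if (is.null(p_list)) p_list <- seq_len(n)
  p_list <- as.integer(p_list)
  if (any(p_list < 1 | p_list > n)) stop("p_list must lie in 1..n")
  g <- greedy_max_coverage(m, n)
  ro <- core_area_removal(m)
  # coverage of the retained (last k) sites for all k, via each species'
  # latest removal position
  pos <- integer(n)
  pos[ro$order] <- seq_len(n)
  maxpos <- apply(m, 2, function(z) max(pos[z]))
  # A[j] = number of species whose last-removed site sits at position >= j;
  # the last p sites of the order cover A[n - p + 1] species
  A <- rev(cumsum(rev(tabulate(maxpos, nbins = n))))
  core_cov <- rev(A)
  O <- integer(length(p_list))
  src <- character(length(p_list))
  exact_sel <- vector("list", length(p_list))
  for (i in seq_along(p_list)) {
    p <- p_list[i]
    cand <- c(greedy = g$coverage[p], core = core_cov[p])
    if (choose(n, p) <= exact_limit) {
      ex <- cpp_max_coverage_exact(m, p)
      cand <- c(cand, exact = ex$coverage)
      exact_sel[[i]] <- ex$selected
    }
    O[i] <- max(cand)
    src[i] <- names(cand)[which.max(cand)]
  }
  structure(list(table = data.frame(p = p_list, O = O, source = src),
                 greedy = g, removal = ro, exact_selections = exact_sel,
                 n_sites = n, n_species = ncol(m)),
            class = "optimal_curve")
}

#' Selection achieving the optimal benchmark at p
#'
#' @param oc an [optimal_curve()] object whose `p_list` contains `p`.
#' @param p number of sites.
#' @return Integer site indices attaining O(p).
#' @export
optimal_selection <- function(oc, p) {
  i <- match(p, oc$table$p)
  if (is.na(i)) stop("p not in the optimal curve")
  switch(oc$table$source[i],
         greedy = oc$greedy$selected[seq_len(p)],
         core = utils::tail(oc$removal$order, p),
         exact = oc$exact_selections[[i]])
}

#' Random-accumulation baseline with confidence bounds
#'
#' Accumulates sites in uniform random order, recording the number of
#' species represented after each addition; over `n_reps` replicates the
#' per-p mean is the baseline R and the 2.5th/97.5th percentiles its 95%
#' interval (percentile bounds, appropriate for discrete counts).
#' Deterministic under a fixed seed.
#'
#' @param m occurrence matrix.
#' @param p_list site counts at which to report; defaults to 1..n.
#' @param n_reps number of random orders (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `random_baseline`: `table` (data frame `p`, `R`,
#'   `lo`, `hi`), `n_reps` and `seed`.
#' @export
random_accumulation <- function(m, p_list = NULL, n_reps = 1000L,
                                seed = NULL) {
  m <- as_occurrence_matrix(m)
  n <- nrow(m)
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (is.null(p_list)) p_list <- seq_len(n)
  p_list <- as.integer(p_list)
  if (any(p_list < 1 | p_list > n)) stop("p_list must lie in 1..n")
  counts <- with_seed(seed, cpp_random_accum(m, as.integer(n_reps)))
  counts <- counts[, p_list, drop = FALSE]
  R <- colMeans(counts)
  qs <- apply(counts, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(table = data.frame(p = p_list, R = R, lo = qs[1, ],
                                    hi = qs[2, ]),
                 n_reps = as.integer(n_reps), seed = seed),
            class = "random_baseline")
}
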