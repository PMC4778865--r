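#' Ordination settings
#'
#' Collects the tunable parameters of the multidimensional-scaling stage.
#' Defaults follow common practice for community data: two dimensions, the
#' best of 10 starts, up to 1000 iterations per start.
#'
#' @param method `"nmds"` (fully nonmetric) or `"hmds"` (hybrid: a metric
#'   least-squares term is added for pairs below `hybrid_threshold`,
#'   countering the saturation of Jaccard dissimilarity at 1).
#' @param n_dims number of dimensions; only 2 is supported.
#' @param n_starts number of starts; the first is classical (metric)
#'   scaling, the rest are random.
#' @param max_iter maximum majorization iterations per start.
#' @param tol relative stress-change convergence threshold.
#' @param hybrid_threshold dissimilarity cutoff in (0, 1] below which pairs
#'   enter the metric term of HMDS.
#' @param metric_weight weight in \[0, 1\] of the metric term in the HMDS
#'   blend; 0 reduces HMDS to NMDS.
#' @param seed integer seed for the random starts; `NULL` uses the current
#'   RNG stream.
#' @return An object of class `ordination_config`.
#' @export
ordination_config <- function(method = c("nmds", "hmds"), n_dims = 2L,
                              n_starts = 10L, max_iter = 1000L, tol = 1e-6,
                              hybrid_threshold = 0.9, metric_weight = 0.5,
                              seed = NULL) {
  method <- match.arg(method)
  stopifnot(n_starts >= 1, max_iter >= 1, tol > 0,
            hybrid_threshold > 0, hybrid_threshold <= 1,
            metric_weight >= 0, metric_weight <= 1)
  if (n_dims != 2) stop("only 2-dimensional ordination is supported")
  structure(list(method = method, n_dims = 2L,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 hybrid_threshold = hybrid_threshold,
                 metric_weight = metric_weight, seed = seed),
            class = "ordination_config")
}

#' Least-squares monotone regression with Kruskal primary ties
#'
#' Fits values non-decreasing in the order of `dissimilarities` by
#' pool-adjacent-violators. Tied dissimilarities are unconstrained among
#' themselves (primary approach): within each tie block the fit follows the
#' ascending order of `distances`.
#'
#' @param distances numeric vector (e.g. configuration distances).
#' @param dissimilarities numeric vector of the same length defining the
#'   target order.
#' @return The fitted disparities, in the input order.
#' @examples
#' monotone_regression(c(3, 1), c(0.2, 0.7)) # pooled to c(2, 2)
#' @export
monotone_regression <- function(distances, dissimilarities) {
  if (length(distances) != length(dissimilarities))
    stop("distances and dissimilarities must have equal length")
  if (!all(is.finite(distances))) stop("distances must be finite")
  tb <- tie_blocks(dissimilarities)
  cpp_monotone_fit(as.numeric(distances), tb$ord, tb$bstart)
}

#' Kruskal stress-1 of a configuration
#'
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} where d are configuration
#' distances and the disparities \eqn{\hat d} are the monotone regression of
#' d on the dissimilarities. 0 means perfect rank agreement.
#'
#' @param coordinates n x 2 matrix of site coordinates.
#' @param d dissimilarity object ([stats::dist]) for the same n sites.
#' @return Stress-1 in \[0, 1\].
#' @export
stress1 <- function(coordinates, d) {
  coordinates <- as.matrix(coordinates)
  n <- attr(d, "Size")
  if (nrow(coordinates) != n)
    stop("coordinates and dissimilarity matrix sizes differ")
  dc <- as.numeric(stats::dist(coordinates))
  ss <- sum(dc^2)
  if (ss <= 0) stop("degenerate configuration: all coordinates coincide")
  dhat <- monotone_regression(dc, as.numeric(d))
  sqrt(sum((dc - dhat)^2) / ss)
}

# shared multistart driver for nmds()/hmds()
mds_multistart <- function(d, cfg, metric_idx, metric_delta, metric_weight) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3) stop("ordination needs at least 3 sites")
  delta <- as.numeric(d)
  pij <- pair_indices(n)
  tb <- tie_blocks(delta)
  run <- function() {
    starts <- vector("list", cfg$n_starts)
    # start 1: classical (metric) scaling
    X0 <- suppressWarnings(stats::cmdscale(d, k = 2))
    if (ncol(X0) < 2)
      X0 <- cbind(X0, matrix(0, n, 2 - ncol(X0)))
    if (all(abs(X0) < 1e-12)) X0 <- matrix(stats::runif(n * 2, -0.5, 0.5), n, 2)
    starts[[1]] <- X0
    if (cfg$n_starts > 1)
      for (k in 2:cfg$n_starts)
        starts[[k]] <- matrix(stats::runif(n * 2, -0.5, 0.5), n, 2)
    lapply(starts, function(X)
      cpp_mds_engine(X, as.integer(pij[, 1] - 1L), as.integer(pij[, 2] - 1L),
                     tb$ord, tb$bstart, metric_idx, metric_delta,
                     metric_weight, cfg$max_iter, cfg$tol))
  }
  fits <- with_seed(cfg$seed, run())
  stresses <- vapply(fits, function(f) {
    s <- f$stress
    if (!is.finite(s)) Inf else s
  }, numeric(1))
  converged <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(converged))
    warning("no start converged within max_iter; returning best configuration found")
  best <- which.min(stresses)
  X <- fits[[best]]$coordinates
  # reproducible orientation: center, then fix the sign of each axis so the
  # coordinate with the largest magnitude is positive
  X <- sweep(X, 2, colMeans(X))
  for (k in 1:2) {
    i <- which.max(abs(X[, k]))
    if (X[i, k] < 0) X[, k] <- -X[, k]
  }
  dimnames(X) <- list(attr(d, "Labels"), c("axis1", "axis2"))
  structure(list(coordinates = X,
                 stress = stresses[best],
                 method = NA_character_,
                 start_stresses = stresses,
                 converged = converged,
                 best_start = best,
                 traces = lapply(fits, `[[`, "trace"),
                 iterations = vapply(fits, `[[`, integer(1), "iterations"),
                 config = cfg),
            class = "betasai_ordination")
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Places sites in two dimensions so that inter-site distances reproduce the
#' rank order of dissimilarities, minimizing Kruskal stress-1 by SMACOF-style
#' majorization with monotone (primary-tie) disparities. The first start is
#' initialized from classical scaling, the remaining `n_starts - 1` from
#' random configurations; the lowest-stress solution is returned.
#'
#' @param d dissimilarity object ([stats::dist]).
#' @param config an [ordination_config()]; its `method` field is ignored.
#' @return An object of class `betasai_ordination`: centered `coordinates`
#'   (n x 2), the minimized `stress`, per-start `start_stresses` and
#'   `converged` flags, and the configuration used.
#' @export
nmds <- function(d, config = ordination_config("nmds")) {
  res <- mds_multistart(d, config, integer(0), numeric(0), 0)
  res$method <- "nmds"
  res
}

#' Hybrid multidimensional scaling
#'
#' As [nmds()], but the loss blends nonmetric stress over all pairs with a
#' metric least-squares term (a through-origin linear fit of distance on
#' dissimilarity) restricted to pairs whose dissimilarity is below
#' `hybrid_threshold`. Large Jaccard dissimilarities saturate at 1 and carry
#' rank information only; small ones are close to linear in ecological
#' distance, which the metric term exploits.
#'
#' @inheritParams nmds
#' @return An object of class `betasai_ordination`.
#' @export
hmds <- function(d, config = ordination_config("hmds")) {
  delta <- as.numeric(d)
  idx <- which(delta < config$hybrid_threshold)
  if (length(idx) == 0) {
    warning("no pair below hybrid_threshold; hmds reduces to nmds")
    res <- mds_multistart(d, config, integer(0), numeric(0), 0)
  } else {
    res <- mds_multistart(d, config, as.integer(idx - 1L), delta[idx],
                          config$metric_weight)
  }
  res$method <- "hmds"
  res
}

#' Run both NMDS and HMDS and keep the better ordination
#'
#' Both methods are fitted with the same settings and seed; the result with
#' the lower stress is returned (ties favour NMDS). The `method` field
#' records which one was kept.
#'
#' @param d dissimilarity object.
#' @param config_nmds,config_hmds configurations for the two methods;
#'   defaults share all settings.
#' @param seed convenience override applied to both configurations.
#' @return The winning `betasai_ordination`, with an extra
#'   `candidate_stresses` field naming both stresses.
#' @export
best_ordination <- function(d, config_nmds = ordination_config("nmds"),
                            config_hmds = ordination_config("hmds"),
                            seed = NULL) {
  if (!is.null(seed)) {
    config_nmds$seed <- seed
    config_hmds$seed <- seed
  }
  a <- nmds(d, config_nmds)
  b <- hmds(d, config_hmds)
  # each method reports stress against its own fitted targets; compare the
  # two configurations on the common, purely nonmetric stress-1 scale
  sa <- stress1(a$coordinates, d)
  sb <- stress1(b$coordinates, d)
  res <- if (sb < sa) b else a # ties favour nmds
  res$candidate_stresses <- c(nmds = sa, hmds = sb)
  res
}

#' @export
print.betasai_ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d sites, stress-1 = %.4f (%d starts, %d converged)\n",
              toupper(x$method %||% "mds"), nrow(x$coordinates), x$stress,
              length(x$start_stresses), sum(x$converged)))
  invisible(x)
}
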