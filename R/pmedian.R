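#' Regular grid of demand points over an ordination
#'
#' Lays a `resolution` x `resolution` lattice over the axis-aligned bounding
#' box of the site coordinates, corners included. The lattice points act as
#' demand points in the p-median selection: a selection that serves all of
#' them cheaply spans the occupied ordination space. The default resolution
#' of 100 gives 10,000 demand points.
#'
#' @param ordination a `betasai_ordination`, or an n x 2 coordinate matrix.
#' @param resolution number of lattice points per axis (>= 2).
#' @return An object of class `demand_grid`: `points` (m x 2 matrix with
#'   m = resolution^2), `resolution` and `bbox`.
#' @export
make_demand_grid <- function(ordination, resolution = 100L) {
  coords <- if (inherits(ordination, "betasai_ordination"))
    ordination$coordinates else as.matrix(ordination)
  if (ncol(coords) != 2) stop("coordinates must have two columns")
  if (nrow(coords) < 2) stop("need at least 2 sites")
  if (resolution < 2) stop("resolution must be at least 2")
  rx <- range(coords[, 1])
  ry <- range(coords[, 2])
  if (diff(rx) <= 0 || diff(ry) <= 0)
    stop("degenerate ordination: zero extent on an axis")
  gx <- seq(rx[1], rx[2], length.out = resolution)
  gy <- seq(ry[1], ry[2], length.out = resolution)
  pts <- cbind(x = rep(gx, times = resolution),
               y = rep(gy, each = resolution))
  structure(list(points = pts, resolution = as.integer(resolution),
                 bbox = c(xmin = rx[1], xmax = rx[2],
                          ymin = ry[1], ymax = ry[2])),
            class = "demand_grid")
}

#' p-median objective of a site selection
#'
#' Sum over demand points of the Euclidean distance to the nearest selected
#' site. Computed by streaming over demand points (no m x n distance matrix
#' is formed), so memory stays bounded for large grids.
#'
#' @param selected integer site indices (1-based into `coords`).
#' @param grid a [make_demand_grid()] object.
#' @param coords n x 2 site coordinates.
#' @return The total distance (a non-negative scalar).
#' @export
pmedian_objective <- function(selected, grid, coords) {
  coords <- if (inherits(coords, "betasai_ordination"))
    coords$coordinates else as.matrix(coords)
  selected <- as.integer(selected)
  if (length(selected) == 0) stop("empty selection")
  if (any(selected < 1 | selected > nrow(coords)))
    stop("selected indices out of range")
  cpp_pmedian_objective(coords, grid$points, sort(selected))
}

pmedian_result <- function(selected, p, objective, method, n_starts = NA_integer_,
                           pool = NA_integer_, seed = NULL,
                           start_objectives = NULL) {
  structure(list(selected = as.integer(sort(selected)), p = as.integer(p),
                 objective = objective, method = method,
                 n_starts = n_starts, pool = pool, seed = seed,
                 start_objectives = start_objectives),
            class = "pmedian_selection")
}

#' Heuristic p-median site selection in ordination space
#'
#' Multistart hybrid heuristic: each start builds a selection by randomized
#' greedy construction (random seed site, then lazy-greedy completion; the
#' first start is pure greedy) and improves it by vertex-substitution (swap)
#' local search; the best `pool` distinct local optima are then hybridized by
#' path relinking, walking between solution pairs and keeping improving
#' intermediates. Deterministic under a fixed seed.
#'
#' @param coords n x 2 site coordinates (or a `betasai_ordination`).
#' @param grid demand grid from [make_demand_grid()].
#' @param p number of sites to select (1 <= p <= n).
#' @param n_starts number of construction + local-search starts.
#' @param pool number of elite solutions hybridized by path relinking.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `pmedian_selection`: sorted `selected`
#'   indices, `p`, the `objective` (recomputed with [pmedian_objective()],
#'   so the invariant `objective == pmedian_objective(selected)` holds
#'   exactly), the per-start local-optimum objectives, and the settings.
#' @export
select_pmedian <- function(coords, grid, p, n_starts = 32L, pool = 10L,
                           seed = NULL) {
  coords <- if (inherits(coords, "betasai_ordination"))
    coords$coordinates else as.matrix(coords)
  n <- nrow(coords)
  p <- as.integer(p)
  if (p < 1) stop("p must be at least 1")
  if (p > n) stop("p exceeds the number of sites")
  if (p == n) {
    sel <- seq_len(n)
    return(pmedian_result(sel, p, pmedian_objective(sel, grid, coords),
                          "all-sites", n_starts, pool, seed))
  }
  D <- cpp_cross_dist(grid$points, coords)
  fit <- with_seed(seed, cpp_select_pmedian(D, p, as.integer(n_starts),
                                            as.integer(pool)))
  pmedian_result(fit$selected, p,
                 pmedian_objective(fit$selected, grid, coords),
                 "greedy+swap+path-relinking", as.integer(n_starts),
                 as.integer(pool), seed, fit$start_objectives)
}

#' Exact p-median by exhaustive enumeration
#'
#' Evaluates every one of the C(n, p) selections; intended as a test oracle
#' for small instances. Ties are broken toward the lexicographically
#' smallest index set.
#'
#' @inheritParams select_pmedian
#' @param max_combinations refuse instances with more candidate subsets than
#'   this.
#' @return A `pmedian_selection` holding the global optimum.
#' @export
select_pmedian_exact <- function(coords, grid, p, max_combinations = 1e6) {
  coords <- if (inherits(coords, "betasai_ordination"))
    coords$coordinates else as.matrix(coords)
  n <- nrow(coords)
  p <- as.integer(p)
  if (p < 1 || p > n) stop("p must be in 1..n")
  if (choose(n, p) > max_combinations)
    stop("instance too large for enumeration (choose(n, p) > ",
         format(max_combinations), "); use select_pmedian()")
  D <- cpp_cross_dist(grid$points, coords)
  fit <- cpp_pmedian_exact(D, p)
  pmedian_result(fit$selected, p,
                 pmedian_objective(fit$selected, grid, coords), "exact")
}

#' Dump a p-median instance as delimited text
#'
#' Writes the site coordinates (`<prefix>_sites.tsv`: site, x, y) and the
#' demand grid (`<prefix>_demand.tsv`: x, y) so a selection can be verified
#' with external solvers.
#'
#' @param coords n x 2 site coordinates (or a `betasai_ordination`).
#' @param grid a [make_demand_grid()] object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The two paths written, invisibly.
#' @export
dump_pmedian_instance <- function(coords, grid, dir, prefix = "pmedian") {
  coords <- if (inherits(coords, "betasai_ordination"))
    coords$coordinates else as.matrix(coords)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, paste0(prefix, "_sites.tsv"))
  dp <- file.path(dir, paste0(prefix, "_demand.tsv"))
  sites <- data.frame(site = rownames(coords) %||% seq_len(nrow(coords)),
                      x = sprintf("%.17g", coords[, 1]),
                      y = sprintf("%.17g", coords[, 2]))
  utils::write.table(sites, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  dem <- data.frame(x = sprintf("%.17g", grid$points[, 1]),
                    y = sprintf("%.17g", grid$points[, 2]))
  utils::write.table(dem, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sp, dp))
}

#' @export
print.pmedian_selection <- function(x, ...) {
  cat(sprintf("p-median selection (%s): p = %d, objective = %.4f\n",
              x$method, x$p, x$objective))
  cat("sites:", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}
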