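#' Species Accumulation Index
#'
#' \eqn{SAI = (S - R) / (O - R)}: the efficiency of a surrogate-based site
#' selection relative to random selection (SAI = 0) and to the best
#' achievable selection of the same size (SAI = 1). Negative values mean
#' worse than random; the scale runs from \eqn{-\infty} to 1. An SAI of 0.6
#' reads "the surrogate delivered 60% of the improvement over random that
#' the optimal selection delivers".
#'
#' @param S species represented by the surrogate selection.
#' @param R mean species represented by random selections of the same size.
#' @param O largest species count achievable with the same number of sites.
#' @return `(S - R) / (O - R)`, vectorized; `NaN` with a warning where
#'   `O == R` (saturated instance). `O < R` is an error: the optimal
#'   benchmark may never fall below the random mean.
#' @examples
#' sai(6, 0, 10) # 0.6
#' @export
sai <- function(S, R, O) {
  k <- max(length(S), length(R), length(O))
  S <- rep_len(as.numeric(S), k)
  R <- rep_len(as.numeric(R), k)
  O <- rep_len(as.numeric(O), k)
  if (any(O < R))
    stop("O < R: the optimal benchmark cannot be below the random mean")
  out <- (S - R) / (O - R)
  if (any(O == R)) {
    warning("O == R at some p: accumulation saturated, SAI undefined (NaN)")
    out[O == R] <- NaN
  }
  out
}

default_fractions <- function() c(0.15, 0.20, 0.25, 0.30, 0.35)

#' Evaluate beta diversity as a surrogate for species representation
#'
#' Runs the full surrogacy pipeline on a cleaned occurrence matrix:
#' Jaccard dissimilarity, the better of NMDS/HMDS ordination, a regular
#' demand grid over ordination space, p-median selection of
#' `round(fraction * n)` sites per fraction, then scores each selection with
#' [sai()] against the optimal benchmark ([optimal_curve()]) and the random
#' baseline ([random_accumulation()]). A fraction is flagged significant
#' when S lies strictly above the 97.5th percentile of the random
#' distribution at the same p.
#'
#' All randomness derives from `seed` through fixed per-stage offsets, so
#' identical inputs and seed give an identical report.
#'
#' @param m cleaned occurrence matrix (see [clean_occurrences()]).
#' @param fractions proportions of sites to select; the default spans 15% to
#'   35% in 5% steps.
#' @param config_nmds,config_hmds ordination settings (see
#'   [ordination_config()]).
#' @param resolution demand-grid side count (default 100, i.e. 10,000
#'   demand points).
#' @param n_starts,pool p-median heuristic settings.
#' @param n_reps random-baseline replicates.
#' @param seed master integer seed.
#' @param selector optional injection point replacing the beta-diversity
#'   surrogate: a `function(m, p, seed)` returning site indices. Used for
#'   calibration (e.g. injecting the optimal or a random selection); the
#'   ordination and p-median stages are skipped.
#' @param exact_limit passed to [optimal_curve()].
#' @return An object of class `sai_report`; see [export_report()] for the
#'   file layout. Key fields: `table` (per-fraction S, R with bounds, O,
#'   SAI, significance), `mean_sai` (unweighted; saturated NaN fractions
#'   are excluded unless all are NaN), `stress`
#'   and `method` of the ordination used, and the full accumulation curves.
#' @export
evaluate_surrogacy <- function(m, fractions = default_fractions(),
                               config_nmds = ordination_config("nmds"),
                               config_hmds = ordination_config("hmds"),
                               resolution = 100L, n_starts = 32L, pool = 10L,
                               n_reps = 1000L, seed = 1L, selector = NULL,
                               exact_limit = 1e5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  m <- as_occurrence_matrix(m)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("matrix contains empty sites or species; run clean_occurrences() first")
  n <- nrow(m)
  fractions <- sort(as.numeric(fractions))
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  p_list <- pmax(1L, as.integer(round(fractions * n)))

  ord <- NULL
  selections <- vector("list", length(p_list))
  if (is.null(selector)) {
    d <- stage("dissimilarity", jaccard_dissimilarity(m))
    ord <- stage("ordination",
                 best_ordination(d, config_nmds, config_hmds,
                                 seed = derive_seed(seed, "ordination")))
    grid <- stage("demand_grid", make_demand_grid(ord, resolution))
    # one heuristic invocation serves all fractions: the randomized greedy
    # constructions are nested in p, so their prefixes seed every p's local
    # search (same algorithm as select_pmedian(), constructions shared)
    ps <- sort(unique(p_list))
    fits <- stage("pmedian", {
      D <- cpp_cross_dist(grid$points, ord$coordinates)
      with_seed(derive_seed(seed, "pmedian"),
                cpp_select_pmedian_multi(D, as.integer(ps),
                                         as.integer(n_starts),
                                         as.integer(pool)))
    })
    for (i in seq_along(p_list))
      selections[[i]] <- fits[[match(p_list[i], ps)]]$selected
  } else {
    for (i in seq_along(p_list)) {
      sel <- stage("selector",
                   selector(m, p_list[i], derive_seed(seed, "selector", i)))
      sel <- as.integer(sel)
      if (length(sel) != p_list[i] || any(sel < 1 | sel > n))
        stop("stage 'selector': injected selection invalid at p = ", p_list[i])
      selections[[i]] <- sel
    }
  }
  S <- vapply(selections, function(sel) species_represented(m, sel), numeric(1))

  oc <- stage("optimal", optimal_curve(m, exact_limit = exact_limit))
  O <- oc$table$O[p_list]
  raised <- S > O
  if (any(raised)) {
    warning("surrogate exceeded the heuristic optimum at p = ",
            paste(p_list[raised], collapse = ", "),
            "; O raised to S there")
    O[raised] <- S[raised]
  }
  rb <- stage("baseline",
              random_accumulation(m, n_reps = n_reps,
                                  seed = derive_seed(seed, "baseline")))
  R <- rb$table$R[p_list]
  R_lo <- rb$table$lo[p_list]
  R_hi <- rb$table$hi[p_list]

  sai_vals <- stage("sai", sai(S, R, O))
  # saturated fractions (O == R) are excluded from the mean unless every
  # fraction is saturated
  if (anyNA(sai_vals))
    warning("undefined SAI at ", sum(is.na(sai_vals)),
            " saturated fraction(s); excluded from the mean")
  mean_sai <- if (all(is.na(sai_vals))) NaN else mean(sai_vals, na.rm = TRUE)
  tab <- data.frame(fraction = fractions, p = p_list, S = S, R = R,
                    R_lo = R_lo, R_hi = R_hi, O = O, SAI = sai_vals,
                    significant = S > R_hi)
  structure(list(table = tab,
                 mean_sai = mean_sai,
                 stress = if (is.null(ord)) NA_real_ else ord$stress,
                 method = if (is.null(ord)) "injected" else ord$method,
                 seed = seed,
                 n_sites = n, n_species = ncol(m),
                 selections = selections,
                 ordination = ord,
                 baseline = rb,
                 optimal = oc,
                 config = list(fractions = fractions,
                               resolution = as.integer(resolution),
                               n_starts = as.integer(n_starts),
                               pool = as.integer(pool),
                               n_reps = as.integer(n_reps),
                               ord_n_starts = config_nmds$n_starts,
                               ord_max_iter = config_nmds$max_iter,
                               ord_tol = config_nmds$tol,
                               hybrid_threshold = config_hmds$hybrid_threshold,
                               metric_weight = config_hmds$metric_weight,
                               seed = seed)),
            class = "sai_report")
}

#' @export
print.sai_report <- function(x, ...) {
  cat(sprintf("SAI report: %d sites x %d species, ordination = %s (stress %s)\n",
              x$n_sites, x$n_species, x$method,
              fmt_num(x$stress, 4)))
  print(x$table, row.names = FALSE)
  cat(sprintf("mean SAI = %s\n", fmt_num(x$mean_sai, 4)))
  invisible(x)
}

#' Write an SAI report to disk
#'
#' Produces three deterministic files (re-exporting the same report is
#' byte-identical): `<prefix>_sai_table.tsv` (per-fraction S, R, bounds, O,
#' SAI, significance), `<prefix>_summary.json` (mean SAI, stress, method,
#' seed and the configuration snapshot) and `<prefix>_accumulation.tsv`
#' (the full optimal and random accumulation curves, the data layer of a
#' species-accumulation figure).
#'
#' @param report an `sai_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the paths written, invisibly.
#' @export
export_report <- function(report, dir, prefix = "betasai") {
  if (!inherits(report, "sai_report")) stop("not an sai_report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab_path <- file.path(dir, paste0(prefix, "_sai_table.tsv"))
  sum_path <- file.path(dir, paste0(prefix, "_summary.json"))
  acc_path <- file.path(dir, paste0(prefix, "_accumulation.tsv"))

  t <- report$table
  out <- data.frame(fraction = fmt_num(t$fraction, 4), p = t$p, S = t$S,
                    R = fmt_num(t$R, 6), R_lo = fmt_num(t$R_lo, 6),
                    R_hi = fmt_num(t$R_hi, 6), O = t$O,
                    SAI = fmt_num(t$SAI, 6), significant = t$significant)
  utils::write.table(out, tab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summary <- list(mean_sai = report$mean_sai, stress = report$stress,
                  method = report$method, seed = report$seed,
                  n_sites = report$n_sites, n_species = report$n_species,
                  significant_fractions = sum(report$table$significant),
                  config = report$config)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, na = "null"), sum_path)

  ot <- report$optimal$table
  bt <- report$baseline$table
  acc <- data.frame(p = ot$p,
                    fraction = fmt_num(ot$p / report$n_sites, 4),
                    O = ot$O, R = fmt_num(bt$R, 6),
                    R_lo = fmt_num(bt$lo, 6), R_hi = fmt_num(bt$hi, 6))
  utils::write.table(acc, acc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(tab_path, sum_path, acc_path))
}
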