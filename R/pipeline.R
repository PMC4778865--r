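#' Assemble and validate a pipeline run configuration
#'
#' A run configuration bundles everything [run_pipeline()] needs: the input
#' occurrence table, the evaluation fractions, ordination and p-median
#' settings, the baseline replicate count, the master seed and the output
#' directory. Configurations round-trip losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param input path to an occurrence table.
#' @param out_dir output directory for reports and logs.
#' @param layout input layout, `"wide"` or `"long"`.
#' @param fractions site fractions evaluated.
#' @param resolution demand-grid side count.
#' @param n_starts,pool p-median heuristic settings.
#' @param n_reps random-baseline replicates.
#' @param ord_n_starts,ord_max_iter,ord_tol,hybrid_threshold,metric_weight
#'   ordination settings (see [ordination_config()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, out_dir, layout = c("wide", "long"),
                       fractions = default_fractions(), resolution = 100L,
                       n_starts = 32L, pool = 10L, n_reps = 1000L,
                       ord_n_starts = 10L, ord_max_iter = 1000L,
                       ord_tol = 1e-6, hybrid_threshold = 0.9,
                       metric_weight = 0.5, seed = 1L) {
  layout <- match.arg(layout)
  # constructor side effects validate the numeric settings
  ordination_config("nmds", n_starts = ord_n_starts, max_iter = ord_max_iter,
                    tol = ord_tol, hybrid_threshold = hybrid_threshold,
                    metric_weight = metric_weight)
  stopifnot(length(fractions) >= 1, all(fractions > 0 & fractions <= 1),
            resolution >= 2, n_starts >= 1, pool >= 1, n_reps >= 2)
  structure(list(input = input, out_dir = out_dir, layout = layout,
                 fractions = as.numeric(fractions),
                 resolution = as.integer(resolution),
                 n_starts = as.integer(n_starts), pool = as.integer(pool),
                 n_reps = as.integer(n_reps),
                 ord_n_starts = as.integer(ord_n_starts),
                 ord_max_iter = as.integer(ord_max_iter),
                 ord_tol = as.numeric(ord_tol),
                 hybrid_threshold = as.numeric(hybrid_threshold),
                 metric_weight = as.numeric(metric_weight),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full surrogacy pipeline from an occurrence table to a report
#'
#' Executes read, clean, dissimilarity, ordination, p-median selection,
#' benchmarks and SAI scoring, then writes the report files
#' ([export_report()]), the ordination coordinates
#' (`betasai_coordinates.tsv`), one selection file per fraction
#' (`betasai_selection_pNN.tsv`: rank, site id) and a run log with stage
#' timings, stage seeds and the configuration snapshot. The report files
#' are byte-identical across runs with the same configuration and seed
#' (timings live only in the log).
#'
#' @param config a [run_config()].
#' @return The `sai_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  log_lines <- c("betasai pipeline run",
                 paste0("master_seed: ", config$seed))
  stages <- character(0)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages <<- c(stages, sprintf("%-14s %8.2fs", name,
                                 proc.time()[["elapsed"]] - t0))
    out
  }
  m <- timed("read", read_occurrences(config$input, config$layout))
  mc <- timed("clean", clean_occurrences(m))
  cfg_n <- ordination_config("nmds", n_starts = config$ord_n_starts,
                             max_iter = config$ord_max_iter,
                             tol = config$ord_tol)
  cfg_h <- ordination_config("hmds", n_starts = config$ord_n_starts,
                             max_iter = config$ord_max_iter,
                             tol = config$ord_tol,
                             hybrid_threshold = config$hybrid_threshold,
                             metric_weight = config$metric_weight)
  report <- timed("evaluate",
    evaluate_surrogacy(mc, fractions = config$fractions,
                       config_nmds = cfg_n, config_hmds = cfg_h,
                       resolution = config$resolution,
                       n_starts = config$n_starts, pool = config$pool,
                       n_reps = config$n_reps, seed = config$seed))
  timed("export", {
    export_report(report, config$out_dir, "betasai")
    co <- report$ordination$coordinates
    coords <- data.frame(site_id = rownames(co),
                         x = sprintf("%.10g", co[, 1]),
                         y = sprintf("%.10g", co[, 2]))
    utils::write.table(coords,
                       file.path(config$out_dir, "betasai_coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_along(config$fractions)) {
      sel <- report$selections[[i]]
      out <- data.frame(rank = seq_along(sel),
                        site_id = rownames(mc)[sel])
      utils::write.table(out,
        file.path(config$out_dir,
                  sprintf("betasai_selection_p%02.0f.tsv",
                          100 * report$table$fraction[i])),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  log_lines <- c(log_lines,
                 sprintf("input: %s (%s)", config$input, config$layout),
                 sprintf("sites x species after cleaning: %d x %d",
                         nrow(mc), ncol(mc)),
                 sprintf("stage seeds: ordination=%d baseline=%d pmedian=%d",
                         derive_seed(config$seed, "ordination"),
                         derive_seed(config$seed, "baseline"),
                         derive_seed(config$seed, "pmedian")),
                 "stage timings:", stages,
                 "config:",
                 paste0("  ", names(unclass(config)), ": ",
                        vapply(unclass(config), function(v)
                          paste(format(v), collapse = ","), character(1))))
  writeLines(log_lines, file.path(config$out_dir, "betasai_run_log.txt"))
  invisible(report)
}

#' Generate and write a synthetic fixture in one call
#'
#' Convenience wrapper over the synthetic-community generators and
#' [write_fixture()]; the seed is echoed in the file prefix.
#'
#' @param dir output directory.
#' @param type `"unimodal"` or `"null"`.
#' @param n_sites,n_species community dimensions.
#' @param seed integer seed.
#' @param ... passed on to [generate_unimodal()] / [generate_null()].
#' @return The paths written, invisibly; the community as attribute
#'   `community`.
#' @export
simulate_fixture <- function(dir, type = c("unimodal", "null"),
                             n_sites = 300L, n_species = 150L, seed = 1L,
                             ...) {
  type <- match.arg(type)
  com <- if (type == "unimodal")
    generate_unimodal(n_sites, n_species, seed = seed, ...)
  else generate_null(n_sites, n_species, seed = seed, ...)
  prefix <- sprintf("%s_seed%d", type, as.integer(seed))
  paths <- write_fixture(com, dir, prefix)
  attr(paths, "community") <- com
  invisible(paths)
}
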