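#' Coerce and validate a site-by-species occurrence matrix
#'
#' Occurrence data are strictly presence/absence: a logical matrix, or a
#' numeric matrix containing only 0 and 1. Positive abundances are an error,
#' not silently binarized, because the downstream Jaccard index is defined
#' for incidence data only.
#'
#' @param x matrix or data frame, sites in rows, species in columns.
#' @return A logical matrix with unique row (site) and column (species)
#'   names.
#' @examples
#' as_occurrence_matrix(matrix(c(1, 0, 0, 1), 2, 2))
#' @export
as_occurrence_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("occurrence data must be a matrix or data frame")
  if (length(x) == 0) stop("occurrence matrix is empty")
  if (is.numeric(x)) {
    bad <- which(!(x == 0 | x == 1))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(x))
      stop(sprintf(
        "non-binary value %s at row %d, column %d: abundances are not accepted, supply presence/absence (0/1)",
        format(x[bad[1]]), rc[1], rc[2]))
    }
    x <- x == 1
  }
  if (!is.logical(x)) stop("occurrence matrix must be logical or 0/1 numeric")
  if (anyNA(x)) stop("occurrence matrix contains missing values")
  if (is.null(rownames(x))) rownames(x) <- paste0("site_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp_", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicated site ids")
  if (anyDuplicated(colnames(x))) stop("duplicated species ids")
  x
}

#' Read an occurrence table from delimited text
#'
#' Two layouts are supported. `wide`: a header row of species names, first
#' column site labels, remaining cells 0/1 (comma or tab, autodetected).
#' `long`: two delimited columns (site, species), one record per occurrence;
#' duplicate records collapse to a single presence, and an initial header
#' line is skipped when its fields match `header_tokens`.
#'
#' @param path file path.
#' @param layout `"wide"` or `"long"`.
#' @param header_tokens for long layout, field names recognised (case
#'   insensitively) as a header line.
#' @return A logical occurrence matrix (see [as_occurrence_matrix()]). The
#'   matrix is not cleaned: empty sites or species are kept and should be
#'   handled with [clean_occurrences()].
#' @seealso [write_occurrences()], [clean_occurrences()]
#' @export
read_occurrences <- function(path, layout = c("wide", "long"),
                             header_tokens = c("site", "species")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (file.size(path) == 0) stop("input file is empty: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  if (layout == "wide") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, colClasses = "character",
                             quote = "\"", comment.char = "")
    if (nrow(tab) == 0 || ncol(tab) < 2)
      stop("wide occurrence table needs a site column and >= 1 species column")
    sites <- tab[[1]]
    cells <- as.matrix(tab[, -1, drop = FALSE])
    ok <- cells == "0" | cells == "1"
    if (!all(ok)) {
      rc <- which(!ok, arr.ind = TRUE)[1, ]
      stop(sprintf("malformed cell at row '%s', column '%s': '%s' (expected 0 or 1)",
                   sites[rc[1]], colnames(cells)[rc[2]], cells[rc[1], rc[2]]))
    }
    m <- cells == "1"
    rownames(m) <- sites
    as_occurrence_matrix(m)
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = sep,
                             check.names = FALSE, colClasses = "character",
                             quote = "\"", comment.char = "")
    if (ncol(tab) < 2) stop("long occurrence table needs two columns (site, species)")
    tab <- tab[, 1:2]
    if (nrow(tab) >= 1 &&
        all(tolower(trimws(unlist(tab[1, ]))) %in% tolower(header_tokens)))
      tab <- tab[-1, , drop = FALSE]
    if (nrow(tab) == 0) stop("no occurrence records in ", path)
    sites <- unique(tab[[1]])
    species <- unique(tab[[2]])
    m <- matrix(FALSE, length(sites), length(species),
                dimnames = list(sites, species))
    m[cbind(match(tab[[1]], sites), match(tab[[2]], species))] <- TRUE
    as_occurrence_matrix(m)
  }
}

#' Write an occurrence matrix as delimited text
#'
#' @param m occurrence matrix.
#' @param path output file.
#' @param layout `"wide"` (0/1 table, first column `site`) or `"long"`
#'   (site, species records with a header line).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(m, path, layout = c("wide", "long"), sep = "\t") {
  layout <- match.arg(layout)
  m <- as_occurrence_matrix(m)
  if (layout == "wide") {
    out <- data.frame(site = rownames(m),
                      ifelse(m, "1", "0"),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(out) <- c("site", colnames(m))
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(m, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    out <- data.frame(site = rownames(m)[idx[, 1]],
                      species = colnames(m)[idx[, 2]],
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Remove empty sites and unobserved species
#'
#' Sites with no recorded species have undefined Jaccard dissimilarity to
#' every other site, and species observed nowhere carry no information;
#' both are dropped, with a warning naming how many of each were removed.
#' The order of the remaining ids is preserved.
#'
#' @param m occurrence matrix.
#' @param min_sites minimum number of sites that must remain (ordination in
#'   two dimensions needs at least 3).
#' @return The cleaned matrix, with attribute `removed` (a list with
#'   elements `sites` and `species` naming what was dropped).
#' @export
clean_occurrences <- function(m, min_sites = 3L) {
  m <- as_occurrence_matrix(m)
  empty_sites <- rowSums(m) == 0
  empty_species <- colSums(m) == 0
  removed <- list(sites = rownames(m)[empty_sites],
                  species = colnames(m)[empty_species])
  if (any(empty_sites) || any(empty_species)) {
    warning(sprintf("removed %d empty site(s) and %d unobserved species",
                    sum(empty_sites), sum(empty_species)))
    m <- m[!empty_sites, !empty_species, drop = FALSE]
  }
  if (nrow(m) < min_sites)
    stop("fewer than ", min_sites, " non-empty sites remain; ordination impossible")
  if (ncol(m) < 1) stop("no species remain after cleaning")
  attr(m, "removed") <- removed
  m
}

#' Pairwise Jaccard dissimilarity between site assemblages
#'
#' For sites i and j with species sets A_i and A_j, the dissimilarity is
#' \eqn{d_{ij} = 1 - |A_i \cap A_j| / |A_i \cup A_j|} (one minus Jaccard
#' similarity), the standard incidence-based measure of beta diversity. The
#' result is a metric: symmetric, zero on the diagonal, in \[0, 1\], and
#' satisfying the triangle inequality.
#'
#' @param m occurrence matrix with no empty sites (see
#'   [clean_occurrences()]).
#' @return A [stats::dist] object with site labels.
#' @examples
#' m <- rbind(s1 = c(a = 1, b = 1, c = 1, d = 0),
#'            s2 = c(a = 0, b = 1, c = 1, d = 1))
#' jaccard_dissimilarity(m) # 1 - 2/4 = 0.5
#' @export
jaccard_dissimilarity <- function(m) {
  m <- as_occurrence_matrix(m)
  if (any(rowSums(m) == 0))
    stop("matrix contains empty sites; run clean_occurrences() first")
  mm <- matrix(as.numeric(m), nrow(m), ncol(m))
  inter <- tcrossprod(mm)
  sz <- rowSums(mm)
  un <- outer(sz, sz, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  d[d < 0] <- 0 # guard against negative float fuzz
  dimnames(d) <- list(rownames(m), rownames(m))
  stats::as.dist(d)
}
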