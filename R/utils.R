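# internal helpers shared across modules

# Stage-seed derivation: every stochastic stage draws from its own seed,
# deterministically derived from the master seed, so any stage can be rerun
# in isolation. Offsets are fixed and documented in the methods vignette.
.stage_offsets <- c(env = 7L, params = 11L, presence = 17L, ordination = 23L,
                    pmedian = 37L, baseline = 53L, selector = 71L)

derive_seed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) + off * 1009 + index * 101) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state; the caller's stream is
# untouched. A NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# row/col indices of each pair in `dist` element order ((2,1),(3,1),...)
pair_indices <- function(n) {
  which(lower.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
}

# tie-block structure of a dissimilarity vector: 0-based sort order plus
# 0-based block starts (one block per run of equal values)
tie_blocks <- function(delta) {
  ord <- order(delta)
  sorted <- delta[ord]
  np <- length(delta)
  bstart <- c(0L, which(diff(sorted) != 0), np)
  list(ord = as.integer(ord - 1L), bstart = as.integer(bstart))
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
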