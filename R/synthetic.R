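#' Niche parameter sampling specification
#'
#' Ranges from which per-species niche parameters are drawn: optima
#' \eqn{\mu_j} uniform on `mu_range` per gradient, tolerances (niche
#' breadths) \eqn{\sigma_j} uniform on `sigma_range`, peak occurrence
#' probabilities \eqn{h_j} uniform on `h_range`. The defaults give
#' communities with marked turnover along both gradients: breadths of
#' 0.05-0.25 gradient units on a unit square, peaks of 0.5-1.
#'
#' @param mu_range,sigma_range,h_range numeric length-2 ranges; sigma must
#'   be strictly positive and h within (0, 1].
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(mu_range = c(0, 1), sigma_range = c(0.05, 0.25),
                       h_range = c(0.5, 1)) {
  stopifnot(length(mu_range) == 2, length(sigma_range) == 2,
            length(h_range) == 2)
  if (min(sigma_range) <= 0) stop("sigma must be strictly positive")
  if (min(h_range) <= 0 || max(h_range) > 1) stop("h must lie in (0, 1]")
  structure(list(mu_range = as.numeric(mu_range),
                 sigma_range = as.numeric(sigma_range),
                 h_range = as.numeric(h_range)),
            class = "niche_spec")
}

site_env <- function(n_sites, env_model, rho) {
  if (env_model == "uniform") {
    matrix(stats::runif(n_sites * 2), n_sites, 2,
           dimnames = list(NULL, c("env1", "env2")))
  } else { # gradient-correlated: second gradient partially tracks the first
    u1 <- stats::runif(n_sites)
    u2 <- stats::runif(n_sites)
    cbind(env1 = u1, env2 = rho * u1 + (1 - rho) * u2)
  }
}

occurrence_probability <- function(env, truth) {
  n <- nrow(env)
  s <- length(truth$h)
  z1 <- outer(env[, 1], truth$mu[, 1], "-") /
    matrix(truth$sigma[, 1], n, s, byrow = TRUE)
  z2 <- outer(env[, 2], truth$mu[, 2], "-") /
    matrix(truth$sigma[, 2], n, s, byrow = TRUE)
  matrix(truth$h, n, s, byrow = TRUE) * exp(-0.5 * (z1^2 + z2^2))
}

make_community <- function(pres, env, truth, seed, model) {
  rownames(pres) <- sprintf("site_%03d", seq_len(nrow(pres)))
  colnames(pres) <- sprintf("sp_%03d", seq_len(ncol(pres)))
  rownames(env) <- rownames(pres)
  structure(list(occurrences = as_occurrence_matrix(pres),
                 environment = env, truth = truth, seed = seed,
                 model = model),
            class = "synthetic_community")
}

#' Simulate a community with unimodal niches on two gradients
#'
#' Sites receive positions on two environmental gradients in the unit
#' square; each species j has a Gaussian occurrence-probability response
#' \deqn{\pi_{ij} = h_j \exp(-\tfrac12 [((e_{i1}-\mu_{j1})/\sigma_{j1})^2 +
#' ((e_{i2}-\mu_{j2})/\sigma_{j2})^2])}
#' and presences are independent Bernoulli(\eqn{\pi_{ij}}) draws. This is
#' the data-generating process the beta-diversity surrogate assumes
#' (unimodal species distributions in environmental space), so pipelines run
#' on these communities quantify best-case surrogate performance.
#'
#' The seed is split internally (environment / parameters / presences), so
#' regenerating from the stored truth, environment and seed reproduces the
#' presences exactly (see [regenerate_community()]).
#'
#' @param n_sites,n_species community dimensions (reference conditions: 300
#'   sites, 150 species).
#' @param env_model `"uniform"` (independent gradients) or
#'   `"gradient-correlated"`.
#' @param niche a [niche_spec()].
#' @param seed integer seed.
#' @param rho gradient correlation used by `"gradient-correlated"`.
#' @return An object of class `synthetic_community`: `occurrences`
#'   (logical matrix, possibly containing empty sites or species — clean
#'   before analysis), `environment`, `truth` (the niche parameters) and
#'   `seed`.
#' @export
generate_unimodal <- function(n_sites = 300L, n_species = 150L,
                              env_model = c("uniform", "gradient-correlated"),
                              niche = niche_spec(), seed = 1L, rho = 0.5) {
  env_model <- match.arg(env_model)
  seed <- as.integer(seed)
  if (n_sites < 3 || n_species < 1) stop("need n_sites >= 3 and n_species >= 1")
  if (!inherits(niche, "niche_spec")) stop("niche must be a niche_spec()")
  env <- with_seed(derive_seed(seed, "env"),
                   site_env(n_sites, env_model, rho))
  truth <- with_seed(derive_seed(seed, "params"), {
    list(mu = matrix(stats::runif(n_species * 2, niche$mu_range[1],
                                  niche$mu_range[2]), n_species, 2),
         sigma = matrix(stats::runif(n_species * 2, niche$sigma_range[1],
                                     niche$sigma_range[2]), n_species, 2),
         h = stats::runif(n_species, niche$h_range[1], niche$h_range[2]))
  })
  pi_mat <- occurrence_probability(env, truth)
  pres <- with_seed(derive_seed(seed, "presence"),
                    matrix(stats::runif(n_sites * n_species), n_sites,
                           n_species) < pi_mat)
  make_community(pres, env, truth, seed, paste0("unimodal-", env_model))
}

#' Expected occupancy of a Gaussian niche over a uniform environment
#'
#' For a species with peak probability h, optimum mu and tolerance sigma on
#' each of two independent gradients uniform on \[0, 1\], the expected
#' occurrence probability is \eqn{h \prod_k \sigma_k \sqrt{2\pi}
#' [\Phi((1-\mu_k)/\sigma_k) - \Phi(-\mu_k/\sigma_k)]} (the mass of the
#' truncated Gaussian response).
#'
#' @param truth a list with `mu`, `sigma` (n_species x 2) and `h`.
#' @return Per-species expected occupancy probabilities.
#' @export
niche_occupancy <- function(truth) {
  mass <- function(mu, sigma)
    sigma * sqrt(2 * pi) *
      (stats::pnorm((1 - mu) / sigma) - stats::pnorm(-mu / sigma))
  truth$h * mass(truth$mu[, 1], truth$sigma[, 1]) *
    mass(truth$mu[, 2], truth$sigma[, 2])
}

#' Simulate an environment-independent null community
#'
#' Presences are Bernoulli draws with per-species occupancies that do not
#' depend on any gradient; site environments are still generated (and
#' stored) for interface uniformity but play no role. Null communities are
#' the negative control: beta diversity carries no environmental signal, so
#' a correct surrogacy pipeline should score SAI near zero on them.
#'
#' @param n_sites,n_species community dimensions.
#' @param occupancy per-species presence probabilities in (0, 1]. The
#'   default draws niche parameters from `niche` and uses their implied
#'   occupancies ([niche_occupancy()]), so the null matches the unimodal
#'   reference community's occupancy (and accumulation-saturation) profile
#'   while severing only the environment link.
#' @param niche a [niche_spec()] used by the default occupancy.
#' @param seed integer seed.
#' @return A `synthetic_community` whose `truth` holds the occupancy
#'   vector.
#' @export
generate_null <- function(n_sites = 300L, n_species = 150L, occupancy = NULL,
                          niche = niche_spec(), seed = 1L) {
  seed <- as.integer(seed)
  if (n_sites < 3 || n_species < 1) stop("need n_sites >= 3 and n_species >= 1")
  env <- with_seed(derive_seed(seed, "env"), site_env(n_sites, "uniform", 0))
  if (is.null(occupancy)) {
    pars <- with_seed(derive_seed(seed, "params"), {
      list(mu = matrix(stats::runif(n_species * 2, niche$mu_range[1],
                                    niche$mu_range[2]), n_species, 2),
           sigma = matrix(stats::runif(n_species * 2, niche$sigma_range[1],
                                       niche$sigma_range[2]), n_species, 2),
           h = stats::runif(n_species, niche$h_range[1], niche$h_range[2]))
    })
    occupancy <- pmin(1, pmax(niche_occupancy(pars), 1e-4))
  }
  occupancy <- rep_len(as.numeric(occupancy), n_species)
  if (any(occupancy <= 0) || any(occupancy > 1))
    stop("occupancy probabilities must lie in (0, 1]")
  pres <- with_seed(derive_seed(seed, "presence"),
                    matrix(stats::runif(n_sites * n_species), n_sites,
                           n_species) <
                      matrix(occupancy, n_sites, n_species, byrow = TRUE))
  make_community(pres, env, list(occupancy = occupancy), seed, "null")
}

#' Regenerate presences from stored truth, environment and seed
#'
#' @param community a `synthetic_community`.
#' @return A new `synthetic_community`; its occurrence matrix equals the
#'   original exactly (the seed contract).
#' @export
regenerate_community <- function(community) {
  stopifnot(inherits(community, "synthetic_community"))
  env <- community$environment
  truth <- community$truth
  n <- nrow(env)
  if (community$model == "null") {
    s <- length(truth$occupancy)
    pi_mat <- matrix(truth$occupancy, n, s, byrow = TRUE)
  } else {
    s <- length(truth$h)
    pi_mat <- occurrence_probability(env, truth)
  }
  pres <- with_seed(derive_seed(community$seed, "presence"),
                    matrix(stats::runif(n * s), n, s) < pi_mat)
  make_community(pres, env, truth, community$seed, community$model)
}

#' Aggregate fine sites into atlas-like grid cells
#'
#' Emulates atlas data: sites are binned into a `cells` x `cells` lattice
#' over environmental space and each cell's assemblage is the union of its
#' member sites' assemblages. Cells containing no site are dropped.
#'
#' @param community a `synthetic_community`.
#' @param cells lattice side count.
#' @return A `synthetic_community` of cells (truth and seed carried over;
#'   `environment` holds cell centers).
#' @export
coarsen_to_grid <- function(community, cells = 10L) {
  stopifnot(inherits(community, "synthetic_community"), cells >= 1)
  env <- community$environment
  cut_idx <- function(x) pmin(pmax(ceiling(x * cells), 1L), cells)
  cx <- cut_idx(env[, 1])
  cy <- cut_idx(env[, 2])
  key <- (cx - 1L) * cells + cy
  cells_used <- sort(unique(key))
  m <- community$occurrences
  agg <- t(vapply(cells_used,
                  function(k) colSums(m[key == k, , drop = FALSE]) > 0,
                  logical(ncol(m))))
  rownames(agg) <- sprintf("cell_%03d", cells_used)
  cenv <- cbind(env1 = (ceiling(cells_used / cells) - 0.5) / cells,
                env2 = ((cells_used - 1L) %% cells + 0.5) / cells)
  rownames(cenv) <- rownames(agg)
  structure(list(occurrences = as_occurrence_matrix(agg), environment = cenv,
                 truth = community$truth, seed = community$seed,
                 model = paste0(community$model, "-atlas")),
            class = "synthetic_community")
}

#' Write a synthetic community to plain-text fixture files
#'
#' Writes the wide occurrence table, the environment table, the truth
#' parameters and a small YAML meta file; [read_fixture()] restores the
#' community and [regenerate_community()] then reproduces the presences
#' exactly.
#'
#' @param community a `synthetic_community`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Paths written, invisibly.
#' @export
write_fixture <- function(community, dir, prefix = "community") {
  stopifnot(inherits(community, "synthetic_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  occ_path <- file.path(dir, paste0(prefix, "_occurrences.tsv"))
  env_path <- file.path(dir, paste0(prefix, "_environment.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.yml"))
  write_occurrences(community$occurrences, occ_path, "wide")
  env <- data.frame(site = rownames(community$environment),
                    env1 = sprintf("%.17g", community$environment[, 1]),
                    env2 = sprintf("%.17g", community$environment[, 2]))
  utils::write.table(env, env_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- community$truth
  if (community$model == "null") {
    tt <- data.frame(species = colnames(community$occurrences),
                     occupancy = sprintf("%.17g", tr$occupancy))
  } else {
    tt <- data.frame(species = colnames(community$occurrences),
                     mu1 = sprintf("%.17g", tr$mu[, 1]),
                     mu2 = sprintf("%.17g", tr$mu[, 2]),
                     sigma1 = sprintf("%.17g", tr$sigma[, 1]),
                     sigma2 = sprintf("%.17g", tr$sigma[, 2]),
                     h = sprintf("%.17g", tr$h))
  }
  utils::write.table(tt, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(model = community$model, seed = community$seed,
                        n_sites = nrow(community$occurrences),
                        n_species = ncol(community$occurrences)),
                   meta_path)
  invisible(c(occ_path, env_path, truth_path, meta_path))
}

#' Read a synthetic-community fixture written by [write_fixture()]
#'
#' @param dir directory holding the fixture files.
#' @param prefix file-name prefix used when writing.
#' @return A `synthetic_community`.
#' @export
read_fixture <- function(dir, prefix = "community") {
  meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yml")))
  occ <- read_occurrences(file.path(dir, paste0(prefix, "_occurrences.tsv")),
                          "wide")
  envt <- utils::read.table(file.path(dir, paste0(prefix, "_environment.tsv")),
                            header = TRUE, sep = "\t")
  env <- as.matrix(envt[, c("env1", "env2")])
  rownames(env) <- envt$site
  tt <- utils::read.table(file.path(dir, paste0(prefix, "_truth.tsv")),
                          header = TRUE, sep = "\t")
  truth <- if (identical(meta$model, "null")) {
    list(occupancy = tt$occupancy)
  } else {
    list(mu = cbind(tt$mu1, tt$mu2), sigma = cbind(tt$sigma1, tt$sigma2),
         h = tt$h)
  }
  structure(list(occurrences = occ, environment = env, truth = truth,
                 seed = meta$seed, model = meta$model),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("synthetic community (%s): %d sites x %d species, seed %s\n",
              x$model, nrow(x$occurrences), ncol(x$occurrences),
              format(x$seed)))
  invisible(x)
}
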