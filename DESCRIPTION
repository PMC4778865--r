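Package: betasai
Title: Beta-Diversity Surrogates for Species Representation via the
    Species Accumulation Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates how efficiently conservation sites selected to span
    compositional dissimilarity (beta diversity) represent species. Builds
    Jaccard dissimilarity matrices from presence-absence data, ordinates
    sites in two dimensions by nonmetric or hybrid multidimensional scaling,
    selects sites with a multistart p-median heuristic over a regular grid
    of demand points in ordination space, and scores selections with the
    Species Accumulation Index (SAI) against optimal and random benchmarks.
    Includes a synthetic community generator with unimodal (Gaussian)
    species responses along environmental gradients for end-to-end
    calibration and null testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
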