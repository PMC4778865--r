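---
title: "Beta-diversity surrogacy with betasai: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-diversity surrogacy with betasai}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(betasai)
```

## The question the package answers

Conservation planners rarely know where every species lives. A classic
workaround is the *indirect environmental diversity* strategy: arrange the
sites of a well-surveyed indicator taxon in an ordination whose distances
reflect assemblage dissimilarity (β diversity), then select the p sites
that best *span* that space. If each species has a unimodal response to
the underlying environmental gradients, sites spread across assemblage
space should sample many different environments and therefore many
species — including species never recorded in the survey.

`betasai` implements that pipeline end to end and scores it with the
Species Accumulation Index,

$$\mathrm{SAI} = \frac{S - R}{O - R},$$

where, for a given number of sites p: S is the species count represented
by the surrogate-selected sites, R the mean count over random selections
of p sites, and O the best achievable count. SAI is 1 when the surrogate
matches the optimum, 0 when it does no better than random, and negative
when it is worse than random. The pipeline evaluates p at 15, 20, 25, 30
and 35% of the sites and averages the five values.

## Pipeline stages and their assumptions

**Dissimilarity.** Jaccard dissimilarity on presence/absence data,
$d_{ij} = 1 - |A_i \cap A_j|/|A_i \cup A_j|$. It is a metric (the triangle
inequality is property-tested), and it is appropriate for incidence data;
abundance-based measures are deliberately out of scope, and abundances in
the input are an error rather than being silently binarized. Sites with
empty assemblages have no defined dissimilarity and are removed by
`clean_occurrences()` rather than given a 0/0 convention.

**Ordination.** `nmds()` minimizes Kruskal's stress-1
$\sqrt{\sum (d - \hat d)^2 / \sum d^2}$ by SMACOF-style majorization:
configuration distances are fit by least-squares monotone regression
(pool-adjacent-violators) on the dissimilarity order, with Kruskal's
primary treatment of ties (tied dissimilarities unconstrained among
themselves), followed by a Guttman transform. The update is over-relaxed
(step doubling) with fallback to the plain transform whenever a doubled
step would increase stress, so each start's recorded stress trace is
non-increasing; this roughly halves the iteration count without changing
fixed points. Start 1 is classical (metric) scaling; the remaining starts
are uniform random configurations. `hmds()` adds a metric least-squares
term — a through-origin linear fit of distance on dissimilarity —
restricted to pairs with dissimilarity below `hybrid_threshold` (default
0.9), blended with weight `metric_weight` (default 0.5, equal weighting;
0 reduces HMDS to NMDS exactly). The rationale is that large Jaccard
values saturate at 1 and carry rank information only, while small values
are nearly linear in ecological distance. `best_ordination()` fits both
and keeps the configuration with the lower *purely nonmetric* stress-1 —
the two methods' internal losses are not on a common scale, so the
comparison is made on recomputed nonmetric stress; ties go to NMDS.

Defaults: 2 dimensions (fixed; the demand grid and the selection stage
are two-dimensional by construction), 10 starts, up to 1000 iterations
per start, relative stress-change tolerance 1e-6. Orientation is made
reproducible by centering and fixing the sign of each axis so its
largest-magnitude coordinate is positive; downstream stages use distances
only, so this is cosmetic.

**Demand grid and p-median selection.** `make_demand_grid()` lays a
`resolution` × `resolution` lattice (default 100, hence 10,000 points)
over the axis-aligned bounding box of the site coordinates, corners
included. The bounding box is the plainest reading of "a grid across
ordination space"; clipping to the convex hull of the sites was
considered and left out (with outlier-free data the two nearly coincide,
and the hull adds an arbitrary masking rule). All demand points carry
equal weight and distances are Euclidean.

`select_pmedian()` minimizes the summed demand-point-to-nearest-selected-
site distance with a multistart hybrid heuristic modeled on the classic
GRASP-with-path-relinking designs for the p-median problem: randomized
lazy-greedy construction (a random seed site, then greedy completion;
start 1 is pure deterministic greedy, which also gives the tested
guarantee that the final result never trails plain greedy), Teitz–Bart
style vertex-substitution local search with incrementally maintained
gain/loss tables, and path relinking among the ten best distinct local
optima of 32 starts. Within `evaluate_surrogacy()` the five fractions
share one heuristic invocation: greedy constructions are nested in p, so
each start's order serves every fraction's local search as a prefix —
the same algorithm, with less repeated construction work. Exactness on
small instances is verified against `select_pmedian_exact()`, a pruned
exhaustive enumeration (ties resolved to the lexicographically smallest
set; all other tie-breaks in the package also prefer the lowest site
index).

**Optimal benchmark O.** Three estimators are combined: forward greedy
complementarity (`greedy_max_coverage()`), the retained sets of a
backward *core-area removal* ranking (`core_area_removal()`: repeatedly
drop the site whose rarest remaining species is most widespread,
v_i = max_j 1/r_j, keeping each species' last occurrences to the end —
with core size fixed at one occurrence and one site removed per step),
and, wherever the subset count `choose(n, p)` is at most `exact_limit`
(default 1e5), exhaustive bitset search. O(p) is the maximum of the
three; greedy and backward removal can each be beaten on particular
instances, and the exhaustive branch makes O exact on every instance
small enough to check, which the oracle tests exercise. If a surrogate
selection nevertheless exceeds O at some p (possible only in the purely
heuristic regime), O is raised to S with a warning, which keeps SAI ≤ 1
and flags the instance.

**Random baseline R.** 1,000 random site orders, species counts
accumulated at every p in one pass per order; R is the mean and the 95%
interval the 2.5th/97.5th percentiles of the replicate counts —
percentile bounds rather than a normal approximation, because the counts
are discrete and skewed near saturation. A fraction is flagged
*significant* when S lies strictly above the 97.5th percentile.

**Aggregation.** p = round(fraction × n), with a floor of 1. The mean SAI
is the unweighted average of the five per-fraction values. When O = R at
some fraction (a fully saturated accumulation curve) that fraction's SAI
is undefined (NaN) and is excluded from the mean, with a warning; the
mean is NaN only if every fraction is saturated.

## Reproducibility machinery

Every stochastic stage draws from its own seed, derived from the master
seed by fixed offsets (`community` environment/parameters/presences,
`ordination`, `pmedian`, `baseline`, `selector`; see
`betasai:::.stage_offsets`). Stages can therefore be rerun in isolation,
and two runs with the same configuration and seed produce byte-identical
report files — number formatting in the exports is fixed-width for
exactly this reason, and wall-clock timings go only to the run log.
Synthetic communities can be regenerated exactly from their stored truth
(niche parameters), environment and seed.

## The synthetic test bed

`generate_unimodal()` instantiates the method's core assumption: sites
uniform on two gradients in the unit square and species with Gaussian
occurrence-probability responses
$\pi_{ij} = h_j \exp(-\frac12[((e_{i1}-\mu_{j1})/\sigma_{j1})^2 +
((e_{i2}-\mu_{j2})/\sigma_{j2})^2])$, presence Bernoulli($\pi_{ij}$).
Reference conditions: 300 sites × 150 species, μ uniform on the unit
square, σ ~ U(0.05, 0.25) per gradient, h ~ U(0.5, 1). A
gradient-correlated environment model and an atlas-style coarsening
(unions of member assemblages per grid cell) are available as variants.
`generate_null()` is the negative control: the same marginal occupancy
profile — each species' occupancy is the analytic mass of a Gaussian
niche drawn from the same specification (`niche_occupancy()`) — but
presences independent of the environment. Matching the occupancy profile
matters: it equalizes the accumulation-curve shape, so unimodal and null
runs differ only in the environmental signal, which is exactly what the
surrogate is supposed to exploit.

What the generator does *not* emulate: spatial autocorrelation beyond
the environment, dispersal limitation, disturbance, interspecific
interactions, observation error, or skewed (log-series-like) abundance
structures. Passing the recovery tests therefore shows the pipeline
extracts an environmental signal when one exists in the assumed form; it
does not show that real landscapes carry such a signal.

## Numerical choices and degenerate inputs

Tolerances: stress convergence 1e-6 (relative change per iteration);
swap-search improvements must exceed 1e-12; the metric oracle comparisons
in the tests run at 1e-9 to 1e-12. Collapsed ordination configurations
(all distances zero) are detected and the start discarded; a degenerate
ordination with zero extent on an axis is an error at the demand-grid
stage. Cleaning requires at least 3 surviving sites (a 2-D ordination of
fewer is meaningless) and at least one species. Empty selections are an
error for the p-median objective and legitimate (count 0) for species
representation.

## Problem sizes used in the validation suite

The oracle-equivalence checks run 100 random instances with up to 12
sites (exhaustive enumeration stays trivial there); calibration of the
SAI identity uses a 200 × 150 community where the denominators O − R are
comfortably positive at all five fractions; the recovery and null
simulation studies use the reference 300 × 150 conditions with 30 seeds
per arm; determinism is checked at 60 sites. These sizes keep the whole
suite within a desktop-scale run while still exercising the reference
conditions end to end.

## Known limitations

* **Accumulation saturation bounds SAI's informative range.** At the
  reference conditions the median species occupies ~21 of 300 sites, so
  random selection already represents ~93% of species at p = 45 and ~99%
  at p = 105: O − R shrinks from ~11 species at the 15% fraction to ~1 at
  35%. A one-species fluctuation in S then moves SAI by a full unit at
  the top fractions, and the strict significance flag becomes
  unattainable there for *any* selector once the random interval's upper
  bound reaches the species total. Mean SAI across seeds is positive for
  most seeds but individual seeds can swing far negative purely through
  this denominator effect. Real inventories with many rare species
  saturate far more slowly; interpret per-fraction SAI together with the
  exported accumulation curves, and distrust SAI wherever O − R is only a
  few species.
* **Solution degeneracy of the p-median stage.** Near-optimal selections
  with practically identical objectives can differ by several represented
  species; the heuristic's seed therefore contributes visible SAI noise
  even at fixed data. This is a property of the surrogate criterion (it
  optimizes spanning, not coverage), not of the optimizer.
* **Within-taxon evaluation only.** The data model would permit scoring
  one taxon's selection against another taxon sharing the site set, but
  no operation implements cross-taxon surrogacy; results here are the
  optimistic within-taxon case.
* Stress values from other NMDS software are comparable only
  approximately (stress formula variants, tie handling and stopping rules
  differ); the test suite checks agreement with an independent
  implementation to within 0.02 stress units rather than bit equality.
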