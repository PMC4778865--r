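# betasai

Evaluates **β diversity as a conservation surrogate**: if you select sites
so that they span the compositional dissimilarity of a well-surveyed
taxon, how many species do those sites actually protect, compared with
picking sites at random or picking them with full knowledge of every
species' distribution?

The package is aimed at conservation planners and community ecologists
working with site-by-species presence/absence tables (vegetation plots,
bird atlases, grid-cell inventories), and at methodologists who want a
fully synthetic, ground-truthed test bed for surrogacy pipelines.

## The method

For a site-by-species incidence matrix the pipeline runs:

1. **β diversity** — pairwise Jaccard dissimilarity
   d<sub>ij</sub> = 1 − |A<sub>i</sub> ∩ A<sub>j</sub>| / |A<sub>i</sub> ∪ A<sub>j</sub>|
   between the species sets of all site pairs.
2. **Ordination** — nonmetric multidimensional scaling (NMDS) and hybrid
   MDS (HMDS: an extra metric least-squares term for pairs below a
   dissimilarity threshold, countering the saturation of Jaccard distance
   at 1), each the best of 10 starts with up to 1000 majorization
   iterations; the lower-stress configuration is kept.
3. **Site selection** — a regular grid of 10,000 demand points is laid
   over the ordination and a multistart p-median heuristic (randomized
   greedy construction, vertex-substitution local search, path relinking
   among the 10 best of 32 starts) picks the p sites minimizing total
   demand-point-to-nearest-site distance, i.e. the sites that best span
   β-diversity space.
4. **Scoring** — the **Species Accumulation Index**
   `SAI = (S − R) / (O − R)`, where S is the number of species in the
   selected sites, R the mean over 1,000 random selections of the same
   size (with a 95% percentile interval), and O the optimal benchmark
   (max of forward-greedy complementarity, backward core-area removal,
   and exhaustive search where feasible). SAI is 1 for optimal, 0 for
   random, negative for worse than random. The pipeline reports SAI at
   15–35% of sites and their mean.

A synthetic-community module generates data with the structure the method
assumes — Gaussian (unimodal) species responses along two environmental
gradients, Bernoulli presences — plus matched environment-independent null
communities, so every stage can be validated without external data.

## Worked example

```r
library(betasai)

com <- generate_unimodal(120, 80, seed = 5)      # sites x species, 2 gradients
m   <- clean_occurrences(com$occurrences)        # drop empty sites/species
rep <- evaluate_surrogacy(m, seed = 5)           # full pipeline
rep
```

```
SAI report: 120 sites x 80 species, ordination = nmds (stress 0.1073)
 fraction  p  S      R   R_lo R_hi  O         SAI significant
     0.15 18 55 55.261 47.000   63 80 -0.01055014       FALSE
     0.20 24 68 61.570 53.975   68 80  0.34888768       FALSE
     0.25 30 70 65.954 59.000   72 80  0.28805354       FALSE
     0.30 36 71 69.006 63.000   74 80  0.18137166       FALSE
     0.35 42 75 71.283 66.000   76 80  0.42640817       FALSE
mean SAI = 0.2468
```

Reading this run: at 25% of sites the β-diversity selection represents 70
species, random selection averages 66.0 (95% interval 59–72), and the
best possible 30-site network holds all 80 — so the surrogate delivered
29% of the achievable improvement over random (SAI 0.29), 25% on average
across fractions. No fraction clears the strict significance flag (S
above the random 97.5th percentile); per-seed SAI is noisy at this
community size. `export_report()` writes the table, a JSON summary and the
full accumulation curves; `run_pipeline(run_config(...))` does everything
from a file on disk and logs stage seeds and timings.

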