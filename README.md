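# nestshore

Multivariate biostatistics for sandy-beach metacommunities: morphodynamic
indexing of sites, spatial eigenfunction analysis with variation
partitioning, community dissimilarity ordination, and gradient-ordered
nestedness testing under fixed-margin null models — plus a seeded synthetic
metacommunity generator with known ground truth for validating every stage.

## Who this is for

Community ecologists working with site-by-species abundance tables along
environmental gradients — the workflow is written around sandy-beach
macrobenthos (beaches indexed on the reflective-dissipative continuum) but
the machinery (Hellinger/RDA variation partitioning, dbMEM spatial
predictors, NODF / matrix temperature against fixed-fixed nulls) is the
standard beta-diversity toolkit used across metacommunity and microbiome
studies.

## The statistics at the core

* **Beach Index**: `BI = log10(Mz * TR / S)` with `Mz` the mean grain
  diameter (phi + 1), `TR` the spring tide range (m) and `S` the beach-face
  slope ratio; higher = more dissipative. Sites are classified
  reflective / intermediate / dissipative on configurable cut-offs.
* **dbMEM spatial predictors**: great-circle distances truncated at the
  longest minimum-spanning-tree edge (distances beyond it replaced by four
  times the threshold), Gower-centred and eigen-decomposed;
  positive-eigenvalue vectors, broad scale first, each with its Moran's I.
* **Variation partitioning**: adjusted-R² fractions
  `[a]` (environment alone), `[b]` (shared), `[c]` (space alone),
  `[d]` (residual) from partial RDA on Hellinger-transformed abundances,
  `a + b + c + d = 1`; forward selection with the double stopping rule
  (per-step permutation test at α plus the global adjusted-R² ceiling);
  Freedman-Lane permutation tests for the pure fractions.
* **Ordination**: Bray-Curtis on `log(x+1)` abundances, NMDS (Kruskal
  stress-1), and Procrustes/PROTEST concordance of sampling periods to
  justify pooling.
* **Nestedness**: presence matrices ranked by explicit morphodynamic
  gradients (decreasing BI, decreasing grain phi, increasing slope,
  decreasing width), scored with NODF and matrix temperature, and tested
  against the fixed-fixed null model sampled by the curveball algorithm;
  `z = (X - mu) / sigma` with one-tailed empirical p. A minimal
  site set-cover diagnostic flags the sparse, exclusive-species-rich
  matrices that lean anti-nested.

## Worked example

```r
library(nestshore)

# Morphodynamics of the bundled 14-sector survey table
env <- read_env(system.file("extdata", "env_saopaulo.csv", package = "nestshore"))
env$state <- classify_state(env$beach_index)
head(env[order(-env$beach_index), c("site_id", "beach_index", "state")], 4)
#>  site_id beach_index       state
#>     Faz2        2.81 dissipative
#>     Faz1        2.72 dissipative
#>      Pal        2.62 dissipative
#>     Cid1        2.59 dissipative

# A synthetic metacommunity with mixed environmental + spatial control
sim <- simulate_metacommunity(scenario_config("MIXED", seed = 42))
pooled <- pool_periods(sim$fall, sim$spring)
pooled
#> community_matrix: 14 sites x 112 species, period = pooled, total count = 2900

# Variation partitioning: environment vs dbMEM spatial predictors
mem <- dbmem(distance_matrix(sim$sites))
Yh  <- hellinger(pooled)
Xe  <- as.matrix(as.data.frame(sim$env)[, c("beach_index", "mean_diameter_phi",
                                            "slope_ratio", "width_m")])
sel <- forward_select(Yh, mem$vectors, n_perm = 999, seed = 2)
variation_partition(Yh, Xe, mem$vectors[, sel$variable], n_perm = 999, seed = 3)
#> Variation partitioning (adjusted R2 fractions)
#>   Environmental [a]: 0.03   F = 1.098, p = 0.346
#>   Spatial       [c]: 0.31   F = 1.943, p = 0.006
#>   Shared        [b]: 0.06
#>   Residual      [d]: 0.60

# Gradient-ordered nestedness against the fixed-fixed null
rk  <- gradient_rankings(sim$env)$BI_desc
rmx <- ranked_matrix(to_presence(pooled), rk)
nestedness_test(rmx, "NODF", n = 1000, seed = 4)
#> NODF under 'BI_desc' ordering: obs = 46.83, exp = 46.52 (sd 0.319),
#>   z = 0.99, p = 0.170 (nested)
```

Reading the output: the spatial fraction `[c]` dominates and is significant
while the pure environmental fraction `[a]` is not — the simulated spatial
control is recovered. The NODF z-score near zero says the gradient-ordered
matrix is no more nested than expected once row and column totals are held
fixed. `run_gradient_battery()` expands the last step to the full
3 periods x 4 gradients x 2 metrics design (24 rows), and `run_all()`
drives every stage from a config list or YAML file, writing CSV/JSON
artifacts with deterministic per-stage seeds.

## Vignette

`vignettes/nestshore-methods.Rmd` documents the models and their
assumptions, the numerical conventions (tie-breaking, eigenvalue cut-offs,
seed handling), what the synthetic scenarios do and do not emulate, and the
known power asymmetry of fixed-fixed nulls (strong for species replacement,
conservative for subset-chain nestedness).
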