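# riverdna

Catchment-scale analysis of fish biodiversity from eDNA metabarcoding read
tables.

`riverdna` is for ecologists who have already run a metabarcoding
bioinformatics pipeline over water samples from a river network and now hold
per-sample taxon read-count tables. From there it answers the questions a
catchment survey is designed for: how does local richness (α-diversity)
change along the river network, how does community dissimilarity
(β-diversity) grow with river distance, and which groups of sites form
distinct biogeographical units worth protecting as such.

## What it computes

* **Cleaning and merging.** Per-sample low-frequency filtering (counts below
  0.1% of the sample total are zeroed), subtraction of the per-taxon maximum
  read count observed in negative controls, merging of field replicates per
  site, and a cross-primer merge taking the per-site, per-taxon maximum
  count over the two assays — yielding one site × taxon community matrix.
* **α-diversity.** Richness per site; distance decay fitted as a Poisson GLM
  `log E(S_i) = β0 + β1 d_i` with `d_i` the along-channel distance (km) of
  site *i* from the outlet (Wald z on `β1`); exact species accumulation
  curves `E[S(k)] = S_obs − Σ_i C(N−n_i,k)/C(N,k)` with permutation SDs;
  PCA of site environmental variables (correlation matrix).
* **β-diversity.** Pairwise Jaccard dissimilarity with the additive
  partition into turnover `β_jtu = 2min(b,c)/(a+2min(b,c))` and nestedness
  `β_jne = β_jac − β_jtu`, and seeded Mantel permutation tests of each
  component against the river-distance matrix.
* **Biogeographical clustering.** Canberra distance on the count matrix;
  hierarchical (ward.D2), k-means, PAM and DIANA clustering; Hopkins
  clustering-tendency statistic; a validation grid of three internal
  (connectivity, Dunn, silhouette) and four stability (APN, AD, ADM, FOM)
  measures over k = 2…10 with per-measure optima; projection of cluster
  labels onto the network with a spatial-coherence summary.
* **Synthetic surveys.** A seeded generator producing dendritic river
  networks, planted community structure (null / distance-decay / two-zone /
  four-zone scenarios), and realistic two-primer read tables with negative
  controls — so the whole pipeline can be validated against a known truth.

All spatial quantities are along-network distances in km. The methods
vignette (`vignettes/methods.Rmd`) documents every model, default and
numerical choice.

## Worked example

Simulate a two-zone survey, clean it, and run the analyses:

```r
library(riverdna)

cfg    <- scenario_config("two_zone", seed = 7)
ds     <- generate_dataset(cfg)                  # network, truth, 2 read tables
counts <- clean_pipeline(ds$kelly, ds$mifish)    # filter, blanks, merges
pres   <- to_presence_absence(counts)

fit <- fit_richness_glm(local_richness(pres), distance_to_outlet(ds$network))
fit
#> Poisson GLM: log E(richness) = b0 + b1 * distance
#>   b0 = 4.0516 (SE 0.0507)
#>   b1 = -0.000285 per km (SE 0.000083), z = -3.430, p = 0.000603
#>   logLik = -129.20, AIC = 262.40, deviance = 29.46, n = 40
```

Richness falls significantly with distance from the outlet (negative slope,
z = −3.4): downstream sites are richer. Turnover rises with river distance:

```r
bp <- jaccard_partition(pres)
mantel_test(bp$turnover, network_distance_matrix(ds$network), seed = 7)
#> Mantel test (n = 40, 999 permutations, greater)
#>   r = 0.4112, p = 0.001
```

Cluster validation compares four algorithms over k = 2…10 with seven
measures:

```r
vg <- validate_grid(counts, seed = 7)
vg
#> Optimal cluster validation measures
#>   Hopkins clustering tendency: 0.74
#>   Type       Measure       Optimal method Optimal k
#>   internal   connectivity  hierarchical  2
#>   internal   dunn          hierarchical  2
#>   internal   silhouette    hierarchical  2
#>   stability  APN           hierarchical  2
#>   stability  AD            hierarchical  10
#>   stability  ADM           hierarchical  2
#>   stability  FOM           kmeans        10
```

Hopkins ≈ 0.74 says the sites are clusterable (0.5 would be random); five of
seven measures support hierarchical clustering with k = 2 — the planted
number of zones. Cutting the tree and projecting onto the network:

```r
cl <- cluster_sites(counts, "hierarchical", k = 2)
project_clusters(cl$labels, ds$network)
#> cluster projection: 40 sites, 42 adjacent site pairs
#>   same-cluster adjacent pairs: 38 (90%)
adjusted_rand_index(cl$labels, ds$truth$zones)
#> [1] 1
```

The two recovered clusters match the planted zones exactly (ARI = 1) and are
spatially coherent on the network. The same stages run from a YAML config
with `run_pipeline(config, out_dir)`, which writes all tables plus a
`manifest.json` recording every default, checksum and timing.

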