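---
title: "From eDNA read tables to catchment biodiversity patterns: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From eDNA read tables to catchment biodiversity patterns: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverdna)
```

## Scope and data model

`riverdna` analyses fish communities surveyed by eDNA metabarcoding across a
river catchment. It deliberately starts *downstream* of the bioinformatic
pipeline: the inputs are per-sample taxon read-count tables (one per primer
set), sample metadata (site, replicate, bank position, negative-control
flags), a river-network edge list with channel lengths in km, and per-site
environmental measurements. Raw sequence processing, taxonomic assignment and
reference-database curation are out of scope; taxon identifiers are opaque
strings.

Three containers carry the analysis:

* `read_count_table` — samples × taxa non-negative integer counts plus
  metadata; the raw input.
* `community_matrix` — sites × taxa, either read counts or presence/absence;
  produced by the cleaning/merging stage and consumed by every diversity and
  clustering function.
* `river_network` — a weighted (km), usually dendritic graph of sites and
  junctions with one designated outlet; the single source of all spatial
  distances.

## Contamination control and merging

eDNA read tables contain low-level noise from tag jumps, cross-contamination
and reagent contamination. Two standard, deliberately simple filters are
applied, in this order by default:

1. **Per-sample low-frequency filter.** Within each sample, any taxon whose
   count is *strictly below* `fraction` (default 0.001, i.e. 0.1%) of that
   sample's total reads is zeroed. The threshold uses the *pre-filter* total
   and is applied in a single pass — no iteration after totals change. A
   count exactly at the threshold survives.
2. **Negative-control subtraction.** For each taxon, the *maximum* count seen
   in any negative control is subtracted from every field sample, floored at
   zero; control rows are then dropped. The global maximum (rather than
   per-day pairing) is the more stringent reading when no pairing of blanks
   to samples is recorded.

Whether blanks should be subtracted before or after the frequency filter is
genuinely ambiguous; both orders are supported and the default (filter first)
follows the order in which the thresholds are usually reported. The
difference is second-order because the filter acts on proportions and the
subtraction on absolute counts.

Field replicates (six per site: two each at left bank, centre, right bank)
are merged to one row per site either as union presence (a taxon is present
if any replicate saw it — used for α/β diversity) or as the per-taxon maximum
count. The two primer sets are then combined by aligning the taxon universes
(union, implicit zeros) and taking the per-site, per-taxon maximum count.
The maximum, not the sum, is used because the two assays amplify the same
template with different efficiencies — counts are semi-quantitative evidence
for the same fish, not independent observations to be added. This merge is
commutative and idempotent, and converting the max-merged counts to
presence/absence equals the union of the two presence matrices (a tested
invariant).

## Spatial distances

All distances are along-channel shortest paths on the network graph in km
(Dijkstra via igraph), not straight-line distances. On a dendritic (tree)
network the path is unique and satisfies
`d(i,j) = d(i,outlet) + d(j,outlet) − 2·d(lca(i,j), outlet)`; the test suite
checks the shortest-path implementation against exhaustive path enumeration
on small random trees. A user-supplied distance matrix can be substituted
anywhere a matrix is accepted.

## Alpha diversity

* **Richness** is the presence-matrix row sum.
* **Distance decay of richness** is modelled as a Poisson GLM with log link,
  `log E(richness) = β0 + β1·d`, with `d` the distance to the outlet in km.
  Fitting is iteratively reweighted least squares (relative tolerance 1e−8,
  at most 100 iterations, non-convergence is an error); the slope's Wald
  `z = β1/SE` is the test statistic. The suite verifies the fit against an
  independent Newton–Raphson maximiser of the Poisson log-likelihood to six
  decimals.
* **Species accumulation curves** (per river or pooled) use the exact
  sample-based rarefaction formula
  `E[S(k)] = S_obs − Σ_i C(N−n_i, k)/C(N, k)` computed on the log scale;
  the standard deviation always comes from seeded random site orderings
  (default 1000), because the figure of interest shows mean ± SD and exact
  variance formulas add little. The exact mean is tested against brute-force
  enumeration of all orderings on tiny matrices and against an independent
  implementation of sample-based rarefaction.
* **Environmental PCA** operates on the correlation matrix, since river
  width (m), altitude (m), pH, conductivity (µS/cm) and dissolved solids mix
  units. Zero-variance columns are an error naming the column. Component
  signs are made deterministic by forcing each loading vector's
  largest-magnitude entry positive.

## Beta diversity and its spatial signal

Pairwise incidence-based dissimilarity uses the Jaccard family with the
additive turnover/nestedness partition. For a site pair with `a` shared taxa
and `b`, `c` uniques:

* `β_jac = (b+c)/(a+b+c)` — total dissimilarity,
* `β_jtu = 2·min(b,c)/(a+2·min(b,c))` — species replacement (turnover),
* `β_jne = β_jac − β_jtu` — the richness-difference (nestedness-resultant)
  component.

The identity `β_jac = β_jtu + β_jne` is enforced to 1e−12 over a thousand
random community pairs in the tests. A pair of two empty communities is
defined as dissimilarity 0 (with a warning) to avoid 0/0.

The association between a dissimilarity matrix and river distance is tested
with a **Mantel permutation test**: Pearson correlation of the lower
triangles, null built by simultaneously permuting rows and columns of the
second matrix, seeded. The default is one-tailed (`greater`, the ecological
expectation that dissimilarity rises with distance) with 999 permutations,
and the p-value carries the +1 correction
`p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm)`, so p is never reported as 0.
At n = 5 the sampled p is checked against the exact null over all 120
permutations.

## Biogeographical clustering and validation

Clustering operates on the cross-primer maximum-count site × taxon matrix,
untransformed, with the **Canberra distance**
`d(x,y) = Σ_{x_j+y_j>0} |x_j−y_j|/(x_j+y_j)`. Canberra weighs proportional
differences, so rare taxa influence the distance as much as dominant ones —
appropriate for read counts that are at best semi-quantitative. Taxa absent
from both sites contribute zero and are simply excluded; unlike `stats::dist`
the sum is *not* rescaled by the number of contributing terms. This
no-rescaling dialect keeps the leave-one-column-out arithmetic of the
stability measures exact, and is verified against a naive double-loop
implementation.

Four algorithms are compared behind one interface (`cluster_sites()`):

* hierarchical agglomeration with the ward.D2 Lance–Williams update
  (`stats::hclust`), verified against a naive O(n³) re-scan agglomeration;
* k-means (Lloyd, best of 25 seeded starts on the raw count rows);
* PAM (k-medoids) on the distance matrix. BUILD + SWAP is a local search and
  can stick even on small instances, so the package additionally restarts
  SWAP from five seeded random medoid sets and keeps the best objective;
  with that refinement the objective matches exhaustive medoid search on all
  tested instances with n ≤ 8;
* DIANA (Macnaughton-Smith divisive analysis) on the distance matrix.

**Clustering tendency** is screened with the Hopkins statistic
(`m = max(2, ⌊0.1·n⌋)` sampled rows versus m uniform pseudo-points in the
per-column bounding box, Euclidean nearest-neighbour distances): ≈ 0.5 for
spatial randomness, → 1 for clustered data.

**Validation** scores every (method, k) pair, k from 2–10 by default, with
three internal measures — connectivity (neighbourhood L = 10), Dunn index,
mean silhouette width — and four stability measures under leave-one-taxon-out
reclustering: average proportion of non-overlap (APN), average distance (AD),
average distance between means (ADM) and figure of merit (FOM). Stability
reclustering reuses the full run's method, k and seed so the deleted column
is the only perturbation; hierarchies are rebuilt once per deleted column and
cut at every k. All seven measures are tested against independent reference
implementations. Each measure's optimum (minimum or maximum as appropriate)
is reported with ties broken toward the smallest k, then the method order as
supplied — determinism everywhere.

Cluster labels are projected back onto the network; the spatial-coherence
summary counts, per cluster, the network-adjacent site pairs (no third site
on the channel path between them) sharing a label.

## The synthetic-data generator

The generator exists so that every stage can be exercised end-to-end with a
known truth. It emulates the design of a single-campaign catchment survey:

* a dendritic network: a mainstem plus tributaries joining at junction
  nodes, 4 rivers × 10 sites by default (close to a typical 39-site
  campaign), lognormal inter-site channel lengths (median 55 km, giving
  a realistically irregular spacing of roughly 30–110 km);
* a pool of 250 detectable taxa. Each widespread taxon has a Gaussian
  occupancy kernel along the distance-to-outlet axis (breadth 250 km) and a
  downstream-increasing exponential gradient (0.0015 per km), producing
  local richness of roughly 15–50 and a negative richness–distance GLM
  slope; zone-private taxa (a fraction `zone_effect`, default 0.6, of the
  pool in the zoned scenarios) occur only within their zone's rivers at
  occupancy 0.45, planting discrete biogeographic clusters;
* per replicate, a lognormal read depth (median 25,000) distributed
  multinomially over the taxa present, with per-site lognormal relative
  abundances shared across replicates and primer-specific per-taxon
  amplification efficiencies on top; a disjoint fraction of taxa is missing
  from each primer's reference (6% / 3%), giving primer-exclusive
  detections; every sample, field or blank, receives sparse Poisson
  contamination (~2 taxa, ~10 reads each);
* scenario presets: `null` (no spatial structure at all — used to check
  Mantel type-I error and Hopkins calibration), `distance_decay`
  (Gaussian kernels with 150 km breadth and a *flat* richness trend, so
  the spatial signal is pure species replacement: with a richness gradient
  included, the nestedness component tracks distance too, which is not what
  this scenario is for), and `two_zone`/`four_zone` (kernels + gradient +
  zone-private taxa).

All randomness flows from one mandatory seed through fixed per-stage
substreams, so every object is reproducible independently of evaluation
order.

What the generator does *not* emulate: sequence-level artefacts (chimeras,
index hopping, misassignment), overdispersion beyond the
lognormal–multinomial hierarchy, eDNA transport between sites, imperfect
per-replicate capture beyond multinomial sampling, and seasonal turnover.
Passing recovery tests therefore demonstrates that the pipeline's inference
machinery is correct under its own assumptions — not that those assumptions
exhaust real eDNA data.

## Numerical choices and degenerate inputs

* Cleaning thresholds compare with *strict* inequality; exact-threshold
  counts survive.
* GLM: IRLS tolerance 1e−8, 100 iterations, error on non-convergence.
* Mantel: +1-corrected p, seeded permutations; constant lower triangles are
  an error (undefined correlation).
* Silhouette of a singleton cluster member is 0; internal measures on a
  single cluster are an error; Dunn is `Inf` when every cluster is a
  singleton.
* Stability measures skip (with a warning) any column whose deletion makes
  clustering fail, and average over the rest.
* Hopkins errors on fully degenerate (all-identical-row) input.
* Canberra zero–zero terms contribute 0 with no rescaling (see above).
* PAM multi-start and k-means multi-start are seeded and deterministic;
  tie-breaks in the validation optimum go to the smallest k, then method
  order.
* Empty-vs-empty community pairs: dissimilarity 0, warned.

## Problem sizes in the tests

The suite runs everything at desk scale, chosen so the whole test run
completes in a couple of minutes: oracle equivalences on n ≤ 20 instances
(exhaustive enumerations at n ≤ 8), invariants over hundreds of random
draws, 10-seed recovery checks on full 40-site surveys, one full 4-method ×
k 2–10 validation grid, and a 200-replicate Mantel type-I calibration. The
same quantities, recomputed from scratch at the same sizes, are what
`scripts/acceptance.R` reports.

## Known limitations

* The 0.1% filter and max-subtraction are blunt instruments; occupancy
  models of per-replicate detection would use the replicate structure more
  efficiently, and are out of scope here.
* Read counts are treated as semi-quantitative throughout; no abundance
  calibration is attempted.
* Taxa are opaque labels: no phylogenetic or functional weighting.
* The distance-decay significance properties hold at the default effect
  sizes with high but not unit probability over random surveys (the
  irregular network geometry occasionally yields weak spatial contrast), so
  seed-level results for single surveys should be read as draws, not
  constants.
* SOTA (self-organising tree) clustering is not implemented; the method
  registry covers the four algorithms above.
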