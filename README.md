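# kinetnet

Network-based integration and interpretation of longitudinal multi-omics
data.

Longitudinal multi-omics experiments measure several molecular layers
(mRNA, proteins, metabolites, microbial taxa, clinical variables) on the
same subjects over time. Correlating layers pairwise rarely yields
interpretable biology: real regulatory mechanisms run *across* layers, and
much of what connects them (protein–protein binding, enzymatic reactions,
TF–target regulation) cannot be inferred from abundances alone. `kinetnet`
builds **hybrid multi-layer networks** that combine data-driven inference
with curated knowledge, labels molecules by their kinetic behaviour, and
interprets the result with network propagation. It is aimed at systems
biologists who have per-omics time-course abundance tables and want
mechanism-level hypotheses rather than correlation lists.

## The method

1. **Profile modelling.** Each molecule's time course is fit with a small
   model hierarchy — constant mean, straight line, cubic smoothing spline
   of the group mean, spline plus shrunken per-subject intercepts — and
   the winner is chosen by BIC. Trendless ("noisy") profiles are removed:
   constant winners, fits with R² below a floor, and fits whose
   improvement over the constant mean fails an F test. A fold-change
   filter (max/min of the per-time means over the course) runs first.
2. **Kinetic clustering.** Standardized fitted profiles from all blocks
   are clustered with multi-block projection to latent structures: `ncomp`
   consensus components are extracted by alternating least squares with
   deflation, and each feature is assigned to (component of its largest
   absolute loading, loading sign), giving up to `2*ncomp` shape clusters.
   The number of components is selected by maximizing the average
   silhouette under correlation distance `d(i,j) = 1 − cor(x_i, x_j)`.
   Sparse per-cluster signatures come from loading thresholding (`keepX`).
3. **Network assembly.** Per layer: mutual-information co-expression
   inference (equal-frequency binning) pruned by the data-processing
   inequality — edge (i,j) is dropped whenever a third node k satisfies
   `MI(i,j) < (1−ε)·min(MI(i,k), MI(j,k))`; curated interaction tables
   with optional confidence filtering and first-degree extension to
   unmeasured interactors; reaction tables linking compounds sharing a
   reaction and their enzymes; log-ratio (SparCC-style) correlation for
   compositional counts; Spearman cross-links at |ρ| ≥ 0.99. Networks are
   built for the entire feature set and rebuilt per kinetic cluster.
4. **Term layers.** Over-representation analysis (upper-tail
   hypergeometric test, Benjamini–Hochberg per ontology, α = 0.05) adds GO
   / disease term nodes connected to their member molecules; Fisher's
   combined probability test (`−2Σlog p ~ χ²(2k)`) compares p-values
   across omics.
5. **Propagation.** On the merged undirected graph G = (V, E), a random
   walk moves from node x to neighbour y with probability `1/d(x)` and
   restarts at the seed distribution with probability `r` (default 0.7):
   `p ← (1−r)·W·p + r·p0`, the fixed point of `(I − (1−r)W)p = r·p0`.
   Steady-state scores rank every node by proximity to the seed. Three
   interpretation modes: *mechanism sub-networks* (top-25 nodes around
   each significant term, screened for multi-omics reach), *function
   prediction* (nearest term node per ontology for unannotated
   molecules), and the *cluster-intersection screen* (top-10 sub-networks
   around measured seeds, retained when they mix kinetic clusters and
   touch a term node — the signature of a cross-programme regulator).

A deterministic synthetic-data generator (`gen_blocks`, `gen_knowledge`,
`gen_annotations`, `gen_compositional`, `gen_regulatory`) produces every
input with stored ground truth, so the whole chain is testable end to end.

## Worked example

```r
library(kinetnet)
res <- run_pipeline(default_config(seed = 1), outdir = "run1")

res$cluster$candidates
#>   ncomp k silhouette
#> 1     1 2  0.5885011
#> 2     2 4  0.9970301
#> 3     3 6  0.6314336

print(res$annotate$network)
#> <mon> assembled: 83 nodes, 211 edges
#>   layers: gene=20 go_term=4 metabolite=14 protein=45
```

The silhouette table shows why four kinetic clusters were chosen: two
latent components (four sign clusters) give an average silhouette of
0.997, far above the two- and six-cluster alternatives, matching the four
planted kinetic programmes of the default fixture. The assembled network
holds the 60 measured molecules plus first-degree knowledge interactors
(unmeasured proteins and reaction compounds) and the four significantly
enriched term nodes. The cluster-intersection screen then flags seeds
whose neighbourhood mixes kinetic clusters:

```r
scr <- res$propagate$intersection
head(scr[scr$retained, c("seed", "seed_cluster", "other_clusters", "n_terms")], 3)
#>           seed seed_cluster other_clusters n_terms
#> 1 met:met_f002            1            2;3       2
#> 2 met:met_f006            1              2       2
#> 3 met:met_f009            2            3;4       1
```

Each retained seed reaches molecules of other kinetic clusters *and* at
least one annotation term within its top-10 propagation neighbourhood —
candidates for regulation across expression programmes. All artifacts
(GraphML networks, enrichment and propagation TSVs, JSON provenance per
stage) land in `run1/`; rerunning with the same config and seed reproduces
them byte for byte, and changing one stage's settings re-executes from
that stage onward only.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/kinetnet.R simulate --outdir sim --seed 1
Rscript inst/cli/kinetnet.R run --outdir out --seed 1 [--until cluster]
```

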