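---
title: "Models and design choices in kinetnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in kinetnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetnet)
```

`kinetnet` turns longitudinal multi-omics abundance tables into annotated
multi-layer networks and interprets them by propagation. This vignette
explains the statistical machinery stage by stage, states every tunable
parameter with its default and rationale, describes what the synthetic
generator does and does not emulate, and records the design decisions
taken where the methodology was genuinely open.

## Data model

An `omics_block` is one layer's samples-by-features matrix with per-sample
metadata (`subject`, `replicate`, `time`) and a declared scale (`linear`
or `log`, with the log base). Blocks need not share timepoints: the
modelling stage interpolates every feature onto a common grid.

A `mon` network is a typed undirected multi-layer graph. Nodes carry a
layer (`gene`, `tf`, `protein`, `metabolite`, `otu`, `clinical`,
`go_term`, `disease`), a `measured` flag, and an optional kinetic-cluster
label; edges carry a provenance (`inferred_mi`, `knowledge_ppi`,
`knowledge_reaction`, `coding`, `tf_target`, `correlation`, `annotation`)
and a non-negative weight. Two conventions matter:

* **Edges are undirected**, because the propagation model is a symmetric
  degree walk. The regulatory direction of a TF–target row is kept as the
  `source_role` edge attribute, not as an arrow.
* **The id namespace is flat.** The assembler prefixes feature ids by
  layer (`rna:`, `prot:`, `met:`, `otu:`, `clin:`, `go:`, `dis:`) so the
  same symbol measured as transcript and protein cannot collide.
* Parallel edges of different provenance between the same pair are kept as
  distinct records; the transition matrix collapses them (maximum weight)
  before any walk.

## Pre-processing and profile modelling

The fold-change filter keeps a molecule when the swing of its per-time
means over the course reaches a threshold: `max/min >= t` on a linear
scale, `max − min >= log_base(t)` on a log scale. Thresholds are
per-block (`default_config()` uses 2 for the transcript-like block and 3
elsewhere, reflecting platform dynamic ranges). Non-positive linear
minima are offset by a pseudocount — half the smallest positive value in
the block — and the pseudocount is recorded in the report.

Each surviving feature is fit with four nested candidates:

| model | form | parameters counted |
|---|---|---|
| `constant` | mean | 1 |
| `linear` | a + b·t | 2 |
| `spline_mean` | cubic smoothing spline (GCV) of the group mean | effective df |
| `spline_subject` | spline + shrunken per-subject intercepts | df + Σ shrinkage |

Selection is by BIC (`n·log(RSS/n) + k·log n`), with near-ties resolved
toward the simpler model, so noiseless constant and linear profiles are
recovered exactly. With 5 or fewer distinct timepoints the smoothing
spline is unreliable and a natural interpolating spline through the
per-time means is used instead; with fewer than 4 the spline candidates
are excluded entirely and a warning is recorded. Subject effects are
random intercepts estimated by shrinking per-subject mean residuals
toward zero by the usual variance-ratio factor; full random-spline
subject curves are deliberately out of scope, so between-subject shape
differences are treated as noise. The grid must lie inside the observed
time range — the fitted splines are not trusted to extrapolate.

The **noise filter** removes profiles with no usable time structure. A
profile is noisy when (i) the constant model wins, (ii) the winning
model's R² against the observations is below 0.1, or (iii) the winning
model's improvement over the constant mean is not significant by F test
at `gof_alpha = 0.01`. The third screen exists because BIC at small n
(15 observations in the default design) selects a non-constant model for
roughly a third of pure-noise profiles, many with R² above any sensible
floor; a conservative goodness-of-fit test brings the false-keep rate of
trendless profiles below 10% while leaving genuine kinetic profiles —
whose F statistics are enormous at the default noise level — untouched.
All three knobs are arguments.

## Kinetic clustering

Standardized profiles (rows centered and scaled — clustering is by shape,
not magnitude) from all blocks enter a consensus-score multi-block PLS:
for each component, alternating least squares finds unit block weights
and a unit consensus score over the grid maximizing summed block
covariance, blocks are deflated on the consensus score, and the next
component repeats. Initialization is the leading singular vector of the
concatenated blocks with a fixed sign convention, so results are
deterministic; the ALS tolerance is 1e-9 (L1 on the unit-norm score) with
a 5000-iteration cap because convergence is geometric but can be slow
when eigenvalues are close.

Each feature is assigned to the component carrying its largest absolute
loading, split by loading sign — up to `2·ncomp` clusters, naturally
pairing "up" and "down" versions of the same latent kinetic programme.
`choose_k()` scans a grid of component counts and keeps the clustering
with the highest average silhouette under correlation distance, breaking
ties toward fewer clusters. Exact numerical agreement with other
multi-block PLS implementations is not promised; cluster-label agreement
on fixtures is the contract. The alternative `pattern_cluster()` labels
profiles by the sign pattern of consecutive fitted differences, with a
zero band of 1% of each profile's range so the labelling is invariant
under positive affine transforms.

`sparse_signature()` keeps the `keepX` largest-absolute loadings per
block and component (soft-thresholding the rest to zero) and recomputes
assignments, yielding a small signature per cluster.

## Network construction

**Mutual information + DPI.** Features are discretized into
equal-frequency bins; MI is computed from the joint table in bits.
The default bin count is `floor(n^(1/3))`, clamped to [3, 10]: with
square-root scaling the expected occupancy of each joint cell does not
grow with n, and the resulting small-sample MI bias is large relative to
the MI *differences* that the data-processing-inequality step compares,
which destroys triangle pruning; cube-root scaling keeps the bias in
check at the sample sizes this package targets. The edge floor defaults
to the 95th percentile of a 20-permutation null (each feature permuted
independently, seeded). DPI pruning then removes, simultaneously, every
edge (i,j) for which some triangle partner k gives
`MI(i,j) < (1−ε)·min(MI(i,k), MI(j,k))`, with tolerance ε = 0.15
(common practice for this algorithm family; ε = 0 removes each
triangle's strictly weakest edge).

**Knowledge layers.** Interaction tables are optionally filtered by a
confidence score, then restricted to rows touching measured molecules;
with `extend = TRUE` the direct interactors of measured molecules enter
as unmeasured nodes. By construction no unmeasured node is ever more
than one hop from a measured one. Reaction tables produce compound
cliques per reaction plus enzyme–compound edges, again including
unmeasured compounds only at first degree. Cross-link tables add
`coding` and `tf_target` edges.

**Compositional counts.** For OTU-like tables, Pearson correlation of
relative abundances is spurious; the log-ratio variance estimator is used
instead: with `t_ij = var(log(x_i/x_j))` and assuming sparse true
correlations, basis variances solve `T_i = (D−2)·ω_i² + Σ_j ω_j²` and
`ρ_ij = (ω_i² + ω_j² − t_ij)/(2ω_iω_j)`, clipped to [−1, 1]. This is the
single-pass basis estimate without iterative exclusion of strongly
correlated pairs — adequate at the planted-correlation densities the
package targets, and noted as a simplification. At least 4 taxa are
required or the variance system is underdetermined. Cross-layer links
for unannotated layers use Spearman correlation on the modelled profiles
with a deliberately stringent default `|ρ| ≥ 0.99`, appropriate because
modelled profiles on a short common grid make high rank correlations
easy to reach by chance at looser cutoffs.

**Assembly.** The entire network is the merge of all layers and
cross-links, with measured nodes stamped by kinetic cluster. Per-cluster
networks are *rebuilt from scratch* on each cluster's measured features —
inference re-run, knowledge extension re-applied — rather than sliced out
of the entire network: rebuilding yields better-connected cluster
networks, and shared knowledge nodes legitimately appear in several
clusters.

## Enrichment and term layers

`ora()` computes the upper-tail hypergeometric probability of the
observed query–term overlap given the universe, adjusts per
ontology/source by Benjamini–Hochberg and flags significance at
α = 0.05. The universe defaults to the measured features and can be
widened to include extended knowledge nodes; the choice is recorded in
the result. BH is a standard, well-defined correction; the significance
cutoff 0.05 is retained from common practice. Significant terms become
term-layer nodes wired to their member molecules present in the network.
`fisher_combine()` implements `X² = −2Σ log p ~ χ²(2k)` for cross-omics
p-value comparison; zero p-values are rejected rather than silently
clamped.

## Propagation

The transition matrix is the degree walk of the collapsed graph: column
x gives `1/d(x)` to each neighbour; isolated nodes self-loop so every
column is stochastic. A weighted variant (per-column weight
normalization) exists but the default walk is unweighted — the degree
walk is the model the rest of the package is built around, and edge
weights of heterogeneous provenance (MI values vs curation scores) are
not commensurable. The restart probability defaults to r = 0.7, the
convention of the restart-walk literature on molecular networks; the
iteration `p ← (1−r)Wp + r·p0` stops when the L1 change drops below
1e-10 (equivalently, it solves `(I −(1−r)W)p = r·p0`). Ranking ties
break lexicographically by node id so outputs are deterministic. Seed
annotation edges are *not* masked during function prediction — a seed's
own annotation edge cannot exist for genuinely unannotated nodes, which
are the only default seeds — and the merged graph is deliberately
monoplex: multiplex inter-layer jump tuning is out of scope.

The three interpretation modes are thin screens over `rwr()`:
`mechanism_subnetworks()` (top-25 per term seed, multi-omics reach
flags), `predict_function()` (nearest term node per ontology),
`cluster_intersection()` (top-10 per measured seed, retained when the
sub-network holds a different cluster label and a term node).

## The synthetic generator

`gen_blocks()` emulates a replicated three-block time-course on a log2
scale: mutually orthogonal archetype curves over the grid, features
assigned a (cluster, sign) pair, per-subject random intercepts
(sd 0.3), i.i.d. Gaussian noise (sd 0.2), baselines uniform in [6, 10]
log2 units, archetype amplitude 2 (a 4-fold swing). The default design —
3 blocks, 5 timepoints, 3 subjects, 20 signal + 5 trendless features per
block — mirrors a compact cell-line multi-omics study while keeping test
runtimes in seconds. Two generator properties are deliberate:

* **Cluster sizes are skewed** (proportional to `n_clusters:1`). With
  perfectly balanced archetypes, the leading latent direction of
  row-standardized profiles is rotationally degenerate — any rotation of
  two equally loaded archetypes is an eigenvector — making component-wise
  assignment unidentifiable in principle, not just in practice. Real
  kinetic clusterings are strongly skewed, so the generator plants
  skewed sizes.
* **Archetype amplitudes are staggered** (factor 0.75 per archetype), so
  programmes differ in raw effect size as they do in real data.

`gen_knowledge()`, `gen_annotations()`, `gen_compositional()` and
`gen_regulatory()` plant, respectively: scored interaction tables whose
unmeasured ids always touch a measured molecule; one strongly enriched
term per cluster (members drawn only from that cluster) among uniform
background terms; log-normal basis abundances with chosen pairwise
correlations, multinomially sampled at fixed depth; and a random
regulatory tree whose signal attenuates along edges so direct pairs
dominate indirect ones. All randomness flows from one integer seed
through a counter-based splitting scheme, so generators are independently
reproducible and calling one does not perturb another.

What the generator does **not** emulate: heavy-tailed abundance
distributions, missing values, batch effects, uneven or missing
timepoints, count overdispersion, correlated noise between features, or
database errors. Passing tests therefore demonstrate that the algorithms
recover planted structure under clean, correctly specified conditions —
not that they are robust to the full messiness of real studies.

## Pipeline and determinism

`run_pipeline()` executes simulate → filter → model → cluster → build →
annotate → propagate from one declarative configuration. Every stage
writes plain-text artifacts plus a JSON provenance record (stage
parameters, config hash, package version) and is cached under a hash of
its own parameters and everything upstream: rerunning with an unchanged
configuration reuses results, changing one stage's settings re-executes
from that stage onward, and a rerun with the same configuration and seed
reproduces all numeric outputs byte for byte (numeric columns are
written with fixed formatting). Default problem sizes (12–20 features
per block, 5 timepoints, 3 subjects; 200 samples and 50 nodes for the
inference recovery studies; 500 samples for compositional calibration)
were chosen so the full suite and the acceptance script run in seconds
to a few minutes on a single CPU.

## Known limitations

* The modelling hierarchy is an approximation of full mixed-model spline
  frameworks: subject effects are intercept-only, and the spline with ≤5
  timepoints interpolates rather than smooths.
* The MI estimator is binned, not kernel- or k-NN-based; its absolute
  values are estimator-specific even though pruning decisions are
  calibrated.
* The compositional correlation estimator is single-pass; strong dense
  correlation structure would bias the basis variances.
* Propagation treats all provenances identically on a monoplex graph;
  edge-confidence weighting is available but off by default for the
  commensurability reason above.
* ORA treats terms as flat sets — no ontology DAG traversal or
  redundancy reduction — and the disease layer is consumed as generic
  term sets.
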