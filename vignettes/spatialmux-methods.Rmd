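---
title: "Spatially aware multiplex Leiden clustering: models and methods"
author: "spatialmux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially aware multiplex Leiden clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialmux)
```

## The problem

Spatial transcriptomics assigns expression profiles to physical
locations — spots on a capture grid (Visium, binned Stereo-seq) or
segmented cells (MERFISH, osmFISH, STARmap, BaristaSeq). A central
analysis step is *spatial domain detection*: partitioning the section
into regions, such as cortical layers, that are coherent both in
expression and in space. Ordinary single-cell clustering connects
spots only by expression similarity and is blind to the tissue
geometry; purely spatial smoothing, conversely, cannot separate
interleaved cell populations. `spatialmux` couples the two sources of
evidence in a single objective.

## The multiplex quality function

Every spot is a node shared by several graph *layers*. For layer $l$
with adjacency $A^{(l)}$, weighted degrees $k_i^{(l)}$ and total weight
$2m_l$, the quality of a partition $c$ is the resolution-parameterized
(Reichardt–Bornholdt) configuration modularity over ordered pairs,

$$Q_l(\gamma_l) \;=\; \sum_{ij}\Bigl(A^{(l)}_{ij} -
\gamma_l\,\frac{k_i^{(l)} k_j^{(l)}}{2m_l}\Bigr)\,\delta(c_i, c_j),$$

and the optimizer maximizes $Q = \sum_l w_l\, Q_l(\gamma_l)$. Two
conventions matter and are deliberate:

* **Per-layer quality is unnormalized** (edge-weight units, no division
  by $2m_l$). Layer weights therefore trade off *raw* quality sums,
  which mirrors how reference multiplex optimizers combine layers. The
  flip side is that a layer with more total edge weight has
  proportionally more influence at equal $w_l$; see *Choosing the
  spatial weight* below.
* $\gamma_l = 1$ recovers unnormalized Newman–Girvan modularity; larger
  resolutions strengthen the null term and yield more, smaller
  clusters.

## The optimizer

`leiden_multiplex()` implements the Leiden scheme over all layers
simultaneously (C++ core):

1. **Local moving.** Nodes are visited in a seeded random order
   (Fisher–Yates; own RNG, so results are independent of R's RNG state)
   from a queue; each node moves to the community — pooled over the
   neighborhoods of all nonzero-weight layers, plus one empty
   community — that maximizes $\Delta Q$, computed incrementally from
   per-community degree sums. Nodes whose neighborhood changed are
   re-queued. Ties keep the current community; among equal new
   communities the lowest id wins, so runs are reproducible.
   On problems of at most 64 nodes all non-empty communities are
   candidates, making each move's search exhaustive at negligible cost.
2. **Refinement.** Within each community, nodes restart as singletons
   and may merge into adjacent refined clusters of the same community,
   but only for strictly positive gain. This guarantees every final
   cluster is connected in the union of the nonzero-weight layers.
3. **Aggregation.** Refined clusters collapse to super-nodes in *every*
   layer at once (edge weights summed, self-loops kept — their weight
   re-enters the within-community adjacency at the next level), and the
   aggregate partition is seeded with the pre-refinement communities.

Passes repeat until a pass yields no quality increase; the quality
trace is asserted non-decreasing on every run. Because greedy Leiden
can land in local optima on small, dense problems — we verified that
the widely used reference implementation returns the identical
suboptimal partition on such instances — `leiden_multiplex()` runs a
deterministic multi-start (8 seeds derived from the user seed, best
quality wins) on problems of at most 256 nodes, where restarts are
essentially free. Large problems use a single pass sequence, matching
standard practice.

## Graph layers

**Spatial layer.** For lattice technologies, spots are connected to
their equidistant lattice neighbors (6 on a hexagonal grid, 4 on a
square grid) with unit weights — neighbors on a grid are equidistant,
so no distance weighting is needed and any constant factor would be
absorbed by the layer weight. The lattice spacing is estimated as the
minimum pairwise distance; pairs within a relative tolerance of `1e-3`
of it become edges, and inputs where this fails (excess degree, or more
than 10% isolated spots) raise a geometry error rather than returning a
silently broken graph. For irregular designs, `build_delaunay_graph()`
(Bowyer–Watson incremental triangulation, implemented in the package)
or `build_knn_graph()` (exact brute-force kNN, union-symmetrized;
default $k = 10$) provide the adjacency, and
`distances_to_connectivities()` converts edge distances $d$ to weights
$1 - d/d_{\max}$ with $d_{\max}$ the global maximum edge distance of
that graph. Edges that reach weight exactly 0 are dropped: a zero-weight
edge is a non-edge for modularity. The transform is scale invariant, and
degenerate graphs (all distances equal) raise an error directing the
caller to unit weights.

**Latent layer.** Expression is reduced to `n_comp = 30` dimensions
(below), the 15 nearest neighbors per spot are union-symmetrized, and
edges are weighted by a local-scaling Gaussian kernel
$\exp(-d^2/\sigma_i\sigma_j)$ with $\sigma_i$ the distance of $i$ to
its $k$-th neighbor. The kernel adapts to local density, gives weights
in $(0,1]$, and is fully specified by the data; a `binary` kernel is
available for unweighted neighborhoods. Coincident points get weight 1
(the $d \to 0$ limit).

## Feature selection and dimensionality reduction

`select_hvgs()` ranks genes by the variance of clipped standardized
counts: a loess curve (span 0.3, degree 2) of $\log_{10}$ variance on
$\log_{10}$ mean provides an expected standard deviation per gene,
counts are standardized by it and clipped at $\sqrt{n}$, and the
variance of the clipped values is the score. `select_svgs()` ranks by
Moran's I on the spatial graph,

$$I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},$$

with row-normalized weights by default (the common autocorrelation
convention; `row_normalize = FALSE` uses raw connectivities). Moran's I
is computed on log-normalized values — the data scale on which distances
and PCA operate — and is affine invariant, so the choice of
normalization target does not affect ranks. Zero-variance genes score
$-\infty$ and are never selected; rank ties break lexicographically by
gene id for reproducibility. The default of 3000 selected genes follows
common capture-based practice.

`multispati()` fits either a standard PCA (eigendecomposition of
$X_c^\top X_c/n$) or its spatially weighted extension: with $W$ the
row-normalized spatial weight matrix, it solves the symmetric
eigenproblem of

$$H = \frac{X_c^\top (W + W^\top) X_c}{2n}.$$

Each eigenvalue factors exactly as
$\lambda_j = \mathrm{var}(s_j)\cdot I(s_j)$ — score variance times score
Moran's I — which `eigenvalue_table()` verifies per component and the
test suite checks against dense eigensolvers. Design choices: genes are
centered but not scaled by default (PCA-like; `scale. = TRUE`
available); only the largest (positive) eigenvalues are kept by default
since negatively autocorrelated components encode checkerboard-like
patterns rarely wanted for domain detection (`n_neg` exposes them);
component signs are canonicalized so the largest-magnitude loading is
positive. $H$ is assembled with implicit centering
($X^\top S X - \mu r^\top - r\mu^\top + (\mathbf{1}^\top S\mathbf{1})\,
\mu\mu^\top$), so sparse count matrices are never densified and memory
stays $O(p^2)$ with $p$ the number of selected genes (at most the 3000
default) regardless of the number of spots; a dense symmetric
eigensolver on $H$ is then exact and fast at any realistic $p$.

## Two-stage resolution search

`search_resolution()` walks the resolution with a fixed step (default
0.1 from 1.0), halving the step at every direction flip, until the
clustering has exactly the target number of clusters (at most 40
evaluations; the closest count is returned with a warning otherwise).
One fixed seed is used for every evaluation in a search.
`spatialleiden()` applies it twice: stage one tunes the latent layer
alone (this *is* non-spatial Leiden); stage two freezes that resolution
and the layer weights $(1, w_\text{spatial})$ and tunes the spatial
layer's resolution, starting from the stage-one value. The stage-one
resolution is not re-tuned afterwards: freezing it keeps the two stages
interpretable and the baseline nested inside the spatial fit
(`spatial_weight = 0` reproduces stage one exactly).

### Choosing the spatial weight

Because per-layer quality is unnormalized, the meaningful scale of
$w_\text{spatial}$ depends on the total edge weight of both layers. The
local-Gaussian latent layer of a typical section carries roughly twice
the total weight of a unit-weight grid layer, so $w = 1$ lets
expression dominate and spatial context acts only as a tie-breaker.
`spatial_weight = "match"` sets the weight to the ratio of total edge
weights between the layers, putting both on the same quality scale; it
is the default for `recovery_experiment()` and a sensible starting
point in practice. `sweep_weight()` exposes the full sensitivity curve,
which is the honest way to choose a weight for a new technology.

## The synthetic tissue generator

`tissue_spec()`/`simulate_tissue()` emulate a layered cortical section
at desk scale. Defaults, chosen once as a realistic capture-based
regime: 2000 spots on a square grid cut into $K = 4$ horizontal bands
of near-equal size (a `voronoi` mode gives irregular patches); 500
genes with log-normal baseline means, 25 markers per domain
up-regulated by a natural-log fold change of 1.0; negative-binomial
counts with dispersion (size) 2 and an expected library size of 2000
counts per spot — overdispersion and depth typical of grid platforms
(`dispersion = Inf` gives the Poisson limit). The key difficulty knob
is `noise_mixing`: with probability 0.3 (default) a spot's counts are
drawn from a uniformly random *other* domain's profile. Whole-profile
swapping, rather than added white noise, mimics the ambiguous mixed
spots at domain borders — exactly the regime where spatial context
carries information that expression cannot.

What the generator does *not* emulate: platform-specific artifacts
(spot swapping, segmentation errors, spatially varying capture
efficiency), histology, continuous gradients within domains, or batch
structure. Passing the recovery tests therefore demonstrates that the
pipeline exploits spatial structure when expression is ambiguous — not
that it is robust to every artifact of real sections.

With the defaults, the simulated domains are strongly separated in
latent space: the latent kNN graph of a $K$-domain tissue has exactly
$K$ connected components, so non-spatial Leiden yields $K$ clusters
over a wide resolution range and cluster counts below $K$ are
structurally unreachable (merging disconnected communities always
decreases the quality for $\gamma > 0$). The resolution-search
validation therefore targets the true domain count on tissues with
$K \in \{3, 4, 6\}$, matching how the search is used in practice —
tuning to a known number of domains.

## Evaluation

`adjusted_rand_index()` and `normalized_mutual_information()` are
computed from the contingency table; NMI uses the arithmetic-mean
normalization by default (geometric/min/max available), defines two
single-cluster partitions as agreement 1 and a one-sided single cluster
as 0. Spots absent from either labeling are excluded with a message.
`wilcoxon_signed_rank()` drops zero differences, midranks ties, and is
exact for up to 25 retained pairs via the full null distribution of the
positive-rank sum (computed by convolution over doubled midranks, so
exactness survives ties); beyond that a normal approximation with tie
and continuity corrections takes over. `benjamini_hochberg()` applies
the standard step-up adjustment. `compare_methods()` pairs per-sample
metric values and corrects across all comparisons in the call.

## Problem sizes and numerical choices

The validation suite and `scripts/acceptance.R` use problem sizes
chosen to make each property sharp yet quick on one CPU: exhaustive
enumeration on up to 8 nodes (4140 partitions), dense eigensolver
cross-checks at up to 300 spots × 100 genes, metric oracles at up to
1000 spots, recovery studies at the generator's native 2000 spots over
10 simulation seeds, and resolution-search studies at 1000 spots.
Quality improvements below $10^{-12}$ (relative) are treated as noise;
the in-run monotonicity assertion allows $10^{-9}$; eigen agreement is
required to $10^{-8}$ and the variance × Moran identity to $10^{-6}$
relative. Degenerate inputs fail loudly and early: empty graphs,
constant values for Moran's I, all-zero Wilcoxon differences,
non-lattice coordinates for grid builders, and double normalization are
all errors, not warnings.

## Known limitations

* The grid builder assumes a single, approximately uniform lattice;
  multi-resolution or heavily distorted grids are rejected.
* Delaunay construction is $O(n^2)$; beyond ~10⁴ cells the kNN spatial
  graph is the practical choice.
* The two-stage search inherits the step search's assumption that the
  cluster count is monotone-ish in resolution; strongly non-monotone
  landscapes can end at the closest, not exact, count (reported via a
  warning and the `converged` flag).
* Multi-start is capped at small problem sizes; large-graph runs are
  single-start and can, like any greedy Leiden, return a local optimum.
* No spatially contiguous-cluster constraint is offered by design:
  domains may legitimately recur in disconnected regions (e.g.,
  bilateral structures), which hard contiguity would forbid.
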