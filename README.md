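# spatialmux

Spatially aware multiplex Leiden clustering for spatially resolved omics.

Clustering of spatial transcriptomics data (Visium, Stereo-seq, MERFISH,
osmFISH, STARmap, BaristaSeq, ...) usually ignores where the cells and
spots sit in the tissue: spots are connected by similarity in a
gene-expression latent space and partitioned with the Leiden algorithm.
`spatialmux` makes this workflow spatially aware at three points:

1. **feature selection** — rank genes by Moran's *I* spatial
   autocorrelation (spatially variable genes) instead of, or alongside,
   variance-stabilized dispersion (highly variable genes);
2. **dimensionality reduction** — MULTISPATI-PCA, a spatially weighted
   decomposition whose eigenvalues factor into *score variance ×
   Moran's I*, so the leading components are both variable and spatially
   coherent;
3. **clustering** — a multiplex Leiden optimizer that maximizes one
   partition over two graph layers simultaneously: the latent-space
   k-nearest-neighbor graph and a physical-space neighbor graph (hex or
   square lattice, Delaunay triangulation, or kNN).

## The model

Each layer *l* contributes a Reichardt–Bornholdt configuration-model
quality at its own resolution γ<sub>l</sub>,

    Q_l(γ_l) = Σ_ij ( A_ij − γ_l k_i k_j / 2m ) δ(c_i, c_j),

and the optimizer maximizes the weighted combination
`Q = Σ_l w_l Q_l(γ_l)` with the Leiden scheme (queue-based local moving,
refinement within communities, simultaneous aggregation of all layers).
Only the ratio of the layer weights matters; the latent layer is kept at
weight 1 and the spatial layer's weight trades expression evidence
against spatial context. Resolutions are tuned in two stages so the
partition reaches a requested number of domains: first the latent layer
alone (ordinary Leiden), then the spatial layer in the multiplex, holding
the latent resolution fixed.

All of this is implemented in the package (the optimizer core in C++);
evaluation (adjusted Rand index, normalized mutual information, paired
Wilcoxon signed-rank tests with Benjamini–Hochberg correction) and a
synthetic layered-tissue generator with known ground truth round out the
toolbox.

## Worked example

```r
library(spatialmux)

# a synthetic cortex-like section: 2000 spots on a square grid, 4 layered
# domains, 500 genes, 30% of spots carrying another domain's expression
# profile (ambiguous "mixed" spots)
spec   <- tissue_spec(noise_mixing = 0.3, seed = 1)
tissue <- simulate_tissue(spec)

logx  <- normalize_log1p(tissue$counts)
hvg   <- select_hvgs(tissue$counts, n_top = 500)
model <- multispati(subset_selected(logx, hvg),
                    build_grid_graph(tissue$coords), n_comp = 30)

latent  <- build_latent_knn(model$scores, k = 15)
spatial <- build_grid_graph(tissue$coords)

fit <- spatialleiden(latent, spatial, spatial_weight = "match",
                     target_k = 4, seed = 7)
print(fit)
#> spatialleiden: 4 clusters over 2000 spots
#>   spatial weight 2.218; resolutions: latent 1, spatial 0.7
#>   multiplex quality 18201.3190

truth <- tissue$truth
evaluate_partition(data.frame(id = truth$id, label = fit$membership), truth)
#> $ari  [1] 0.8310772
#> $nmi  [1] 0.809685
#> ...

# the non-spatial baseline on the same data
base <- spatialleiden(latent, spatial, spatial_weight = 0,
                      target_k = 4, seed = 7)
evaluate_partition(data.frame(id = truth$id, label = base$membership), truth)
#> $ari  [1] 0.3702553
```

With 30% of spots expressing the "wrong" domain's profile, expression
alone recovers the layering poorly (ARI ≈ 0.37); adding the spatial
layer resolves most of the ambiguous spots (ARI ≈ 0.83). At
`noise_mixing = 0` both exceed 0.95. `recovery_experiment()` repeats
this comparison over seeds and weights, and `compare_methods()` tests
the paired differences.

A thin command-line interface over the same functions ships in
`inst/cli/spatialmux.R` (subcommands `simulate`, `graph`, `reduce`,
`cluster`, `evaluate`, `compare`, `sweep-weight`).

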