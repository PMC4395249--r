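# netscale

Multi-scale, correspondence-preserving structural brain networks from
cortical landmarks and streamline tractography.

## The problem

Structural connectomes are usually built at one fixed resolution, yet
brain networks are modular at several nested scales, and without
node-level correspondence two subjects' networks cannot be compared
directly. `netscale` starts from a set of cortical landmarks whose ids
are shared across subjects (a corresponding-landmark system such as a
dense connectivity-based landmark atlas), and partitions them into
sub-networks recursively, producing a tree whose cut at depth *s* is the
scale-*s* network — nested by construction and corresponding across
subjects by construction.

## The model

For each subject *n* and landmark pair *(i, j)*:

* `G_n(i,j)` — approximate geodesic distance along the cortical mesh
  (Dijkstra on the edge-bisected mesh graph with in-triangle shortcuts):
  the short-range feature.
* `C_n(i,j) = 1` iff more than `thres` streamlines connect the two
  landmark patches (endpoints snapped to the surface first);
  `P_n(i,j)` = Dijkstra hop count on `C_n`: the long-range feature.

Per subject, `G_n` is max-normalized and `P_n` is max-normalized then
histogram-equalized; both are averaged over subjects and combined:

    D = α·G + (1−α)·P,      W_ij(δ) = exp(−D_ij² / (2δ²)),   α = 0.5

The number of clusters and the kernel scale are selected together from
the random-walk spectrum of `W(δ)`: with eigenvalue magnitudes
`λ_1 ≥ |λ_2| ≥ …`,

    Δ(M, δ) = max_k (λ_k^M − λ_{k+1}^M),    K(M, δ) = argmax_k (…)

are scanned over walk lengths `M = 1, 2, …` until `K = 1`; for each δ the
best local maximum of Δ is scored by its stability `M_b − M_a` (the walk
interval over which the structure survives), the most stable `(δ*, K*)`
wins, and the baseline spectral clustering (k-means on the top-`K*`
random-walk eigenvectors) performs the split. Recursion into each cluster
(with δ re-gridded on its sub-matrix) yields the multi-scale tree.

A scale's labels then group streamlines: fibers whose endpoints share a
sub-network form its **backbone bundle**; remaining fibers are classified
to the nearest bundle by mean closest distance under a 4 mm threshold.
Bundle correspondence across subjects is scored by Hausdorff distance
between bundle center fibers, and per-bundle FA/MD group differences by
Welch's two-tailed t-test.

## Worked example

Everything is testable without data downloads through the seeded
synthetic-cortex generator, which plants a known 4-group × 3-leaf
hierarchy of 36 landmarks on two bridged hemisphere meshes and draws
Poisson-modular streamlines:

```r
library(netscale)

scene <- generateScene(sceneSpec(seed = 7))
scene
#> SyntheticScene: 3 subject(s), 36 landmarks (4 groups / 12 leaves),
#>   350 fibers in subject 1

result <- analyzeScene(scene)
result$tree
#> NetworkTree: 36 landmarks, 3 scale(s); sub-networks per scale: 1, 4, 12

result$consistency$curve
#>   scale consistency nBlocks nPairs
#> 1     1  0.57242767       1    630
#> 2     2  0.21653057       4    144
#> 3     3  0.08751179      12     36

truth <- sceneTruth(scene)
truthAdjustedRand(scaleLabels(result$tree, 2), truth$groupLabel)  # 1
truthAdjustedRand(scaleLabels(result$tree, 3), truth$leafLabel)   # 1

result$atlas
#> BundleAtlas (scale 3): 12 bundles, 130 backbone + 2 classified fibers,
#>   218 unassigned (threshold 4.0 mm)
```

The tree found the planted hierarchy exactly: one network at scale 1,
the 4 groups at scale 2, the 12 leaf clusters at scale 3 (adjusted Rand
index 1 against the planted labels at both depths). The consistency
column is the mean within-sub-network `0.5·G + 0.5·P` — a distance, so
the decreasing curve (0.572 → 0.217 → 0.088) says sub-networks tighten
as the scale refines. The atlas groups the 350 fibers of subject 1 at
the deepest scale: 130 backbone fibers (37% of the whole set) whose
endpoints share a leaf, plus 2 fibers classified within the 4 mm
threshold; the rest — mostly deliberately planted cross-group
streamlines — stay unassigned.

`runPipeline()` is the same analysis driven from files (PLY/OFF
surfaces, landmark TSVs, TCK/TRK/plain-text fibers) that writes every
matrix, the tree JSON, per-scale label tables, the bundle atlas and a
manifest from which the run is reproducible.

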