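---
title: "Multi-scale structural brain networks: model, parameters and validation"
author: "netscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale structural brain networks: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscale)
```

## The problem

Whole-brain structural networks are usually built at a single resolution:
one atlas, one node size, one number of modules. Brains are not organised
that way — modules nest inside modules — and analyses are sensitive to the
scale at which nodes are defined. `netscale` builds *nested* partitions of
a common set of cortical landmarks, each landmark identified by an id that
is shared across subjects, so that the resulting sub-networks correspond
across individuals at every scale without image registration.

The package takes three inputs per subject:

* a triangular mesh of the cortical sheet (mm coordinates),
* a landmark table mapping shared landmark ids to mesh vertices
  (in the spirit of a dense connectivity-based landmark system with a few
  hundred corresponding points per brain),
* whole-brain streamline tractography as 3-D polylines, optionally with
  per-point diffusion scalars (FA, MD).

## The similarity model

Two complementary features are computed per subject `n` between every pair
of landmarks:

* **Short-range: geodesic distance** `G_n(i, j)`, the length of the
  shortest path along the cortical mesh between the two landmark center
  vertices. Nearby patches of cortex are likely to share short local
  connections that tractography cannot track, so surface proximity stands
  in for them. Geodesics are approximated by Dijkstra's algorithm on the
  mesh graph augmented with edge-midpoint nodes (level *s* bisects every
  edge into `2^s` segments; inside each triangle all boundary nodes are
  joined by straight segments so paths can cut across faces). Refining the
  level can only shorten distances, because each level's graph contains the
  previous one. On a flat criss-cross grid the level-1 approximation stays
  within about 4% of the true planar distance (worst-case stretch
  `1/cos(13.3°)`), which the test suite checks against the analytic oracle.

* **Long-range: fiber hop count** `P_n(i, j)`. Streamline endpoints are
  first snapped to the cortex (terminal segments extended to their first
  mesh intersection or truncated at their last crossing, default reach
  5 mm), then assigned to landmark patches (mesh vertices within a 5 mm
  geodesic radius of a center; overlaps resolve to the nearest center). A
  pair of landmarks is *connected* when strictly more than `thres` fibers
  join their patches (default 1, so at least two fibers — one stray
  streamline is not evidence). `P_n` is the shortest-path hop count on this
  binary graph; disconnected pairs receive the finite cap `L` so that later
  normalization stays defined and unreachable pairs look maximally distant.

Per subject, `G_n` is normalized by its maximum; `P_n` is normalized and
then histogram-equalized (mapped through its empirical CDF over the
off-diagonal entries). Hop counts concentrate on a few small integers;
equalization spreads them over (0, 1] so the long-range feature can
actually move the combined distance. Both features are then averaged over
subjects — legitimate only because landmark ids correspond across brains,
which the code enforces — and combined as

```
D = alpha * G + (1 - alpha) * P,     W(delta) = exp(-D^2 / (2 delta^2))
```

with `alpha = 0.5` by default (results are reported in the source
literature as robust for alpha roughly 0.4–0.65). The Gaussian denominator
is switchable to `delta^2` (`kernelDenom = "delta2"`) because both
conventions appear in print; the standard form is the default.

## Scale selection by random-walk eigengaps

For a fixed `delta`, let `lambda_1 >= |lambda_2| >= ...` be the eigenvalue
magnitudes of the degree-normalized random-walk matrix of `W(delta)`.
After `M` steps of the walk,

```
Delta(M, delta) = max_k (lambda_k^M - lambda_{k+1}^M)
K(M, delta)     = argmax_k (...)
```

`K` is the number of clusters the `M`-step walk sees; `Delta` how clearly
it sees them. Scanning `M = 1, 2, 3, ...` stops at the first `M` with
`K = 1` (a connected walk always mixes; a hard cap of `10^4` guards
near-disconnected cases in floating point). Powers are taken of
*magnitudes* so that `Delta` is well defined when the walk has negative
eigenvalues; `powering = "signed"` restores raw powers.

For each `delta` on a grid (evenly spaced from the smallest positive to
the largest entry of `D`, with as many points as the matrix order), the
best local maximum `M¹` of `Delta(·, delta)` is found, and its *stability*
is `M_b − M_a`, the span between the local minima bracketing it (scan
bounds substitute at the ends; plateaus collapse to their leftmost index
with a flatness tolerance of `1e-6`). The `(delta*, K*)` with the largest
stability wins; ties break toward larger `delta`, since coarse structure
lives at large length scales. The split itself is the baseline spectral
clustering: k-means (20 seeded restarts, best inertia) on the
row-normalized top-`K` random-walk eigenvector embedding.

The procedure recurses into every cluster with the delta grid re-derived
on the cluster's own sub-matrix, producing a tree. Recursion stops when a
node is unsplittable (no eigengap structure above the flatness tolerance),
smaller than `minSize = 3` (a pair has no meaningful spectrum), or at
`maxDepth = 5`. Scale-`s` labels cut the tree at depth `s`, with nodes
that stopped splitting persisting; by construction every scale refines the
previous one, and both properties are asserted in the test suite on every
tree built.

Two closed-form limits pin the selector down: two disconnected equal
cliques keep `K = 2` at every `M` with `Delta → 1` (selected and split
exactly), and a uniform complete graph has the gap at `K = 1` dominating
from `M = 1` (declared unsplittable immediately).

## Fiber bundles

Given a scale's labels, every fiber whose two endpoint landmarks share a
label joins that sub-network's **backbone bundle**; fibers bridging blocks
stay out. Remaining fibers are classified to the nearest bundle by the
symmetrized mean closest distance (fibers resampled to a 1 mm arc-length
step first, which makes the parallel-segment closed form exact), with
single-linkage to the backbone members (`linkage = "center"` measures to
the bundle's center fiber instead). A fiber joins only if its distance is
at most 4 mm — a heuristic threshold calibrated in the source literature
on manually delineated bundles — and near-ties go to the smaller label.
Classification is idempotent and can never place a fiber farther than the
threshold from its bundle; both are asserted in tests.

Bundle agreement across subjects is summarized by the Hausdorff distance
between bundle *center* fibers (the member minimizing the worst-case
Hausdorff distance to its co-members), averaged over subject pairs
(`averaging = "reference"` switches to distance-to-first-subject). Group
comparisons of per-bundle mean FA/MD use Welch's two-tailed t-test per
bundle; zero-variance degenerate inputs are flagged
(`exactDifference`) rather than crashed on, and no multiplicity
correction is applied — raw p-values are reported.

## The synthetic cortex generator

Real DTI cohorts cannot ship with a package, so validation rests on
seeded synthetic scenes with planted ground truth (`sceneSpec()`,
`generateScene()`). A scene emulates:

* **two hemispheres**: icosphere meshes (subdivision 4, 642→2562 vertices,
  ~4.5 mm vertex spacing, 70 mm radius) placed left and right of the
  midline with a 20 mm gap, joined by a short two-triangle medial strip.
  The strip matters: the cortical sheet is one connected surface, and
  without it cross-hemisphere geodesics are set by the disconnected-pair
  cap convention, which plants a spurious two-block structure stronger
  than any intended one. With the strip, cross-hemisphere geodesics are
  comparable to antipodal within-hemisphere ones.
* **hierarchically clustered landmarks**: 4 groups (alternating
  hemispheres, equally spaced on a great circle) of 3 leaf clusters
  (ring of angular radius 35° around the group center) of 3 landmarks
  (center vertex plus a 6° ring), 36 landmarks in all — small enough for
  exhaustive oracles. The 35° ring keeps cross-leaf geodesic separation
  several times the within-leaf spread given the 4.5 mm vertex
  quantization, so leaf identity is unambiguous.
* **modular streamlines**: fibers are quadratic arcs sagging toward the
  deep white matter between jittered patch points (endpoints nudged
  0.5 mm under the surface so endpoint snapping has real work), with
  per-pair Poisson counts at three rates: `lambdaLeaf = 4` within leaves,
  `lambdaGroup = 1.2` across leaves of one group, `lambdaInter = 0.2`
  across groups. With the default `thres = 1`, these give connection
  probabilities of about 0.91, 0.34 and 0.02. `lambdaGroup` is chosen so
  that every leaf pair within a group carries at least one direct link
  with probability ≈ 0.98 — the hop feature then reliably sees each group
  as a hop-1/hop-2 module while groups stay hops apart, mirroring the
  short-range/long-range logic of the method itself.
* **multi-subject variability**: per-subject vertex jitter (σ = 1 mm),
  per-fiber point jitter (σ = 0.5 mm, smoothed), 3 subjects sharing the
  landmark id schema; all randomness derives from one seed and the same
  seed reproduces a scene bitwise.

What the generator deliberately does **not** emulate: cortical folding
(geodesics on a sphere are benign; on a folded sheet geodesic and
Euclidean distance diverge much more), tractography failure modes
(premature stops, false continuations), distance-dependent fiber loss,
and partial-volume effects. Passing the planted-recovery tests therefore
shows the machinery is correct and stable under geometric jitter and
Poisson sampling noise — not that the method's anatomical conclusions on
real DTI data are right.

## Validation results the package computes

With the defaults above, across 20 generator seeds: the first split
selects `K* = 4` and recovers the planted groups (adjusted Rand ≥ 0.9),
the depth-2 cut recovers the 12 leaves (ARI ≥ 0.9), and the mean
within-sub-network `0.5 G + 0.5 P` (the consistency measure; smaller =
tighter) is non-increasing from scale 1 to the deepest scale — each in at
least 18 of 20 seeds, and in the shipped configuration in 20 of 20. The
same study, plus oracle checks (BFS hop counts, dense eigendecomposition,
the closed-form limits, the 4 mm classification contract, planted-bundle
recovery at 1 mm jitter ≥ 0.95, flat-mesh geodesic error < 8%) is
recomputed from scratch by `scripts/acceptance.R` and by the test suite;
the vignette intentionally states no number that those runs do not
themselves produce.

Problem sizes were chosen to keep the full validation comfortably
desk-sized: 36 landmarks, ~2500 vertices per hemisphere mesh, ~350 fibers
per subject, 3 subjects, 20 seeds.

## Numerical choices and edge cases

* Eigenvalue magnitudes are clamped at 1 before powering (floating-point
  `1 + 1e-15` raised to the 10^4 would otherwise drift).
* `delta` grids on constant sub-matrices collapse to a single point with
  a warning; all-equal distances make `bipartitionCheck()` return an
  explicit `"no structure"` token rather than an arbitrary split.
* k-means failures on degenerate embeddings (fewer distinct rows than
  `K`) make the node a leaf instead of crashing the tree.
* Unreachable landmark pairs: geodesic cap defaults to twice the largest
  finite distance (`cap = NA` turns them into an error); hop cap defaults
  to the landmark count.
* Classification prescreens candidate backbone fibers with a
  centroid/radius lower bound on the mean closest distance; the bound is
  conservative, so results equal the exhaustive computation.
* Serializations (`treeToJSON()`, the pipeline manifest) are
  deterministic: fixed field order, sorted ids, `NA` as JSON null; two
  runs with the same seed are byte-identical, which the determinism test
  asserts.

## Known limitations

* The stability measure saturates when several structures all outlive the
  `10^4`-step scan cap; ties then resolve toward larger `delta`. This is
  inherent to a finite scan of a quantity the theory defines at `M → ∞`.
* Histogram equalization makes every directly connected pair look equally
  close in the hop feature, regardless of which module the link crosses;
  leaf-level discrimination therefore leans on the geodesic feature.
* Patch membership is vertex-based; on meshes much coarser than the patch
  radius a patch can degenerate to its center vertex alone.
* TRK voxel-to-mm conversion applies the header affine to
  voxel-size-scaled coordinates without the half-voxel origin shift some
  tools use; round-trips through this package are exact either way.
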