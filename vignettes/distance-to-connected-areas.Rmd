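---
title: "Connectivity-distance gradients anchored in primary cortex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-distance gradients anchored in primary cortex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(geodca)
```

## The measure

Most cortico-cortical connections are local; long-range connections
concentrate in heteromodal association cortex.  **Distance-to-connected-areas
(DCA)** turns that observation into a per-vertex scalar.  For a vertex $v$ of
a triangulated hemisphere mesh, let $N_p(v)$ be the $k$ vertices with the
highest Pearson correlation to $v$'s BOLD-like time series, with
$k = \max(1, \mathrm{round}(\tfrac{p}{100}(N-1)))$ and $p = 2$ by default.
Then

$$\mathrm{DCA}(v) \;=\; \frac{1}{|N_p(v)|} \sum_{u \in N_p(v)} d_g(v, u),$$

where $d_g$ is the geodesic distance along the cortical sheet.  Low values
mean a vertex's strong connections are nearby (typical of primary visual,
auditory, somatomotor cortex); high values mean it participates in
distributed networks (association cortex).  The package's inferential claim
is that the DCA map increases with geodesic distance from primary-cortex
landmarks, and that this anchoring is unlikely under a randomly arranged
network topography.

```{r pipeline}
mesh   <- make_icosphere(4, radius_mm = 70)        # or read_fs_surface()
dist   <- geodesic_distance_matrix(mesh)
config <- generator_config(rng_seed = 1)
tiers  <- make_tiered_parcellation(mesh, config, dist = dist)
sim    <- simulate_timeseries(mesh, tiers$parc, config, dist)
conn   <- correlation_matrix(sim$ts[[1]])
dca    <- distance_to_connected_areas(conn, dist, percent = 2)
dfp    <- multi_source_distance(mesh, tiers$seeds, dist_matrix = dist)
spatial_correlation(dca, dfp)
```

## Geodesic distances on a triangle mesh

Exact polyhedral geodesics (continuous shortest paths across faces) are
approximated by Dijkstra on an enriched graph:

1. one round of **flat edge-midpoint subdivision** — midpoints lie on the
   original faces, so the surface is unchanged while the graph is refined;
2. **unfolding shortcuts** — for every pair of adjacent triangles the two
   faces are rotated into a common plane; if the straight segment joining
   the two opposite vertices crosses the shared edge, it is a valid surface
   path and becomes an extra graph edge of that length.

The result is bracketed entrywise by the straight-line (Euclidean) distance
below and the plain edge-graph Dijkstra distance above; both bounds are
asserted in the test suite.  On a subdivision-4 unit icosphere the
antipodal distance comes out within 0.2% of the great-circle arc $\pi$,
versus ~6% for edge-restricted Dijkstra.  Dense $N \times N$ matrices are
practical to roughly a 10k-vertex hemisphere (~800 MB); beyond that the
`sources` argument computes selected rows.  All distances are per
hemisphere; no cross-mesh distance is defined.

To adjust for brain size before group analysis, `normalize_distances()`
affinely rescales the **off-diagonal** distance distribution to $[0, 1]$
(the self-distance diagonal is excluded from the min/max — a deliberate
convention, recorded with the matrix so
`rescale_to_mm()` / `denormalize_distances()` stay exact inverses).  The
mm-rescaling of a group map uses the mean of subject minima and ranges,
`value_mm = value * mean(range) + mean(min)` — a documented convention
chosen for being the exact inverse in the single-subject case.

## Connectivity

Per-run connectivity is the Pearson correlation of vertex time series;
runs are combined by entrywise averaging of raw r; a Fisher-z option
exists but is off by default.
Correlation is invariant to per-row affine rescaling, so upstream
mean-centering/variance-normalization needs no counterpart here.  Vertices
without data (e.g. occipital-pole dropout) are repaired before correlation
by iteratively averaging immediate neighbours that hold data
(`fill_missing_vertices()`); the repair is idempotent and never touches
valid vertices.  Thresholding is node-wise (each vertex keeps its own top
$p\%$), which compensates for overall correlation-strength differences
across vertices; ties at the cutoff break towards the lower vertex index
so results are reproducible, and negative correlations simply rank low.

## The permutation null

The observed anchoring statistic could in principle arise from any
spatially smooth arrangement.  The null model therefore re-places the
parcellation's patches at random while preserving their sizes:

1. patches are the connected components of each network's vertex set
   (`extract_patches()`; components above 25 vertices by default);
2. `random_patch_layout()` grows one random, spatially connected,
   size-matched patch per template;
3. connectivity of the layout is modelled as a **binary graph linking
   vertices within, but not between, networks**, so the model DCA of a
   vertex is its mean distance to all other vertices of its network
   (`model_distance_map()`);
4. distance-from-primary is recomputed from the new locations of the
   patches whose templates belonged to the primary networks;
5. the Spearman correlation of (3) and (4) is recorded; over `n_iter`
   draws the one-sided empirical p-value uses the add-one rule
   $p = (1 + \#\{r_{null} \ge r_{obs}\})/(n_{iter} + 1)$, the observed
   statistic being the same binary-model correlation on the original
   parcellation.

Two placement regimes exist.  When templates cover only part of the mesh
(the real-data regime — e.g. a 17-network template with the medial wall
unassigned and small patches dropped), patches are grown one at a time in
descending size order by uniform boundary accretion, and leftover vertices
stay unassigned.  When templates tile the mesh exactly (the synthetic
regime), sequential growth can never leave a perfectly fillable remainder
— random blobs always enclose pockets — so all patches grow competitively
to their size caps from random starts, leftover pockets are flooded from
adjacent patches, and sizes are then matched exactly by transferring
single boundary vertices, each move keeping the donor patch connected.
Placement order and randomness depend only on the template sizes and
their grouping (never on network ids), making the null distribution
invariant to relabeling of non-primary networks, and the whole layout is
reproducible from its seed.  Same-network patches are not constrained
apart; if two touch they merge as spatial components, which leaves the
network-level binary model unchanged.  Spearman (midranks) is used for
the per-iteration correlation, keeping the null statistic on the same
rank-based scale as the observed anchoring correlation.

This null preserves patch-size structure but not the spatial
autocorrelation of the data maps; autocorrelation-preserving alternatives
(spin tests, variogram matching) are deliberately out of scope.

## Network profiles

`sample_network_distributions()` collects the DCA values within each
network and sorts by increasing mean.  Pairs of distributions are compared
with the Jensen-Shannon divergence on shared equal-width bins spanning the
pooled range of **all** networks (64 bins by default; natural log, so the
upper bound is $\ln 2$ — bin count and log base are both configurable).  `cluster_networks()` applies k-means
to the divergence-matrix rows (best of at least 10 restarts) with $k = 3$
by default, the grouping the sorted means suggest on cortical data.

## The synthetic cortex

Real resting-state surface data cannot be bundled, so the generator
supplies study conditions with known ground truth.  Defaults (all chosen as desk-scale
but geometrically nontrivial): a subdivision-4 icosphere of radius 70 mm
(2,562 vertices, comparable spacing to a 10k-vertex hemisphere template at
half resolution), 8 equal-size networks (2 primary, 3 intermediate, 3
distributed), local correlation decay $\exp(-d_g/\lambda)$ with
$\lambda = 10$ mm, cross-patch correlation $\rho = 0.35$ within
distributed networks and $\rho/2$ within intermediate ones, $T = 600$
timepoints, measurement noise SD 0.5, one subject and one run (more via
the config).

The layout is built around two antipodal anchor vertices on a random axis:
the nearest quarter of the mesh (by geodesic distance to the anchors)
forms the two compact primary caps, whose union is the primary seed
region; the middle band forms three intermediate networks (north/south
arc pairs); the far, equatorial band is split into six alternating
longitude sectors giving three distributed networks of two patches each,
placed far from the anchors.  Tiny discretization slivers at band
boundaries are absorbed into neighbouring labels so every patch is a
meaningful spatial unit.

Design notes:

* **Why intermediate networks carry $\rho/2$.**  With long-range coupling
  only in the distributed tier, primary and intermediate vertices would
  both have purely local top connections and therefore indistinguishable
  DCA distributions — a three-way network grouping would be structurally
  unrecoverable.  A reduced cross-patch coupling gives intermediate
  networks moderately distant partners (their paired arcs sit ~80-100 mm
  apart versus ~140 mm for distributed sectors), which is exactly the
  mechanism that gives attention networks their intermediate connectivity
  distance in cortical data.
* **Covariance repair.**  Local decay plus block increments need not be
  positive semi-definite; eigenvalues are clipped at a small positive
  floor and the matrix renormalized to unit diagonal.  Sampling uses the
  factor of the repaired matrix directly, so the sample correlation
  converges to the repaired target.
* **Noise and ranks.**  Independent measurement noise attenuates all
  off-diagonal sample correlations by $1/(1+\sigma^2)$ uniformly.  Because
  thresholding is rank-based per node, attenuation changes no top-$k$ set:
  `ground_truth_dca()` is computed from the noiseless repaired target and
  remains the correct recovery limit.
* **What the generator does not emulate**: hemodynamic response shapes,
  temporally autocorrelated noise, head motion, folding geometry
  (sulci/gyri), inter-subject anatomical variability.  Passing recovery
  tests therefore demonstrates the estimator and the inference machinery,
  not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* `k(percent, N) = max(1, round(percent/100 * (N-1)))` with base R
  rounding; `k >= 1` means no vertex ever has an empty neighbour set.
* Distance normalization requires at least two distinct off-diagonal
  values; constant matrices are rejected.
* `model_distance_map()` rejects single-vertex networks (mean over an
  empty set) and returns `NA` for unassigned vertices, which all
  correlations drop.
* The ICC map uses ICC(2,1) — two-way random effects, absolute agreement,
  single measurement — across runs, with ICC(3,1) (consistency) as a
  config option.  Values are clipped to $[-1, 1]$.
* The empirical p lives on the grid $\{1, \ldots, n+1\}/(n+1)$; its
  calibration under exchangeable (unstructured) topographies is checked
  by simulation in the test suite.
* Random layouts retry on dead ends (bounded per-patch retries, bounded
  layout restarts) and fail loudly suggesting a new seed; failed
  iterations inside the null test are redrawn with derived sub-seeds and
  counted in the result.

## Problem sizes used in the tests

The test suite exercises the full default synthetic cortex (2,562
vertices, $T = 600$, 200 null iterations) once and shares it across the
end-to-end checks; geodesic oracle checks use twenty varied meshes of at
most 500 vertices; the definition oracle uses fifty random instances of at
most 200 vertices; null calibration uses a subdivision-2 icosphere (162
vertices) with 100 repeats of 50-iteration nulls.

## Known limitations

* The geodesic approximation is an upper-bounded surrogate, not the exact
  polyhedral geodesic; on very anisotropic or degenerate triangulations
  its error grows with triangle quality.
* Dense distance matrices bound the practical mesh size; row streaming is
  available but the pipeline's thresholding currently expects the full
  matrix.
* The binary within-network model ignores connection weights and
  between-network coupling; it is a topography null, not a generative
  model of connectivity.
* Hemispheres are processed separately throughout; pooling of network
  distributions across hemispheres, if desired, is the caller's
  concatenation step.
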