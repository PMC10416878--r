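---
title: "Counting epithelial cell layers by onion peeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting epithelial cell layers by onion peeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onionpeel)
```

## The problem

Oral epithelium is a stratified squamous sheet: a basal cell layer sits on
connective tissue (stroma), further epithelial layers pile on top of it, and
the surface is covered by the largely anuclear stratum corneum. Altered
stratification — in particular an increased number of cell layers — is one
of the features pathologists weigh when grading oral dysplasia, but it is
usually assessed by eye. `onionpeel` turns a table of segmented nuclei
(centroid position and cell class, as produced by modern segmentation
networks) into a per-slide layer count with an explicit, reproducible
procedure.

## The procedure

Given one slide's cell table, the per-slide chain
(`count_layers()`) is:

1. **Neighbor graph.** Delaunay triangulation of all nucleus centroids;
   every triangulation edge makes its endpoints neighbors. Edges longer
   than `max_edge_len = 500` pixels (40x magnification) are removed —
   points that far apart are not biological neighbors. The threshold is
   strict: an edge of exactly 500 px survives, 500.1 px does not.
2. **Edge-point classification.** For each epithelial nucleus (basal,
   other-epithelial, or intraepithelial lymphocyte): a background or
   corneum point among its neighbors makes it an *outside edge point*; a
   stroma nucleus among its neighbors makes it an *inside edge point*;
   both conditions give the role `BOTH`; neither gives `INTERIOR`.
3. **Fragment filter.** Connected components of the epithelial induced
   subgraph with fewer than `min_component_size = 20` cells — debris from
   tissue cracks or small connective islands — have all roles reset to
   `NON_EDGE`, so they neither seed nor absorb the peeling wave. Exactly
   20 cells is kept.
4. **Peeling.** All outside edge points form layer 1. Each
   breadth-synchronous step visits the whole frontier's unvisited
   epithelial neighbors and increments the layer index. When an inside
   edge point is first reached, the current index is recorded as its
   layer count; `BOTH` nodes (a one-cell-thick epithelium) record 1.
   The recorded count therefore equals 1 + the minimum hop distance from
   the outer seed set within the epithelial subgraph — an invariant the
   test suite checks against an independent shortest-path oracle.
5. **Summary.** The slide's thickness is the median (type-7 interpolated
   quantile, configurable) of the reached inside-edge counts; the
   population SD measures thickness variability. Inside edge points in
   components with no outer boundary are reported as unreachable and
   excluded, never imputed.

Two deliberate asymmetries are worth stating. The wave is seeded at the
*outer* edge and counts are recorded at the *inner* (basal) edge: on a
fixed graph the two directions give symmetric hop counts, and recording
at the basal edge matches where the counts are biologically interpreted
(thickness above the basement membrane). And only epithelial nuclei are
traversable — stroma, corneum and background points serve purely as
classification context, otherwise the wave could short-circuit around
the epithelium through the stroma.

```{r example}
spec <- epithelium_spec(n_layers = 5, length = 30, jitter_sd = 6, seed = 1)
res <- count_layers(generate_epithelium(spec)$cells)
res
```

## Pseudo-points

Background and stratum corneum contain no segmentable nuclei, yet the
outside-edge rule needs background/corneum *points* among a nucleus's
neighbors. `generate_pseudo_points()` therefore lays a hexagonal grid
(default spacing 60 px at 40x, about one nucleus diameter) over the
BACKGROUND and CORNEUM regions of the semantic map and marks the points
`is_pseudo = TRUE`. This is this package's reconstruction of how such
regions become graph nodes; the choice of grid geometry has no effect on
counts beyond guaranteeing that boundary-crossing Delaunay edges exist.

## Fusing the two segmentation models

Whole-slide prediction processes aligned patch pairs: a 500x500 patch at
10x for the semantic (region-class) model and the co-located 2000x2000
region at 40x for the instance (nucleus) model, the latter sub-tiled
into partially overlapping 500x500 windows. `plan_tiles()` steps windows
by `500 - 2 * margin` (default margin 50 px, roughly two nucleus
diameters) and assigns every location to exactly one window's retained
interior; a property test fuzzes this ownership partition with random
centroids. `fuse_slide()` drops margin-only detections, keeps one record
per nucleus, and gives each surviving instance the cell class of the
semantic map at its centroid (`SEMANTIC_TO_CELL`), keeping the instance
geometry untouched. Non-epithelial tissue collapses to `STROMA`: the
peeling rules only need "stroma-like tissue outside the epithelium".
The map cannot produce `LYMPHOCYTE`; that class survives only in
ingested tables from instance models that emit it. Lymphocytes are
traversable and acquire edge roles by the same neighbor rules — an
intraepithelial lymphocyte occupies a layer position.

## The synthetic generator

`generate_epithelium()` builds point patterns with known ground truth:

* **Strips** are hexagonal-offset lattices (row pitch
  `spacing * sqrt(3)/2`): background and corneum rows above, K epithelial
  rows (outermost first, basal last), stroma rows below. On a hex lattice
  the Delaunay neighbors of an interior point are exactly its six lattice
  neighbors, so row count equals hop count + 1 exactly. The short cut
  ends of the strip are capped with columns of stroma: a straight lattice
  end has vertically collinear boundary points whose Delaunay edges skip
  a row, which would create hop shortcuts at the ends; the caps (read:
  the lateral continuation of connective tissue where the section was
  cut) block these, at the cost of a few extra inside-edge points along
  the cap interface whose counts (1..K) are exact by construction and do
  not move the median for the default strip length of 40 cells.
* **Annuli** place concentric rings — stroma core, K epithelial rings
  (basal innermost), corneum, background — with radial pitch equal to the
  azimuthal spacing. With that pitch a ring-skipping Delaunay edge is
  geometrically impossible (a blocking point of the intermediate ring
  always lies within the critical lateral distance of the chord), so
  radial adjacency, and hence exact recovery of K, is guaranteed for any
  rotation.
* **Noise and defects.** Gaussian positional jitter (the recovery tests
  use up to 15% of the spacing), rectangular cracks entering from the
  outer surface (depth fraction 1 detaches a fragment; less than 1
  leaves a thinned bridge), and a lymphocyte replacement fraction.

Defaults — spacing 60 px, strip length 40 cells, 3 stroma / 2 corneum /
2 background rows, 2 cap columns — are nucleus-scale values typical of
40x oral epithelium imagery and are fixed; they are the conditions under
which all reported recovery rates are measured. What the generator does
*not* emulate: irregular nucleus density gradients, curved or branching
epithelium (rete pegs), segmentation misclassification noise, and
staining artifacts. Passing the recovery suite therefore demonstrates
the counting algorithm's correctness on layered point patterns, not the
robustness of any upstream segmentation.

`generate_cohort()` draws per-slide medians from group-specific normal
distributions (rounded to the half-integer grid medians of integer
counts live on; default three groups of 45/82/8 slides with mean
thickness 8/11/15 layers, SD 2) and simulates progression-free intervals
as exponential with log-hazard `intercept + beta * median_layers`
(defaults -7.5 and 0.15 per layer, giving realistic day-scale times).
Censoring is independent `Uniform(0, u)`, with `u` solved per subject so
the marginal censoring probability equals the requested rate (default
0.3).

## Cohort statistics

`compare_groups()` is a one-way ANOVA F-test of a per-slide summary
(median layers, or their SD) across diagnosis groups, with the two
degenerate decompositions made explicit: zero between-group sum of
squares reports F = 0, p = 1 even when the within-group variance also
vanishes; perfect separation with zero within-group variance reports
F = Inf, p = 0. `survival_split()` ranks slides by median layer number,
splits at the cohort median into groups of `floor(n/2)` and
`ceiling(n/2)` (ties broken by a stable sort on slide id — for 135
slides, 67 vs 68), estimates Kaplan-Meier curves per group and fits a
Cox proportional-hazards model on the group indicator with Efron tie
handling. The Cox model is group-only by default; additional covariate
columns can be passed in, since the relevant covariate set for a
"multivariate" model is a study-level choice this package does not make
for you.

## Numerical choices and edge cases

* Coordinates are raster-convention throughout: x = column, y = row,
  0-based, 40x pixels; 10x maps carry `scale = 4` and are only ever
  sampled, never resampled.
* Exactly co-located centroids (real tables contain them) are jittered
  by 1e-6 px under a fixed internal seed before triangulation; original
  coordinates are kept on the nodes, and construction is deterministic.
* Long-edge pruning is applied once, globally, before classification and
  peeling. Pruning inside the peeling loop would visit the same
  neighbor sets in the same order; the global form is the simpler
  contract.
* The slide summary uses the type-7 interpolated quantile and the
  population (ddof = 0) standard deviation; both conventions are stated
  so results can be reproduced elsewhere.
* The fragment filter counts *epithelial* cells per component of the
  epithelial induced subgraph — the full graph is globally connected
  through pseudo-points, so filtering on it would never remove anything.
* Readers reject invalid class labels and unparseable coordinates with
  row-level errors rather than coercing them.
* `run_pipeline()` isolates failures per slide, and its manifest records
  parameters, seed, package version and input/output MD5 hashes — and no
  timestamps, so identical configuration reproduces byte-identical
  output trees.

## Problem sizes used in the checks

The recovery and oracle suites run at desk scale, chosen to finish in a
few minutes on one core while keeping every property meaningfully
exercised: 200 random epithelial point clouds of up to ~200 nodes for
the shortest-path oracle; K = 1..15 noise-free strips and annuli; 150
jittered strips (50 seeds x K in {3, 6, 10}, sigma = 15% of spacing) for
the noisy-recovery rate and the recovered-vs-true regression; and
100-seed cohort simulations for the Cox and ANOVA recovery rates. The
`scripts/acceptance.R` entry point recomputes all of these from scratch
with a caller-supplied seed.

## Known limitations

* Layer counts are hop counts: they measure cell layers, not microns,
  and are undefined inside the stratum corneum.
* A slide whose epithelium nowhere touches background/corneum (or
  stroma) in the cell table has no outer (or inner) boundary and is
  rejected rather than guessed at.
* The semantic fixture and the fusion stage assume axis-aligned band
  zonation when rasterizing; real label maps are consumed as-is.
* Manual layer counting — the clinical comparator — is itself variable
  between observers; synthetic ground-truth recovery is this package's
  substitute for that comparison, with the caveats listed above.
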