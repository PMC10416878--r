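# onionpeel

Counting oral epithelium cell layers from segmented nuclei.

## What it does, and for whom

Oral epithelial dysplasia is graded in part by how the epithelium
stratifies — more cell layers generally means worse disease — but layer
number is normally judged by eye on H&E slides. `onionpeel` is for
digital-pathology researchers who already run nucleus segmentation on
whole-slide images and want a reproducible, quantitative layer count per
slide, plus the cohort-level statistics to use it.

The input is a cell table: one row per nucleus with its centroid
(pixels at 40x), class (basal, other epithelial, lymphocyte, stroma,
corneum, background) and optional area. The package supplies:

* **the Onion Peeling layer counter** — the core algorithm;
* **a fusion stage** that builds such cell tables from semantic label
  maps (10x, five region classes) plus instance-segmentation centroids,
  with whole-slide tiling, overlap-discard and center-based
  reclassification;
* **a synthetic generator** of layered epithelial point patterns with
  known ground truth, and of cohorts with thickness-dependent survival;
* **cohort statistics**: one-way ANOVA across diagnosis groups,
  median-split Kaplan–Meier curves and Cox proportional hazards on
  progression-free interval (PFI);
* a directory-level pipeline (`run_pipeline()`) and a thin CLI
  (`inst/scripts/onionpeel`).

## The algorithm

Let `G` be the Delaunay triangulation of all nucleus centroids, with
edges longer than 500 px (40x) removed — strictly: an edge of exactly
500 px is kept. For each epithelial nucleus `v`:

* a BACKGROUND or CORNEUM neighbor makes `v` an *outside edge point*;
* a STROMA neighbor makes `v` an *inside edge point* (both ⇒ `BOTH`).

Epithelial connected components with fewer than 20 cells (crack debris,
small connective islands) are re-labeled non-edge. The peeling wave then
starts from all outside edge points (layer 1) and expands
breadth-synchronously through epithelial nuclei only; when an inside
edge point is first reached, the current layer index is its layer
count, i.e.

```
layer_count(v) = 1 + min-hop-distance(outer edge set → v)
```

within the epithelial subgraph. The slide's thickness is the median of
the inside-edge counts and its variability is their (population) SD.
Unreachable inside-edge points are reported, not imputed. Since
background and corneum contain no nuclei, hexagonal grids of
pseudo-points are synthesized in those regions so boundary-crossing
Delaunay edges exist.

## Worked example

```r
library(onionpeel)

# a 7-layer epithelium strip, 30 cells long, with positional noise
spec <- epithelium_spec(n_layers = 7, length = 30, jitter_sd = 6, seed = 42)
gen  <- generate_epithelium(spec)   # 460 cells incl. stroma + pseudo-points
res  <- count_layers(gen$cells)
res
#> layer_result: n_inner = 42  median = 7  sd = 1.826  unreachable = 0
```

The slide's 42 inside-edge (basal-boundary) nuclei have median layer
count 7 — the planted ground truth — with SD 1.83 reflecting the noise
and the cap-interface counts; no inside-edge nucleus was unreachable.

```r
co <- generate_cohort(cohort_spec(seed = 42))   # 135 slides, 3 groups
compare_groups(co, "median_layers")
#> one-way ANOVA on median_layers
#>                       group  n      mean median
#>  hyperkeratosis_hyperplasia 45  7.877778   8.00
#>               mild_moderate 82 10.780488  10.75
#>            severe_carcinoma  8 14.937500  14.50
#> F(2, 132) = 54.02, p = 7.228e-18

survival_split(co)
#> median split at 10 layers; group sizes: low=67, high=68
#> Cox HR (high vs low) = 2.044 [1.287, 3.247], Wald p = 0.002455, LRT p = 0.00253
```

Thicker epithelium separates the synthetic diagnosis groups (F-test)
and carries the planted survival hazard: the high-layer half of the
cohort progresses about twice as fast.

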