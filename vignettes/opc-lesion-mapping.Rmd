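---
title: "Lesion-centered spatial and morphometric quantification of stroke-responsive OPCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-centered spatial and morphometric quantification of stroke-responsive OPCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opcmap)
```

## The problem

After a white-matter stroke, oligodendrocyte progenitor cells (OPCs,
PDGFRα+) proliferate and redistribute around the lesion and along the
vasculature — the oligovascular niche. Quantifying that response from
confocal microscopy raises several linked measurement problems:

* Where, relative to the lesion, is OPC density different between two
  cohorts (e.g. control diet versus diet-induced obesity), and is the
  difference statistically defensible position by position?
* How close are OPCs to the nearest vessel, and how many sit on a vessel
  per millimeter of vascular length?
* How large is the lesion, given only 3–5 measured section areas?
* Is myelin thinner (higher g-ratio), is the vascular network longer or
  more branched, and how much of a marker colocalizes with vessels?

`opcmap` implements each of these as a tested, seeded computation, together
with a synthetic-data module that generates every input with known ground
truth. The workflow scripts under `analysis/` run the full sequence.

## Coordinate and raster conventions

All coordinates are micrometers with the lesion center at the origin
(`recenter_pattern()` translates raw coordinates there) and y increasing
upward. Sections are thin (10 µm) slabs: a z coordinate is carried through
but ignored by the 2D analyses. Rasters are `(row, col)` matrices with row 1
at the top; written grid TSVs put the maximal y in row 1.

## kNN density maps and the permutation p-value map

The local density at grid node $x$ is the k-nearest-neighbor estimate

$$\hat f(x) = \frac{k}{n \,\pi\, d_k(x)^2},$$

where $d_k(x)$ is the distance from the node to its $k$-th nearest cell and
$n$ the pattern's cell count. The default smoothing parameter is $k = 8$.
Dividing by $n$ makes maps of sections with different cell counts
comparable (each map integrates to roughly 1 over the support of the
pattern); the alternative $k-1$ numerator is a one-line change in
`knn_density_map()`. Two numerical choices matter:

* **Coincident cells.** If a node coincides with $\ge k$ stacked cells,
  $d_k = 0$ would give an infinite estimate; $d_k$ is floored at half the
  grid spacing, preserving ordering without infinities.
* **No edge correction.** Near the window boundary $d_k$ reaches into empty
  space and densities are biased low. The default grid (±1 mm at 50 µm
  spacing, ~40 nodes per lesion axis) keeps the lesion well inside the
  window; the bias is documented rather than corrected.

The estimator's irreducible noise is worth keeping in mind: for a
homogeneous pattern, $\hat f$ at a node behaves as $k/\Gamma(k)$ (inverse
gamma), so at $k=8$ the per-map coefficient of variation is ≈ 0.41 and the
median relative error ≈ 0.24 regardless of $n$. Averaging the per-section
maps within a group reduces this by $\sqrt{n_\text{sections}}$.

`density_pvalue_map()` compares two groups of section patterns: per-section
maps are averaged within group, the observed difference
$\Delta(x) = \bar f_B(x) - \bar f_A(x)$ is referred to a null distribution
obtained by permuting section-level group labels and recomputing
$\Delta^*(x)$, and the two-sided p-value at each node uses the add-one
convention $p = (1 + \#\{|\Delta^*| \ge |\Delta|\})/(B+1)$, so $p$ is never
0. Implementation detail: per-section maps are computed once and stacked,
and every permutation is a weight-vector multiply against that matrix, so
999 permutations cost little more than one.

Choices where the design was genuinely open:

* **Exchangeable unit.** Sections are the default unit (a 3 × 3 design
  gives 9 vs 9 sections, $\binom{18}{9} = 48620$ arrangements). Animal-level
  permutation is available (`unit = "animal"`), but with 3 vs 3 animals only
  $\binom{6}{3} = 20$ arrangements exist and the smallest achievable
  two-sided p is 2/20 = 0.1 — below no conventional threshold. Section-level
  exchange is what makes p < 0.05 maps possible at this design size; it
  assumes sections are exchangeable across animals under the null, which is
  stronger than animal-level exchangeability.
* **Exhaustive enumeration.** When the number of arrangements is at most
  `exhaustive_cap` (default 5000) the full enumeration replaces sampling and
  $p = \#\{|\Delta^*| \ge |\Delta|\}/n_\text{arr}$ with the identity
  arrangement included.
* **No multiple-testing correction across nodes.** Maps are thresholded at
  raw p < 0.05 per position; an optional Benjamini–Hochberg switch
  (`fdr = TRUE`) is off by default.

`significant_region_area()` reports flagged-node counts, areas (count ×
spacing²) and the centroid. For annular signals note that the centroid of a
radially symmetric mask is the origin; `mask_annulus_jaccard()` therefore
also reports the mean radial position of flagged nodes, the meaningful
localization summary for ring-shaped regions.

## Vessel proximity

`nearest_vessel_distances()` computes each cell's exact minimum distance to
a polyline vessel network (orthogonal projection onto every segment, clamped
to endpoints; ties to the lowest segment id). Distances are to the
centerline by default; with per-segment radii, `subtract_radius = TRUE`
approximates surface distance (floored at 0). The distance distribution uses
half-open 5 µm bins over 0–35 µm plus an overflow bin (bin width is a
choice: seven bins over the 0–35 µm range). A cell is "vessel-associated"
when its distance is at most 5 µm — about one cell radius; the threshold is
a configuration value because the underlying contact criterion is not
measurable from centerline data alone.

## Lesion-volume bootstrap

From an animal's 3–5 measured section areas, each bootstrap replicate draws
25 areas with replacement and sums area × 40 µm — 25 sections of 40 µm
representing the full ~1 mm lesion span. Resampling is per-animal; group
comparison of per-animal volumes is delegated to the Mann–Whitney U test.
Two readings of "a bootstrapped area distribution (n = 25)" are possible;
the default treats 25 as the resampled section count (the span reading), and
`scheme = "replicates"` provides the 25-replicate alternative. Resampling is
with replacement (the standard bootstrap; the source procedure does not
say). When the exact resampling distribution is small
(`|areas|^25` ≤ 4096, e.g. toy inputs) it is enumerated exactly.

The estimator is unbiased for (mean sampled area) × span, not for the true
volume: where the sampled planes sit matters. Planes clustered at the
lesion's widest part overestimate; the generator therefore spaces sampled
planes 240 µm apart by default so 5 planes span the lesion, and
`analysis/05_lesion_volume.R` reports the bootstrap mean next to the
generating ellipsoid's analytic volume $(4/3)\pi abc$.

## Morphometry

* **g-ratio** — axon diameter / fiber diameter per fiber; myelin thickness
  is (fiber − axon)/2. Inputs violating axon ≤ fiber are rejected at
  construction and counted. `equivalent_diameter()` converts area
  measurements for area-based inputs.
* **Raster vessel metrics** — mirrors an AngioTool-style measurement at its
  published settings: intensity band 40–255, vessel-width band-pass 5–40 px
  (opening at the lower bound removes sub-minimum structures, the opening at
  the upper bound is subtracted to suppress super-maximum cores), components
  under the particle threshold dropped, then Zhang–Suen thinning. Parallel
  thinning leaves staircase artifacts on diagonals, so a serial pass removes
  8-simple corner pixels (Hilditch crossing number 1); without it, diagonal
  branches inflate length by ~50% and create spurious junctions. Skeleton
  length counts orthogonal steps as 1 and diagonal steps as √2 pixel
  pitches; junction zones are skeleton pixels with ≥ 3 skeleton neighbors
  merged by 8-connectivity, so a thick branch point counts once. Length is
  stable to ±5% across tube diameters for tubes much longer than wide (end
  erosion during thinning is O(radius)).
* **Connectivity conventions** — 8-connectivity in 2D and 26-connectivity in
  3D everywhere (components, particle filters, junction clustering).
* **Particle filters** — vessel volumes drop 26-connected components below
  30 µm³; object tables drop components below 800 voxels, both before
  measurement.
* **Colocalization** — 100 · |marker ∩ vessel| / |marker|: asymmetric by
  design (the denominator is the marker); an empty marker yields a flagged
  undefined result. The intensity threshold that produces the masks is
  configuration, with no claim of equivalence to any specific imaging setup.

## Group statistics

`per_animal_summary()` averages all field-of-view values per animal (plain
mean; unbalanced designs are flagged, not reweighted). `compare_groups()`
encodes the test dispatch: Welch's t for per-animal summaries, Mann–Whitney
U for ultrastructure and lesion volumes, two-way ANOVA with Holm–Šidák
step-down post hocs for core/edge counts, a Pearson chi-square comparison of
binned distributions for radial myelination profiles, Kruskal–Wallis with
Benjamini–Hochberg correction across features for analyte panels, the
one-sample t against zero for expression-versus-none readouts, and an r×c
chi-square on ordinal grades (with a Cochran–Armitage-style trend option)
for severity scores. The ordinal test rejects inputs with more than 12
distinct score values as not ordinal. The tests themselves are the vetted
`stats::` routines; Holm–Šidák
($p_{(i)}^{adj} = 1-(1-p_{(i)})^{m-i+1}$, monotonized) is implemented here.

## What the synthetic generators emulate — and what they do not

Each generator is a pure function of its parameters and a seed, and emits
ground truth (channel labels, lengths, volumes, overlap counts) so every
downstream analysis is testable without external data. One global seed
expands into fixed per-generator substreams (`substream_seed()`), so adding
a generator to a pipeline never perturbs existing streams.

* **Cohorts** (`gen_cohort_patterns()`): inhomogeneous Poisson patterns —
  uniform baseline over the ±1 mm window plus, for group B, an added
  `excess_ratio` × baseline intensity inside a radial annulus (default
  300–500 µm, default excess 1, i.e. doubled density). Defaults follow the
  emulated design: 3 animals × 3 sections per group, ~200 cells per section.
  The lesion is an axis-aligned ellipse (500 × 350 µm semi-axes) — the
  simplest shape matching an "elliptical" lesion; z is uniform in a 10 µm
  slab. Real sections have anisotropic cell distributions, reactive
  gliosis gradients and segmentation errors that this model does not
  emulate: passing tests demonstrate correctness of the computations and
  calibration of the statistics, not robustness to real-microscopy
  artifacts.
* **Vasculature** (`gen_vessel_network()`): a branching persistent random
  walk; ground-truth length and junction count are those of the generated
  graph. `gen_opc_positions()` places a fraction of cells at
  exponential-kernel distances from the centerline — a phenomenological
  attraction, not a chemotaxis model.
* **Fibers** (`gen_fiber_set()`): lognormal axon calibers; per-fiber g from
  a truncated normal in (0,1), fiber diameter = axon/g. Group calibrations
  0.80/0.88 reproduce the published control/DIO contrast.
* **Section areas** (`gen_section_areas()`): exact elliptical cross-sections
  of a known ellipsoid times lognormal noise (CV 0.1 by default).
* **Mask pairs** (`gen_voxel_masks()`): the vessel mask is a union of random
  balls; the marker mask is built by exact voxel sampling so the overlap
  fraction is hit to one-voxel rounding (it is a voxel set, not a blob —
  immaterial for voxel-count colocalization).
* **Summaries** (`gen_group_summaries()`): per-animal values drawn at
  published group means/SEMs (default 6.46 ± 0.23 vs 8.94 ± 0.31 cells/mm,
  n = 3), for power checks of the test layer.

## Problem sizes and runtime choices

The test suite and `scripts/acceptance.R` use the study-scale design
throughout: 9 vs 9 sections, 999 permutations on the 41 × 41 grid (the
weight-matrix formulation makes one map ≈ 1–2 s), 20 independent cohort
seeds for calibration and recovery checks, 100 seeds for attraction and
g-ratio detection rates, 2000 null replicates per statistical test, fiber
sets of n = 300, and component-labeling oracles on masks up to 20³ voxels.
Oracle comparisons (kNN, nearest-segment, flood fill) run at n ≤ 200 cells ×
500 segments where brute force is exact and fast.

## Known limitations

* Sensitivity of the p-value map at the emulated study scale is modest: the
  k = 8 estimator's smoothing radius at ~50 cells/mm² is ≈ 225 µm,
  comparable to the 200 µm annulus used in recovery checks, and the 1/n
  normalization slightly depresses the apparent baseline of the
  larger-count group. Recovered significance masks localize to the planted
  region (mean radius inside the annulus) but their Jaccard overlap with it
  fluctuates around 0.3–0.5 seed to seed; `analysis/02_density_map.R` and
  the acceptance script report the realized values.
* No 3D density estimation, no kernel (non-kNN) estimators, no edge
  correction.
* Vessel tracing/segmentation from fluorescence stacks is out of scope:
  vessel inputs are centerline graphs or rendered rasters.
* The raster band-pass implements the published tool settings'
  *measurement semantics*, not the tool's full pipeline; masks from real
  imaging will differ upstream of it.
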