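# opcmap

Lesion-centered spatial and morphometric quantification of
stroke-responsive oligodendrocyte progenitor cells (OPCs).

After a white-matter stroke, OPCs (PDGFRα+) proliferate around the lesion
and along the vasculature. `opcmap` is an R package plus an analysis
workflow for quantifying that response from microscopy-derived data:

* **kNN density maps and permutation p-value maps** — at each node of a
  lesion-centered grid, local density is estimated as
  f̂(x) = k / (n·π·d_k(x)²) with smoothing parameter k = 8 (d_k = distance
  to the k-th nearest cell, n = cells in the section). Two cohorts of
  section patterns are compared position-wise by permuting section-level
  group labels: Δ(x) = mean_B − mean_A, two-sided
  p(x) = (1 + #{|Δ*| ≥ |Δ|}) / (B+1), thresholded at p < 0.05 to delimit
  regions of significant density difference.
* **OPC–vessel proximity** — exact point-to-segment nearest distances to a
  vessel centerline network, 0–35 µm distance distributions, and
  vessel-associated cells per mm of vessel length.
* **Lesion-volume bootstrap** — from 3–5 measured section areas per animal,
  resample 25 sections × 40 µm (the ~1 mm lesion span) with replacement;
  per-animal volume distributions, compared across groups by Mann-Whitney U.
* **Morphometry** — EM g-ratio (axon/fiber diameter) statistics; skeleton
  length and junction counts of rastered vessel networks at the published
  filter settings (intensity 40–255, width band 5–40 px, particle filters);
  3D vessel volume with a 30 µm³ particle filter; voxel colocalization
  percentages; 800-voxel-filtered object size tables; radial intensity
  profiles.
* **Group statistics** — per-animal averaging of field-of-view records and
  the study's named tests (Welch's t, Mann-Whitney U, two-way ANOVA with
  Holm-Šidák post hocs, chi-square distribution comparison, Kruskal-Wallis
  with FDR, one-sample t, ordinal shift chi-square).
* **Synthetic data** — seeded generators for every input (cohorts with a
  planted peri-infarct density excess, branching vessel networks with
  vessel-attracted cells, fiber sets with set mean g-ratio, ellipsoid
  section areas, mask pairs with exact overlap), each emitting ground truth.

See `vignettes/opc-lesion-mapping.Rmd` for the models, parameter choices
and limitations.

## Worked example

```r
library(opcmap)

# a 3 animals x 3 sections cohort per group with doubled OPC density in the
# 300-500 um peri-infarct annulus of group B
coh <- gen_cohort_patterns(cohort_spec(excess_ratio = 1, seed = 2))
is_B <- sapply(coh$patterns, function(p) p$group == "B")

pv <- density_pvalue_map(coh$patterns[!is_B], coh$patterns[is_B],
                         grid_spec(), k = 8, B_perm = 999, seed = 2)
pv
#> pvalue_map: 1681 nodes, 999 permutations (sampled, unit=section), 166 nodes B>A and 63 nodes A>B at p<0.05
significant_region_area(pv, direction = "B>A")$area_um2
#> [1] 415000
mask_annulus_jaccard(pv, c(300, 500))$jaccard
#> [1] 0.4166667
```

166 grid nodes (0.415 mm²) show significantly more OPCs in group B; they
overlap the planted annulus with Jaccard 0.42, i.e. the map recovers the
planted peri-infarct excess where it was planted. The `A>B` nodes lie
outside the annulus: the 1/n normalization makes the larger-count group's
baseline proportionally lower there (see the vignette).

The numbered scripts run the full workflow and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # all synthetic inputs + ground truth
Rscript analysis/02_density_map.R     # null + excess cohort p-value maps
Rscript analysis/03_vessel_proximity.R
Rscript analysis/04_morphometry.R     # g-ratio, skeleton metrics, coloc
Rscript analysis/05_lesion_volume.R
Rscript analysis/06_group_stats.R
```

`analysis/04_morphometry.R`, for example, prints:

```
g-ratio: control 0.801 +/- 0.002, DIO 0.882 +/- 0.002 (n=300 each)
colocalization: 50.0% of marker voxels inside vessels
vessel volume after 30 um^3 particle filter: 2124 um^3
rendered network: skeleton 392 um, 2 junctions
```

— the generator calibrations (g-ratio 0.80 vs 0.88, 50% overlap) recovered
by the measurement code.

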