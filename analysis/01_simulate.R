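#!/usr/bin/env Rscript
# Generate every synthetic input of the workflow with known ground truth:
# the two-group point-pattern cohort around the elliptical lesion, a vessel
# network with vessel-attracted OPCs, EM fiber sets, serial-section lesion
# areas and the colocalization mask pair. All downstream scripts re-derive
# what they need from the same seed, so this script's artifacts are for
# inspection and external reuse.

library(opcmap)

cfg <- default_config()
sim <- run_stage("simulate", cfg, outdir = "results")

cat("cohort:", length(sim$cohort$patterns), "sections,",
    "baseline intensity", signif(sim$cohort$ground_truth$baseline_intensity_per_um2, 3),
    "cells/um^2\n")
cat("vessels:", nrow(sim$vessels$segments), "segments,",
    round(sim$vessels$total_length_um), "um,",
    sim$vessels$junction_count, "junctions\n")
cat("fibers: target g 0.80 / 0.88; sections:", length(sim$areas$areas_um2),
    "areas; masks:", sum(sim$masks$vessel$mask), "vessel voxels\n")
cat("artifacts under results/\n")
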