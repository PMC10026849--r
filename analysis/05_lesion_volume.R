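#!/usr/bin/env Rscript
# Bootstrap lesion-volume estimation: resample 25 sections (40 um each, the
# 1 mm lesion span) from each animal's sparse observed areas and compare the
# bootstrap mean against the generating ellipsoid's analytic volume.

library(opcmap)

cfg <- default_config()
boot <- run_stage("bootstrap-volume", cfg, outdir = "results")
sa <- gen_section_areas(seed = substream_seed(cfg$seed, "areas"))
truth <- attr(sa, "ground_truth")$true_volume_um3
cat(sprintf("bootstrap mean volume %.3f mm^3 (true ellipsoid %.3f mm^3)\n",
            boot$mean_volume_um3 / 1e9, truth / 1e9))
cat(sprintf("95%% CI: [%.3f, %.3f] mm^3\n",
            boot$ci_um3[1] / 1e9, boot$ci_um3[2] / 1e9))
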