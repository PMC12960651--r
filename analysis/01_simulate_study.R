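#!/usr/bin/env Rscript
# Generate the synthetic study all downstream analyses consume: a
# 27-accession panel (subgroups 3/3/21) on an 11 x 1.8 Mb genome with
# ~2,020 genes, 20,000 Balding-Nichols SNPs (F = 0.15 between the 13/14
# trait groups), an XP-CLR-style score track with 8 planted peaks, and
# ~2,000 deletion-dominated SVs with 10 planted hotspot clusters.
# The planted truth is written alongside so later steps can score
# themselves against it.

library(pangenpop)

out_dir <- "results/simdata"
cfg <- sim_config(seed = 1)
st <- simulate_study(cfg, out_dir = out_dir)

cat("Synthetic study written to", out_dir, "\n")
print(cfg)
cat("Planted truth:", length(st$truth$differential_ids),
    "differential genes,", nrow(st$truth$sweep_peaks), "sweep peaks,",
    nrow(st$truth$hotspot_clusters), "hotspot clusters\n")
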