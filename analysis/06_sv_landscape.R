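#!/usr/bin/env Rscript
# Structural-variant landscape: filtering (length > 50 bp, <= 50% missing,
# MAF >= 1%), per-type and per-sample tallies, genomic-context annotation
# (genic > 2 kb flank > intergenic), and 200 kb / 100 kb hotspot detection
# scored against the planted clusters.

library(pangenpop)

sim <- "results/simdata"
if (!dir.exists(sim)) stop("run analysis/01_simulate_study.R first")

truth <- jsonlite::fromJSON(file.path(sim, "truth.json"))
layout <- simulate_layout(sim_config(seed = truth$seed))
sv <- read_sv_vcf(file.path(sim, "svs.vcf"), min_length = 50,
                  max_missing_fraction = 0.5, min_maf = 0.01)
genes <- read_gene_models(file.path(sim, "genes.gff3"))

ss <- sv_summary(sv)
cat(sprintf("SVs after filtering: %d (%d DEL, %d DUP, %d INS)\n",
            ss$total, ss$type_totals[["DEL"]], ss$type_totals[["DUP"]],
            ss$type_totals[["INS"]]))
cat(sprintf("Per-sample SV count: %d-%d; deletion fraction %.1f-%.1f%%\n",
            min(ss$per_sample$count), max(ss$per_sample$count),
            100 * min(ss$per_sample$del_fraction),
            100 * max(ss$per_sample$del_fraction)))
write.table(ss$per_sample, "results/sv_per_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ctx <- annotate_context(sv, genes, flank_bp = 2000)
write.table(ctx, "results/sv_context.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Genomic context by type (column fractions):\n")
print(round(prop.table(table(ctx$context, ctx$type), margin = 2), 3))

hs <- hotspot_scan(sv, layout, window_bp = 200000, step_bp = 100000,
                   top_fraction = 0.05)
write_regions_bed(data.frame(hs$regions[c("chrom", "start", "end")],
                             name = paste0("hotspot_",
                                           seq_len(nrow(hs$regions))),
                             score = hs$regions$n_breakpoints),
                  "results/sv_hotspots.bed")
cat(sprintf(
  "Hotspots: %d regions covering %.1f%% of the genome, capturing %.1f%% of SVs\n",
  nrow(hs$regions), 100 * hs$genome_fraction, 100 * hs$capture_fraction))
clusters_hit <- sum(vapply(seq_len(nrow(truth$hotspot_clusters)),
                           function(i) {
  cl <- truth$hotspot_clusters[i, ]
  any(hs$regions$chrom == cl$chrom & hs$regions$start < cl$end &
        cl$start < hs$regions$end)
}, TRUE))
cat(sprintf("Planted clusters intersected: %d / %d\n", clusters_hit,
            nrow(truth$hotspot_clusters)))
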