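#!/usr/bin/env Rscript
# Selective-sweep post-processing of the XP-CLR score track: 10 kb window
# means, top-5% signal calling with the single-gap top-10% merge rule,
# candidate genes within +/-2 kb of each region, and the FST profile over
# each candidate gene, scored against the planted peaks.

library(pangenpop)

sim <- "results/simdata"
if (!dir.exists(sim)) stop("run analysis/01_simulate_study.R first")

layout <- {
  truth <- jsonlite::fromJSON(file.path(sim, "truth.json"))
  cfg <- sim_config(seed = truth$seed)
  simulate_layout(cfg)
}
track <- read_score_track(file.path(sim, "xpclr.tsv"))
genes <- read_gene_models(file.path(sim, "genes.gff3"))
design <- read_design(file.path(sim, "design.tsv"))
snp <- read_snp_vcf(file.path(sim, "snps.vcf"))
truth <- jsonlite::fromJSON(file.path(sim, "truth.json"))

w <- window_scores(track, layout, window_bp = 10000)
regions <- call_and_merge(w, top_signal_fraction = 0.05,
                          gap_fraction = 0.10)
write_regions_bed(data.frame(regions, name = paste0("sweep_",
                                                    seq_len(nrow(regions)))),
                  "results/sweep_regions.bed")
cat(sprintf("Sweep regions: %d, spanning %.2f Mb (max region score %.1f)\n",
            nrow(regions), sum(regions$end - regions$start) / 1e6,
            max(regions$score)))

hits <- sum(vapply(seq_len(nrow(truth$sweep_peaks)), function(i) {
  p <- truth$sweep_peaks[i, ]
  any(regions$chrom == p$chrom & regions$start < p$end &
        p$start < regions$end)
}, TRUE))
cat(sprintf("Planted peaks intersected: %d / %d\n", hits,
            nrow(truth$sweep_peaks)))

assign <- genes_in_regions(regions, genes, flank_bp = 2000)
write.table(assign, "results/sweep_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Candidate genes in regions (+/-2 kb): %d\n",
            length(unique(assign$gene_id))))

# FST profile over the first candidate gene
if (nrow(assign) > 0) {
  g <- genes[genes$gene_id == assign$gene_id[1], ]
  prof <- gene_flank_fst(snp, design, "trait_a", "trait_b", g,
                         flank_bp = 2000)
  cat(sprintf("FST over %s +/-2 kb: mean %.3f, weighted %.3f (%d sites)\n",
              g$gene_id, prof$mean_fst, prof$weighted_fst, prof$n_sites))
}
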