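# pangenpop

Population analysis of a plant pan-genome from standard variant and
annotation formats. The package implements the analysis layer used in
pan-genome resequencing studies of perennial fruit crops — a panel of
accessions mapped against a pan-genome reference, from which gene
presence/absence, selective sweeps, and structural-variant (SV)
differentiation are read out — and ships a seeded synthetic-study
generator with planted ground truth so the whole pipeline can be
exercised and validated without any external data.

It is aimed at population-genomics practitioners who have already run
the upstream heavy machinery (alignment, variant calling, XP-CLR
scoring) and need the downstream statistics, screens, and window
arithmetic to be correct, reproducible and testable.

## What it computes

**Gene presence/absence (PAV).** A gene is *present* in an accession
when reads at depth ≥ minCov cover **more than** a cutoff fraction
(lostCutoff = 0.2 by default) of its exon bases; the package consumes
the per-gene per-sample covered fraction. With *n* accessions, genes
present in all *n* are **core**, in exactly one **private**, and in
2..*n*−1 **dispensable** — a disjoint partition. Pan/core saturation
curves over random accession orderings are fitted with the conventional
power law *P(k) = A·k^γ + C* and exponential decay
*F(k) = A·e^(−k/τ) + C*.

**Gene-frequency selection screen.** Per gene, a two-sided Fisher exact
test on the 2×2 presence table between two trait groups,
Benjamini–Hochberg FDR across testable genes, and a Haldane–Anscombe
log2 fold change `log2((a+0.5)/(nA+1)) − log2((b+0.5)/(nB+1))`;
significance requires FDR < 0.001 **and** |log2FC| > 1. Hypergeometric
term enrichment runs on user-supplied annotation tables.

**Population structure.** PCA of the gene-centered binary PAV matrix
(samples as observations) and an average-linkage tree on Jaccard
distances between presence sets, exported as Newick.

**Selective sweeps.** Per-site XP-CLR scores are averaged in
non-overlapping 10 kb windows; windows in the top 5% genome-wide are
strong signals; adjacent signal windows, or signal windows separated by
a single window whose score is in the top 10%, are merged, and the
merged region carries the **maximum** member window mean. Candidate
genes are those whose span ±2 kb intersects a region.

**FST / Pi differentiation.** The two-population Weir–Cockerham (1984)
variance-components estimator, per site and in 100 kb windows (both the
arithmetic mean of per-site estimates and the ratio-of-sums weighted
estimate Σa/Σ(a+b+c) are reported). Windows are banded: FST < 0.05
minimal, 0.05–0.15 moderate, ≥ 0.15 significant differentiation. Pi per
group is Σ 2p̂(1−p̂)·2n/(2n−1) over window sites divided by window
length. SVs run through the identical estimator path as SNPs, enabling
the SNP-vs-SV comparison of differentiated windows and genes.

**SV landscape.** Filtering (length strictly > 50 bp, ≤ 50% missing,
MAF ≥ 1%), per-type/per-sample tallies, genomic-context annotation with
precedence genic > 2 kb flank > intergenic, and hotspot detection:
breakpoint counts in 200 kb windows sliding by 100 kb, top 5% of
windows (ties included) merged into hotspot regions, with capture and
genome-fraction statistics.

**Assay calculators.** Relative electrolyte conductivity
REC = R1/R2 × 100%, malondialdehyde content
MDA = 25.58 × (ΔA + 0.0076)/W with ΔA = A532 − A600, and the 2^−ΔΔCt
relative-expression method.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic
27-accession study (subgroups 3/3/21, 11 chromosomes, ~2,020 genes,
20,000 SNPs at Balding–Nichols F = 0.15 between 13/14 trait groups,
~2,000 deletion-dominated SVs):

```sh
Rscript analysis/01_simulate_study.R    # inputs + planted truth
Rscript analysis/02_pav_pangenome.R
Rscript analysis/05_sweeps.R
Rscript analysis/06_sv_landscape.R
```

which prints, for seed 1:

```
Classified 1960 genes: 1611 core, 298 dispensable, 51 private
Genes per accession: 1747-1793 (core fraction 90-92%)
Pan curve: 1766 (k=1) -> 1960 (k=27); power-law gamma = 0.005
Sweep regions: 8, spanning 1.04 Mb (max region score 20.7)
Planted peaks intersected: 8 / 8
Hotspots: 10 regions covering 10.1% of the genome, capturing 87.2% of SVs
Planted clusters intersected: 10 / 10
```

Category counts always sum to the number of genes present in at least
one accession; every planted sweep peak intersects a reported region
with no false regions; and the ten planted hotspot clusters, holding
85% of SV breakpoints, are all recovered by the top-5% window scan.
`analysis/07_differentiation.R` recovers the simulated F:
`Genome-wide weighted FST (SNPs): 0.1479 (simulated F = 0.15)`.

Equivalent calls in R:

```r
library(pangenpop)
pav <- classify_genes(call_presence(read_coverage("coverage.tsv")))
category_counts(pav)
res <- fisher_presence_test(pav, read_design("design.tsv"),
                            "trait_a", "trait_b")
```

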