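---
title: "Pan-genome population analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome population analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangenpop)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters
with their defaults and units, the numerical conventions, what the
synthetic-data generator emulates (and what it deliberately does not),
and the design choices made where more than one defensible reading
existed.

## Coordinate and genotype conventions

All internal coordinates are **0-based, half-open**; the 1-based
conventions of VCF and GFF3 are converted at the reader boundary, once.
This makes window arithmetic unambiguous: a site at exactly a window
boundary belongs to the *next* window, an interval that merely touches
another does not intersect it. Genotypes are stored as alt-allele
dosages 0/1/2; a half-missing call such as `./1` is treated as missing.
Minor-allele frequencies are computed from non-missing calls only,
matching common VCF-tool semantics.

One filter threshold deserves a note: the SNP-filtering protocol this
package mirrors prints a VCFtools `--maf 0.5` while its prose describes
removing sites with MAF below 5%. A MAF threshold of 0.5 would discard
nearly every site, so the reader defaults to `min_maf = 0.05`; the
parameter is exposed and can be set to any value, including 0.5.

## Gene presence/absence

A gene is called **present** in an accession when the fraction of its
exon bases covered at or above a minimum read depth (minCov, typically
2 reads) strictly exceeds `lost_cutoff` (default 0.2). The strict
inequality follows the rule's phrasing — "more than 20% of its exon
regions" — so a covered fraction of exactly 0.2 is absent; presence is
monotone in coverage by construction. The package consumes the covered
fraction per gene and sample directly; computing it from alignments is
upstream of this package's scope, which keeps the tested surface
format-simple.

Classification with *n* accessions: occurrence *n* is **core**,
occurrence 1 is **private**, occurrences 2..*n*−1 are **dispensable**.
Descriptions of this scheme sometimes give "dispensable" as the range
1..*n*−1, which would overlap "private"; the categories here are
disjoint, which is the only reading under which the three counts sum to
the classified total. Genes absent from every sample cannot arise from
real calling and are dropped with a message (they can arise in
synthetic edge cases).

## Saturation curves and their fitted forms

For each random ordering of the accessions, the pan curve is the
cumulative union size and the core curve the cumulative intersection
size of the presence sets; 100 permutations by default, under a
mandatory seed. Per permutation the pan curve is non-decreasing, the
core curve non-increasing, and both curves coincide at *k* = 1.

The fitted forms follow pan-genome convention, since no functional form
is canonical: power law $P(k) = A k^{\gamma} + C$ for the pan curve
(the openness regime: $\gamma > 0$ open, $\gamma \approx 0$ closed) and
exponential decay $F(k) = A e^{-k/\tau} + C$ for the core curve, fitted
with Levenberg–Marquardt least squares. A numerically constant curve is
reported directly ($A = 0$) rather than fitted, and non-convergence is
reported with diagnostics rather than raised. The power law describes
*unsaturated* pan curves well; on a panel whose pan curve has already
plateaued the endpoint fit degrades (several percent at high occupancy
in our fixtures), which is a limitation of the conventional form, not
of the fitting.

## The gene-frequency screen

Each gene's presence counts in two trait groups form a 2×2 table
`[[a, nA−a], [b, nB−b]]`, tested with a **two-sided Fisher exact
test**. Two-sided conventions for Fisher's test differ between
implementations; this package sums the probabilities of all tables (at
fixed margins) whose hypergeometric probability does not exceed the
observed table's, with a `1 + 1e-7` relative tie guard — the convention
of `stats::fisher.test`, reimplemented vectorized and cross-checked in
the tests against both `fisher.test` and a literal enumeration.

Benjamini–Hochberg adjustment runs across *testable* genes only. Genes
fixed present or fixed absent in every contrasted sample carry no
frequency information; they are reported with p = 1 and `fdr = NA` and
logged. The log2 fold change uses the Haldane–Anscombe correction,
`log2((a+0.5)/(nA+1)) − log2((b+0.5)/(nB+1))`, so zero-presence groups
yield finite values; no correction rule is canonical here and the
choice is documented rather than hidden. The significance gate is
`fdr < 0.001` **and** `|log2FC| > 1`.

Fisher's exact test is conservative for small groups: with groups of
13 and 14 accessions, the exact null rejection rate at nominal
$\alpha = 0.05$ is only ≈ 0.026 (computed by full enumeration over the
table distribution). The package's null-calibration simulation
(`simulate_null_pav`) therefore uses two groups of 50 and 51 samples
with per-gene presence probabilities drawn from U(0.3, 0.7): exact
enumeration over that design gives an attained level of ≈ 0.042,
i.e. close to nominal, so the calibration check measures the
implementation rather than the test's small-sample discreteness. The
odd total matters — 50 v 50 attains only ≈ 0.032–0.035 because of how
ties fall in the symmetric case — and the group sizes were fixed from
that exact computation. Enrichment of a hit list on a user-supplied
gene–term table is an upper-tail hypergeometric test with BH
adjustment; the background defaults to the full gene universe of the
table and is typically set to all genes of the PAV matrix.

## Population structure from the PAV matrix

PCA treats samples as observations and genes as features, centering by
gene and not scaling — the standard treatment for binary PAV data,
where scaling would up-weight near-fixed genes. Component signs are
fixed (largest-magnitude loading positive) so results are reproducible.
The tree is average-linkage agglomerative clustering on **Jaccard
distances** between presence sets, exported as Newick. This stands in
for maximum-likelihood inference on binary characters, which needs a
dedicated phylogenetic engine; for cluster structure (the use made of
it here) the distance tree carries the same signal. Two samples with
empty presence sets get distance 0 by convention, with a warning.

## Selective-sweep post-processing

The XP-CLR statistic itself is consumed as a per-site score track — any
per-site sweep score works. Windows of 10 kb tile each chromosome from
0; a window's score is the mean over its sites; windows with no sites
are excluded from ranking. "Top 5%" is operationalized as score ≥ the
value at descending rank ⌈0.05 · #ranked windows⌉, **ties included**,
so equal-scored windows are never split by an arbitrary cut; the same
rule at 10% defines bridge eligibility. Chromosome-terminal partial
windows are ranked (their means are valid) and flagged.

The merge rule: signal (top-5%) windows that are adjacent merge;
signal windows separated by exactly one window merge **iff that gap
window's score is in the top 10%**. The alternative reading — that the
top-10% condition binds the merged windows rather than the gap — is
vacuous, since merged windows are already top-5%; hence the gap-window
reading. A gap window with no sites is unranked and never bridges. The
merged region carries the maximum member window mean, so a region's
score never understates its strongest window. Merging is idempotent,
and the implementation is tested for exact equality against a literal
connected-components enumeration of the rule on thousands of random
window vectors. Genes map to regions when their span ±2 kb (half-open)
intersects the region; a gene may map to several regions.

## Weir–Cockerham FST and Pi

The two-population Weir & Cockerham (1984) variance components are
computed from per-group non-missing sample size, allele frequency and
observed heterozygote fraction:

$$ a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{s^2}{2} - \frac{\bar h}{4}\right)\right] $$

with the standard $b$ and $c$ components, per-site estimate
$a/(a+b+c)$, and genome-wide weighted estimate
$\sum a / \sum (a+b+c)$. Per-site estimates may be negative and are
**retained** in window means (the behavior of the common command-line
implementation); clamping at 0 is available by flag. Sites monomorphic
across both groups (zero total variance) or with fewer than two
non-missing calls in either group are skipped with a recorded reason.

Windows of 100 kb report both the arithmetic mean of per-site estimates
and the weighted estimate; the differentiation **bands** — below 0.05
minimal, 0.05 to 0.15 moderate, at or above 0.15 significant — apply to
the arithmetic mean, which is what "average FST per window" denotes;
the weighted estimate is always reported alongside because the two can
differ materially and the banding convention does not specify one.
Per-group Pi sums the unbiased per-site heterozygosity
$2\hat p(1-\hat p)\cdot 2n/(2n-1)$ over a window's sites and divides by
the **window length in bp** (not the site count), so windows with no
polymorphic sites have Pi = 0 rather than undefined.

SVs are treated as biallelic markers located at their start breakpoint
and run through the *same* estimator code path as SNPs — asserted by a
property test on identical genotype input — which is what makes the
SNP-vs-SV comparison of significant windows and their gene content an
apples-to-apples contrast. Analyses are two-group by design; the
workflows this package serves contrast exactly two phenotype groups per
run.

## SV landscape

Filters: length strictly greater than 50 bp ("exceeding" — a 50 bp
variant is removed), missing-call fraction ≤ 0.5, MAF ≥ 0.01. For
DEL/DUP the length comes from `abs(SVLEN)` when present, else
`END − POS`; INS length comes from `SVLEN` only, and an INS occupies
the single insertion point. Context annotation is exclusive with
precedence genic > 2 kb flank > intergenic.

Hotspots: breakpoints are the two interval endpoints of a DEL/DUP (an
SV spanning two windows contributes to both) and the single point of an
INS — "breakpoint frequency" is read as a per-window breakpoint count,
the standard reading of sliding-window SV density. Windows of 200 kb
slide by 100 kb, so interior breakpoints are counted twice across the
tiling; windows are ranked by count, the top 5% (ties included) are
hotspot windows, and overlapping or abutting hotspot windows merge into
maximal regions. A window with zero breakpoints is never a hotspot even
when a sparse genome pushes the percentile cut to zero. Each captured
SV is assigned to exactly one region (that of its leftmost captured
breakpoint), so capture lists partition the captured set; capture
fraction and genome fraction summarize the scan.

## The synthetic study generator

`sim_config()` defaults define the study conditions the package is
validated under, chosen once to emulate a 27-accession fruit-tree
resequencing panel at desk scale: subgroups of 3/3/21 accessions; 11
chromosomes of 1.8 Mb (a ~20 Mb toy genome, so every stage runs in
seconds); ~2,020 genes of which ~76% core, ~23% dispensable with a
U-shaped Beta(0.3, 0.3) frequency law and subgroup-divergent frequencies
(Balding–Nichols-style divergence 0.3), ~1% private, plus 20 planted
differential genes at presence probabilities 0.95 vs 0.05 between two
trait groups of 13 and 14; coverage fractions Beta(18, 2) for present
genes (floored at 0.25 to keep the truth consistent with the presence
rule) and uniform residuals below 0.1 for absent genes, with
`residual_max = 0` giving the noise-free limit; 20,000 SNPs under the
Balding–Nichols model (per-group frequency Beta(p(1−F)/F,
(1−p)(1−F)/F), diploid genotypes Binomial(2, freq), ancestral
frequencies U(0.1, 0.9)) at F = 0.15, whose expected Weir–Cockerham FST
is ≈ F; an Exponential(1) score background with 8 planted peaks of 130
kb elevated 10× (130 kb × 8 ≈ the top-5% window budget of a 20 Mb
genome, so the percentile cut falls inside the peaks); and ~2,000 SVs
mixed ≈ 77.5% DEL / 22.4% DUP / 0.15% INS with log-normal lengths
(median 500 bp, truncated at 51), of which 85% of breakpoints fall in
10 planted hotspot clusters.

Two generator choices warrant emphasis. First, hotspot clusters are
**centred on the scan's step grid** (width = one step, well separated,
away from chromosome ends), so each planted cluster corresponds to
exactly one fully-containing scan window and the planted truth is
unambiguous — with ~200 windows the top-5% budget is ~10 windows,
exactly the cluster count, and off-grid clusters that split their
counts across two windows would make "recovered the planted cluster"
ill-defined. Real hotspots are of course not grid-aligned; the
recovery bands measured here say the scan finds well-separated dense
clusters, not that it resolves overlapping or straddling ones. Second,
the planted-subgroup recovery property (k-means on the first two PCs
reproducing the partition exactly) is asserted under **balanced**
subgroups, where it holds essentially always at the default divergence;
under the study-like 3/3/21 design the two small subgroups separate
cleanly from the main group on the leading PCs, but k-means' objective
often splits the large diffuse group instead of separating the two
small tight ones — a property of k-means with very unequal cluster
sizes, not of the ordination — so exact label recovery is not asserted
there.

What the generator does **not** emulate: linkage disequilibrium or
coalescent structure (loci are unlinked), read-level noise (coverage
fractions are drawn directly, not from alignments), gene-length or GC
effects on coverage, overlapping genes, multi-allelic variation, and
SV genotyping error. Passing tests therefore demonstrate correctness of
the statistics and rules on data with the stated marginal structure;
they do not demonstrate robustness to alignment artifacts or LD, which
only real data can.

## Problem sizes and runtimes

The shipped test suite and acceptance script use the desk-scale sizes
above: 5,000-locus FST replicates, 1,000 random 200-window vectors for
the merge-rule oracle, exhaustive Fisher enumeration to group sizes of
30, and 20-seed recovery runs for hotspots and null calibration. The
full suite runs in about a minute on one CPU; the acceptance script in
a few seconds. These sizes were chosen so the complete validation is
cheap to re-run whenever any rule is touched.

## Known limitations

- Saturation fits use the conventional closed forms; strongly saturated
  pan curves are fitted with visible endpoint bias (inspect the
  reported residuals).
- The distance tree is not a maximum-likelihood phylogeny and carries
  no support values.
- FST is the two-population estimator; hierarchical or multi-population
  designs are out of scope, as are kinship correction and LD pruning.
- The Fisher screen treats accessions as independent; population
  structure inside a trait group can inflate apparent frequency
  differences (on real panels, inspect the PAV ordination first).
- Enrichment requires a user-supplied term table; no ontology topology
  is used.
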