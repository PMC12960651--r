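Package: pangenpop
Title: Pan-Genome Presence/Absence and Population Differentiation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population analysis of a fruit-tree pan-genome from standard
    variant and annotation formats. Calls gene presence/absence (PAV) from
    exon-coverage fractions and classifies genes as core, dispensable or
    private; computes pan/core saturation curves with model fits; screens
    gene frequencies between trait groups with Fisher's exact test and
    Benjamini-Hochberg control; ordinates and clusters accessions from the
    binary PAV matrix; post-processes per-site XP-CLR score tracks into
    merged selective-sweep regions; estimates Weir-Cockerham FST and
    nucleotide diversity in sliding windows for both SNPs and structural
    variants; detects structural-variant hotspots by windowed breakpoint
    density; and provides the closed-form electrolyte-leakage, MDA and
    2^-ddCt assay calculators. A seeded synthetic-study generator with
    planted ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    GenomeInfoDb,
    jsonlite,
    minpack.lm,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
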