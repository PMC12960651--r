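# Small fixtures built in code at test time.

`%||%` <- function(x, y) if (is.null(x)) y else x

# hand-written 10-sample SNP VCF: 5 records, of which one tri-allelic,
# one missing-heavy and one monomorphic; expected retention worked out by
# hand in test-io-filters.R
write_toy_snp_vcf <- function(path) {
  samples <- paste0("s", 1:10)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gts <- function(...) paste(c(...), collapse = "\t")
  body <- c(
    # site 1: clean biallelic, MAF 0.3 -> kept
    paste("chr1", 100, "r1", "A", "G", ".", "PASS", ".", "GT",
          gts("0/0", "0/1", "0/1", "0/0", "0/1", "0/1", "0/1", "0/1",
              "0/0", "0/0"), sep = "\t"),
    # site 2: tri-allelic -> dropped
    paste("chr1", 200, "r2", "A", "G,T", ".", "PASS", ".", "GT",
          gts(rep("0/1", 10)), sep = "\t"),
    # site 3: 40% missing -> dropped at max_missing 0.7
    paste("chr1", 300, "r3", "C", "T", ".", "PASS", ".", "GT",
          gts("./.", "./.", "./.", "./.", "0/1", "0/1", "0/1", "1/1",
              "0/0", "0/1"), sep = "\t"),
    # site 4: singleton het -> MAF 1/20 = 0.05, exactly at cutoff -> kept
    paste("chr1", 400, "r4", "G", "A", ".", "PASS", ".", "GT",
          gts("0/1", rep("0/0", 9)), sep = "\t"),
    # site 5: monomorphic (MAF 0; one half-missing call, which must count
    # as missing) -> dropped for any min_maf > 0
    paste("chr1", 500, "r5", "T", "C", ".", "PASS", ".", "GT",
          gts("0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0",
              "0/0", "./0"), sep = "\t")
  )
  writeLines(c(hdr, body), path)
  path
}

# hand-written SV VCF: 6 records exercising the length/missingness/MAF
# filters; hand-count in test-io-filters.R
write_toy_sv_vcf <- function(path) {
  samples <- paste0("s", 1:10)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  common <- paste(rep("0/1", 5), collapse = "\t")
  rest <- paste(rep("0/0", 5), collapse = "\t")
  carried <- paste(common, rest, sep = "\t")  # MAF 0.25, no missing
  gts60miss <- paste(c(rep("./.", 6), "0/1", "0/1", "0/0", "0/0"),
                     collapse = "\t")
  gts_mono <- paste(rep("0/0", 10), collapse = "\t")  # MAF 0 < 0.01
  body <- c(
    # lengths via END - POS: 20, 50 (boundary, dropped), 51, 300, 300, 300
    paste("chr1", 1001, "del20", "N", "<DEL>",
          ".", "PASS", "SVTYPE=DEL;END=1021", "GT", carried, sep = "\t"),
    paste("chr1", 2001, "del50", "N", "<DEL>",
          ".", "PASS", "SVTYPE=DEL;END=2051", "GT", carried, sep = "\t"),
    paste("chr1", 3001, "del51", "N", "<DEL>",
          ".", "PASS", "SVTYPE=DEL;END=3052", "GT", carried, sep = "\t"),
    paste("chr1", 4001, "dup300", "N", "<DUP>",
          ".", "PASS", "SVTYPE=DUP;END=4301;SVLEN=300", "GT", carried,
          sep = "\t"),
    paste("chr1", 5001, "del_miss", "N", "<DEL>",
          ".", "PASS", "SVTYPE=DEL;END=5301", "GT", gts60miss, sep = "\t"),
    paste("chr1", 6001, "dup_mono", "N", "<DUP>",
          ".", "PASS", "SVTYPE=DUP;END=6301", "GT", gts_mono, sep = "\t")
  )
  writeLines(c(hdr, body), path)
  path
}

# random PAV fixture with known dimensions
random_pav <- function(n_genes, n_samples, p = 0.5, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_genes * n_samples, 1, p), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  as_pav_matrix(m)
}

# stat_windows data frame built directly (single chromosome, full tiling)
make_windows <- function(scores, window_bp = 10000, chrom = "chr1",
                         keep = NULL) {
  n <- length(scores)
  w <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * window_bp,
                  end = seq_len(n) * window_bp, n_sites = 10L,
                  mean_score = scores, terminal = FALSE,
                  stringsAsFactors = FALSE)
  if (!is.null(keep)) w <- w[keep, , drop = FALSE]
  w$percentile <- rank(w$mean_score, ties.method = "max") / nrow(w)
  rownames(w) <- NULL
  structure(w, class = c("stat_windows", "data.frame"),
            window_bp = window_bp)
}

# sv_set built directly from a record table and optional genotype matrix
make_sv_set <- function(type, chrom, start, length, samples = 4,
                        geno = NULL) {
  n <- base::length(type)
  end <- ifelse(type == "INS", start, start + length)
  records <- data.frame(
    sv_id = sprintf("sv%03d", seq_len(n)), type = type, chrom = chrom,
    start = start, end = end, length = length, stringsAsFactors = FALSE
  )
  if (is.null(geno)) {
    geno <- matrix(1L, n, samples,
                   dimnames = list(NULL, paste0("s", seq_len(samples))))
  }
  ord <- order(records$chrom, records$start)
  pangenpop:::new_sv_set(records[ord, ], geno[ord, , drop = FALSE])
}
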