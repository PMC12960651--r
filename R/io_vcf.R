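# VCF readers/writers for the SNP and SV dialects the pipeline consumes.
# Genotypes are stored as alt-allele dosage (0/1/2) with NA for missing;
# half-missing calls (e.g. "./1") count as missing. Internal coordinates are
# 0-based half-open; the 1-based VCF convention is converted at this boundary.

# dosage matrix (sites x samples) from a vcfR GT matrix of "a/b" strings
.gt_to_dosage <- function(gt) {
  al1 <- substr(gt, 1L, 1L)
  al2 <- substr(gt, 3L, 3L)
  d <- (al1 == "1") + (al2 == "1")
  d[al1 == "." | al2 == "." | is.na(gt) | gt == "."] <- NA_integer_
  matrix(as.integer(d), nrow = nrow(gt), dimnames = dimnames(gt))
}

.missing_fraction <- function(geno) rowMeans(is.na(geno))

# minor-allele frequency from non-missing diploid dosages
.maf <- function(geno) {
  p <- rowMeans(geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  pmin(p, 1 - p)
}

#' Read and filter a population SNP VCF
#'
#' Reads a VCF of diploid genotypes, keeps only biallelic SNPs, and applies
#' the per-site missingness and minor-allele-frequency filters. Missingness
#' is expressed as the *kept* fraction, matching the VCFtools
#' `--max-missing` convention: a site is retained when the fraction of
#' non-missing calls is at least `max_missing_keep_fraction`.
#'
#' Note on the MAF default: the source protocol's printed VCFtools call reads
#' `--maf 0.5` while its prose describes removing sites with MAF < 5%; this
#' reader defaults to `min_maf = 0.05` and the threshold is always
#' user-overridable.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param max_missing_keep_fraction Minimum fraction of non-missing calls a
#'   site must have to be retained (default 0.7, i.e. drop sites with >30%
#'   missing data).
#' @param min_maf Minimum minor-allele frequency, computed from non-missing
#'   calls only (default 0.05). Monomorphic sites are removed for any
#'   `min_maf > 0`.
#' @return A `snp_matrix`: list with `sites` (data frame `chrom`, `pos`
#'   0-based, `ref`, `alt`), `geno` (integer dosage matrix, sites x samples),
#'   and `samples`.
#' @export
read_snp_vcf <- function(path, max_missing_keep_fraction = 0.7,
                         min_maf = 0.05) {
  stopifnot(max_missing_keep_fraction >= 0, max_missing_keep_fraction <= 1,
            min_maf >= 0, min_maf <= 1)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_drop <- sum(!biallelic_snp)
  if (n_drop > 0) {
    message("read_snp_vcf: dropped ", n_drop, " non-biallelic-SNP record(s)")
  }
  gt <- vcfR::extract.gt(vcf)
  geno <- .gt_to_dosage(gt)[biallelic_snp, , drop = FALSE]
  sites <- data.frame(
    chrom = fix[biallelic_snp, "CHROM"],
    pos = as.numeric(fix[biallelic_snp, "POS"]) - 1,
    ref = ref[biallelic_snp],
    alt = alt[biallelic_snp],
    stringsAsFactors = FALSE
  )
  keep <- .missing_fraction(geno) <= (1 - max_missing_keep_fraction) &
    .maf(geno) >= min_maf
  sites <- sites[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL
  new_snp_matrix(sites, geno)
}

new_snp_matrix <- function(sites, geno) {
  stopifnot(nrow(sites) == nrow(geno))
  rownames(geno) <- paste0(sites$chrom, ":", sites$pos)
  structure(
    list(sites = sites, geno = geno, samples = colnames(geno)),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("SNP matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Read and filter a structural-variant VCF
#'
#' Reads an SV VCF (DEL/DUP/INS records carrying `SVTYPE` plus `END` and/or
#' `SVLEN` INFO fields) and applies the SV-level filters: strict minimum
#' length ("exceeding" `min_length`), maximum per-site missing-call fraction,
#' and minimum MAF. Records of other SV types are dropped with a logged
#' count; records that allow no length derivation are rejected with a
#' warning.
#'
#' Length semantics: for DEL/DUP the length is `abs(SVLEN)` when present,
#' otherwise `END - POS`; the internal interval is 0-based half-open
#' `[POS-1, POS-1+length)`. For INS the length comes from `SVLEN` only and
#' the interval is the point `start` (`end == start`).
#'
#' @param path Path to the SV VCF.
#' @param min_length Minimum SV length in bp, strict (default 50: a 50 bp
#'   variant is removed, a 51 bp variant kept).
#' @param max_missing_fraction Maximum fraction of missing genotype calls
#'   per record (default 0.5).
#' @param min_maf Minimum minor-allele frequency from non-missing calls
#'   (default 0.01).
#' @return An `sv_set`: list with `records` (data frame `sv_id`, `type`,
#'   `chrom`, `start`, `end`, `length`), `geno` dosage matrix and `samples`.
#' @export
read_sv_vcf <- function(path, min_length = 50, max_missing_fraction = 0.5,
                        min_maf = 0.01) {
  stopifnot(min_length >= 0, max_missing_fraction >= 0,
            max_missing_fraction <= 1, min_maf >= 0, min_maf <= 1)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  end1 <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "END")))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "SVLEN")))
  pos1 <- as.numeric(fix[, "POS"])

  known <- !is.na(svtype) & svtype %in% c("DEL", "DUP", "INS")
  if (any(!known)) {
    message("read_sv_vcf: dropped ", sum(!known),
            " record(s) of types outside DEL/DUP/INS")
  }

  len <- ifelse(svtype == "INS", abs(svlen),
                ifelse(!is.na(svlen), abs(svlen), end1 - pos1))
  no_len <- known & is.na(len)
  if (any(no_len)) {
    warning("read_sv_vcf: rejected ", sum(no_len),
            " record(s) lacking both END and SVLEN")
  }
  usable <- known & !is.na(len)

  gt <- vcfR::extract.gt(vcf)
  geno <- .gt_to_dosage(gt)
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == ".")) {
    blank <- is.na(ids) | ids == "."
    ids[blank] <- paste0("sv_", which(blank))
  }

  start0 <- pos1 - 1
  end0 <- ifelse(svtype == "INS", start0, start0 + len)
  records <- data.frame(
    sv_id = ids, type = svtype, chrom = fix[, "CHROM"],
    start = start0, end = end0, length = len, stringsAsFactors = FALSE
  )[usable, , drop = FALSE]
  geno <- geno[usable, , drop = FALSE]

  keep <- records$length > min_length &
    .missing_fraction(geno) <= max_missing_fraction &
    .maf(geno) >= min_maf
  records <- records[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  ord <- order(records$chrom, records$start)
  records <- records[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(records) <- NULL
  new_sv_set(records, geno)
}

new_sv_set <- function(records, geno) {
  stopifnot(nrow(records) == nrow(geno),
            all(records$end >= records$start))
  rownames(geno) <- records$sv_id
  structure(
    list(records = records, geno = geno, samples = colnames(geno)),
    class = "sv_set"
  )
}

#' @export
print.sv_set <- function(x, ...) {
  cat("SV set:", nrow(x$records), "variants x", length(x$samples),
      "samples (", paste(names(table(x$records$type)),
                         table(x$records$type), collapse = ", "), ")\n")
  invisible(x)
}

.dosage_to_gt <- function(geno) {
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  gt[geno == 0L] <- "0/0"
  gt[geno == 1L] <- "0/1"
  gt[geno == 2L] <- "1/1"
  gt
}

.vcf_header <- function(layout, extra_info = character()) {
  c("##fileformat=VCFv4.2",
    "##source=pangenpop",
    sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
            as.integer(layout$length)),
    extra_info,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
}

#' Write a SNP matrix as a plain-text VCF
#'
#' @param snp A `snp_matrix`.
#' @param layout The `genome_layout` (for contig header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snp, layout, path) {
  gt <- .dosage_to_gt(snp$geno)
  body <- paste(snp$sites$chrom, as.integer(snp$sites$pos + 1),
                paste0("snp_", seq_len(nrow(snp$sites))),
                snp$sites$ref, snp$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c(.vcf_header(layout),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", snp$samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an SV set as a plain-text VCF
#'
#' Emits `SVTYPE`, `END` (1-based inclusive, consistent with the reader's
#' `END - POS` length derivation) and `SVLEN` INFO fields.
#'
#' @param sv An `sv_set`.
#' @param layout The `genome_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(sv, layout, path) {
  r <- sv$records
  gt <- .dosage_to_gt(sv$geno)
  pos1 <- as.integer(r$start + 1)
  end1 <- as.integer(ifelse(r$type == "INS", pos1, pos1 + r$length))
  svlen <- as.integer(ifelse(r$type == "DEL", -r$length, r$length))
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", r$type, end1, svlen)
  body <- paste(r$chrom, pos1, r$sv_id, "N", paste0("<", r$type, ">"),
                ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  extra <- c('##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
             '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
             '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
             '##ALT=<ID=DEL,Description="Deletion">',
             '##ALT=<ID=DUP,Description="Duplication">',
             '##ALT=<ID=INS,Description="Insertion">')
  hdr <- c(.vcf_header(layout, extra),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sv$samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
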