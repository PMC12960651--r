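# Two-population Weir & Cockerham (1984) FST variance components, windowed
# FST/Pi scans with differentiation banding, gene +/- flank profiles, and
# the SNP-vs-SV differentiated-window comparison. SNPs and SVs run through
# the identical estimator path: any biallelic dosage matrix with site
# coordinates qualifies.

# extract a common marker representation: sites (chrom, pos) + dosage geno
marker_sites <- function(x) {
  if (inherits(x, "snp_matrix")) {
    list(sites = data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                            stringsAsFactors = FALSE),
         geno = x$geno)
  } else if (inherits(x, "sv_set")) {
    list(sites = data.frame(chrom = x$records$chrom, pos = x$records$start,
                            stringsAsFactors = FALSE),
         geno = x$geno)
  } else {
    stop("expected a snp_matrix or sv_set")
  }
}

# Weir & Cockerham (1984) variance components for two populations, from
# per-site per-group non-missing sample size n, alt-allele frequency p and
# observed heterozygote fraction h. All arguments are vectors over sites.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

# per-site group summaries from a dosage matrix and a sample index vector
.group_site_stats <- function(geno, idx) {
  g <- geno[, idx, drop = FALSE]
  n <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * n)
  h <- rowSums(g == 1, na.rm = TRUE) / n
  list(n = n, p = p, h = h)
}

#' Per-site Weir-Cockerham FST between two groups
#'
#' Computes the two-population Weir & Cockerham (1984) variance components
#' (a: between populations; b: between individuals within populations;
#' c: within individuals) at every marker and the per-site estimate
#' `a / (a + b + c)`. Per-site estimates may be negative and are not
#' clamped. Sites monomorphic across both groups (zero total variance) and
#' sites with fewer than 2 non-missing calls in either group are skipped
#' with a recorded reason.
#'
#' @param x A `snp_matrix` or `sv_set` (SVs are treated as biallelic
#'   markers located at their start breakpoint).
#' @param design Design data frame (`sample`, `group`).
#' @param group_a,group_b Group labels to contrast.
#' @return Data frame with one row per marker: `chrom`, `pos`, per-group
#'   `n`, `p` (alt frequency), components `a`, `b`, `c`, `fst` and
#'   `skipped` reason (`NA` when estimated).
#' @export
fst_scan <- function(x, design, group_a, group_b) {
  mk <- marker_sites(x)
  grp <- design_groups(design, group_a, group_b, colnames(mk$geno))
  s1 <- .group_site_stats(mk$geno, grp$a)
  s2 <- .group_site_stats(mk$geno, grp$b)
  out <- data.frame(
    chrom = mk$sites$chrom, pos = mk$sites$pos,
    n1 = s1$n, p1 = s1$p, n2 = s2$n, p2 = s2$p,
    stringsAsFactors = FALSE
  )
  too_few <- s1$n < 2 | s2$n < 2
  comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  denom <- comp$a + comp$b + comp$c
  mono <- !too_few & abs(denom) < .Machine$double.eps
  out$a <- ifelse(too_few, NA_real_, comp$a)
  out$b <- ifelse(too_few, NA_real_, comp$b)
  out$c <- ifelse(too_few, NA_real_, comp$c)
  out$fst <- ifelse(too_few | mono, NA_real_, comp$a / denom)
  out$skipped <- ifelse(too_few, "fewer than 2 calls in a group",
                        ifelse(mono, "monomorphic in both groups",
                               NA_character_))
  n_skip <- sum(too_few | mono)
  if (n_skip > 0) {
    message("fst_scan: ", n_skip, " site(s) skipped (",
            sum(too_few), " undersampled, ", sum(mono), " monomorphic)")
  }
  out
}

#' Single-site Weir-Cockerham FST from two genotype vectors
#'
#' Convenience wrapper around the same estimator path as [fst_scan()] for
#' one site given the diploid dosage vectors of the two groups.
#'
#' @param genotypes_a,genotypes_b Dosage vectors (0/1/2, `NA` missing).
#' @return List with `a`, `b`, `c`, `fst` and the per-group `n`, `p`, `h`.
#' @export
site_fst <- function(genotypes_a, genotypes_b) {
  geno <- rbind(c(genotypes_a, genotypes_b))
  colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  s1 <- .group_site_stats(geno, seq_along(genotypes_a))
  s2 <- .group_site_stats(geno, length(genotypes_a) + seq_along(genotypes_b))
  if (s1$n < 2 || s2$n < 2) stop("each group needs >= 2 non-missing calls")
  comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  denom <- comp$a + comp$b + comp$c
  list(a = comp$a, b = comp$b, c = comp$c,
       fst = if (abs(denom) < .Machine$double.eps) NA_real_ else
         comp$a / denom,
       n1 = s1$n, p1 = s1$p, h1 = s1$h, n2 = s2$n, p2 = s2$p, h2 = s2$h)
}

# band labels from mean FST: < low minimal, < high moderate, else significant
.fst_band <- function(fst, bands) {
  ifelse(is.na(fst), NA_character_,
         ifelse(fst < bands[1], "minimal",
                ifelse(fst < bands[2], "moderate", "significant")))
}

#' Windowed FST and nucleotide diversity between two groups
#'
#' Tiles the genome with non-overlapping windows and reports, per window:
#' the arithmetic mean of per-site FST estimates (`mean_fst`, the quantity
#' the differentiation bands are applied to), the ratio-of-sums weighted
#' estimate `sum(a) / sum(a+b+c)` (`weighted_fst`), and per-group
#' nucleotide diversity Pi. Pi sums the unbiased per-site heterozygosity
#' `2*p*(1-p) * 2n/(2n-1)` over the window's sites and divides by the
#' window length in bp. Bands: `mean_fst < bands[1]` minimal,
#' `< bands[2]` moderate, `>= bands[2]` significant; windows with no
#' estimable site get `NA`.
#'
#' @param x A `snp_matrix` or `sv_set`.
#' @param design Design data frame (`sample`, `group`).
#' @param group_a,group_b Group labels to contrast.
#' @param layout A `genome_layout`.
#' @param window_bp Window size in bp (default 100000).
#' @param bands Two increasing FST thresholds (default `c(0.05, 0.15)`).
#' @param clamp_negative If `TRUE`, negative per-site estimates are set to
#'   0 before averaging (default `FALSE`, the VCFtools-style behavior).
#' @return An `fst_windows` data frame covering every tiled window:
#'   `chrom`, `start`, `end`, `n_sites`, `n_est`, `mean_fst`,
#'   `weighted_fst`, `pi_a`, `pi_b`, `band`.
#' @export
windowed_fst_pi <- function(x, design, group_a, group_b, layout,
                            window_bp = 100000, bands = c(0.05, 0.15),
                            clamp_negative = FALSE) {
  stopifnot(window_bp > 0, length(bands) == 2, bands[1] < bands[2])
  scan <- fst_scan(x, design, group_a, group_b)
  len <- layout_length(layout, scan$chrom)
  if (any(scan$pos < 0 | scan$pos >= len)) {
    stop("marker beyond chromosome length")
  }
  # unbiased per-site heterozygosity contributions per group
  pi_site <- function(p, n) {
    v <- 2 * p * (1 - p) * (2 * n / (2 * n - 1))
    ifelse(is.na(v) | n < 1, 0, v)
  }
  scan$pi1 <- pi_site(scan$p1, scan$n1)
  scan$pi2 <- pi_site(scan$p2, scan$n2)
  fst_for_mean <- if (clamp_negative) pmax(scan$fst, 0) else scan$fst

  wins <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    starts <- seq(0, layout$length[i] - 1, by = window_bp)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + window_bp, layout$length[i]),
               stringsAsFactors = FALSE)
  }))
  widx <- match(paste0(scan$chrom, ":", (scan$pos %/% window_bp) * window_bp),
                paste0(wins$chrom, ":", wins$start))
  agg <- function(v, f = sum) {
    out <- rep(0, nrow(wins))
    ok <- !is.na(v)
    if (any(ok)) {
      s <- rowsum(v[ok], widx[ok])
      out[as.integer(rownames(s))] <- s[, 1]
    }
    out
  }
  wins$n_sites <- agg(rep(1, nrow(scan)))
  wins$n_est <- agg(as.numeric(!is.na(scan$fst)))
  sum_fst <- agg(fst_for_mean)
  wins$mean_fst <- ifelse(wins$n_est > 0, sum_fst / wins$n_est, NA_real_)
  sum_a <- agg(scan$a)
  sum_abc <- agg(scan$a + scan$b + scan$c)
  wins$weighted_fst <- ifelse(sum_abc != 0, sum_a / sum_abc, NA_real_)
  wins$pi_a <- agg(scan$pi1) / (wins$end - wins$start)
  wins$pi_b <- agg(scan$pi2) / (wins$end - wins$start)
  wins$band <- .fst_band(wins$mean_fst, bands)
  structure(wins, class = c("fst_windows", "data.frame"),
            window_bp = window_bp, bands = bands)
}

#' Genome-wide weighted FST
#'
#' Ratio-of-sums Weir-Cockerham estimate over all estimable sites:
#' `sum(a) / sum(a + b + c)`.
#'
#' @inheritParams fst_scan
#' @return A single numeric value.
#' @export
global_weighted_fst <- function(x, design, group_a, group_b) {
  scan <- suppressMessages(fst_scan(x, design, group_a, group_b))
  ok <- !is.na(scan$a)
  sum(scan$a[ok]) / sum(scan$a[ok] + scan$b[ok] + scan$c[ok])
}

#' FST profile over a gene and its flanks
#'
#' Summarizes per-site FST over `[start - flank_bp, end + flank_bp)` of
#' one gene: mean and weighted estimates plus the positional series for
#' plotting.
#'
#' @param x A `snp_matrix` or `sv_set`.
#' @param design Design data frame.
#' @param group_a,group_b Group labels.
#' @param gene One row of a `gene_models` data frame (or any list with
#'   `chrom`, `start`, `end`).
#' @param flank_bp Flank in bp (default 2000).
#' @return List with `gene_id` (if present), `n_sites`, `mean_fst`,
#'   `weighted_fst` and `sites` (positional data frame). Empty span gives
#'   zero sites and `NA` estimates with a warning.
#' @export
gene_flank_fst <- function(x, design, group_a, group_b, gene,
                           flank_bp = 2000) {
  scan <- suppressMessages(fst_scan(x, design, group_a, group_b))
  span <- c(gene$start - flank_bp, gene$end + flank_bp)
  sel <- scan$chrom == gene$chrom & scan$pos >= span[1] & scan$pos < span[2]
  sub <- scan[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no sites in gene span ", gene$chrom, ":", span[1], "-", span[2])
    return(list(gene_id = gene$gene_id, n_sites = 0L, mean_fst = NA_real_,
                weighted_fst = NA_real_, sites = sub))
  }
  ok <- !is.na(sub$fst)
  list(gene_id = gene$gene_id, n_sites = nrow(sub),
       mean_fst = if (any(ok)) mean(sub$fst[ok]) else NA_real_,
       weighted_fst = if (any(ok))
         sum(sub$a[ok]) / sum(sub$a[ok] + sub$b[ok] + sub$c[ok])
       else NA_real_,
       sites = sub)
}

#' Compare SNP- and SV-based differentiated windows
#'
#' Given two windowed FST scans on the same tiling (one from SNPs, one
#' from SVs), counts significantly differentiated windows per marker
#' class, the window-level Venn partition (shared / SNP-only / SV-only),
#' and the gene sets overlapping each class's significant windows with
#' their intersection and union.
#'
#' @param snp_windows,sv_windows `fst_windows` data frames on the same
#'   layout and banding.
#' @param genes A `gene_models` data frame.
#' @return List with `windows` (counts: snp, sv, shared, snp_only,
#'   sv_only), `genes_snp`, `genes_sv`, `genes_shared`, `genes_union`.
#' @export
compare_marker_classes <- function(snp_windows, sv_windows, genes) {
  key <- function(w) paste0(w$chrom, ":", w$start, "-", w$end)
  if (nrow(snp_windows) != nrow(sv_windows) ||
      !identical(sort(key(snp_windows)), sort(key(sv_windows)))) {
    stop("window sets are on different layouts or tilings")
  }
  sig <- function(w) w[!is.na(w$band) & w$band == "significant", ,
                       drop = FALSE]
  s_snp <- sig(snp_windows)
  s_sv <- sig(sv_windows)
  k_snp <- key(s_snp)
  k_sv <- key(s_sv)
  gene_hits <- function(wins) {
    if (nrow(wins) == 0) return(character())
    unique(genes_in_regions(wins, genes, flank_bp = 0)$gene_id)
  }
  g_snp <- gene_hits(s_snp)
  g_sv <- gene_hits(s_sv)
  list(
    windows = c(snp = nrow(s_snp), sv = nrow(s_sv),
                shared = length(intersect(k_snp, k_sv)),
                snp_only = length(setdiff(k_snp, k_sv)),
                sv_only = length(setdiff(k_sv, k_snp))),
    genes_snp = g_snp, genes_sv = g_sv,
    genes_shared = intersect(g_snp, g_sv),
    genes_union = union(g_snp, g_sv)
  )
}
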