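# Weir-Cockerham FST components, windowed FST/Pi, gene profiles and the
# SNP-vs-SV comparison.

snp_from_geno <- function(geno, pos = NULL, chrom = "chr1") {
  if (is.null(pos)) pos <- (seq_len(nrow(geno)) - 1) * 1000
  colnames(geno) <- colnames(geno) %||% paste0("s", seq_len(ncol(geno)))
  pangenpop:::new_snp_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE), geno)
}
two_group_design <- function(samples, n1) {
  data.frame(sample = samples,
             group = rep(c("g1", "g2"), c(n1, length(samples) - n1)),
             stringsAsFactors = FALSE)
}

test_that("fixed difference gives FST 1; identical groups are null", {
  res <- site_fst(rep(2L, 10), rep(0L, 10))
  expect_equal(res$fst, 1)
  # both groups identical at p = 0.5: per-site estimates are <= 0 and
  # average near 0 over many such sites
  set.seed(2)
  g <- matrix(rbinom(2000 * 24, 2, 0.5), 2000, 24)
  snp <- snp_from_geno(g)
  design <- two_group_design(snp$samples, 12)
  scan <- suppressMessages(fst_scan(snp, design, "g1", "g2"))
  expect_lt(abs(mean(scan$fst, na.rm = TRUE)), 0.01)
})

test_that("variance components equal the independent formula oracle", {
  set.seed(3)
  for (i in 1:50) {
    n1 <- sample(2:15, 1)
    n2 <- sample(2:15, 1)
    g1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    g2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    if (sum(g1) + sum(g2) == 0 || sum(g1) + sum(g2) == 2 * (n1 + n2)) next
    got <- site_fst(g1, g2)
    want <- oracle_wc_fst(list(g1, g2))
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$b, want$b, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$fst, want$fst, tolerance = 1e-12)
  }
  # the worked configuration: n1=6, n2=8, p1=0.75, p2=0.25 with known
  # heterozygote counts
  g1 <- c(2, 2, 2, 1, 1, 1)      # p = 0.75, 3 hets
  g2 <- c(0, 0, 0, 0, 1, 1, 1, 1)  # p = 0.25, 4 hets
  expect_equal(site_fst(g1, g2)$fst, oracle_wc_fst(list(g1, g2))$fst,
               tolerance = 1e-12)
})

test_that("undersampled and monomorphic sites are skipped with reasons", {
  g <- rbind(c(2L, NA, NA, NA, 0L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
             c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  snp <- snp_from_geno(g)
  design <- two_group_design(snp$samples, 4)
  expect_message(scan <- fst_scan(snp, design, "g1", "g2"), "skipped")
  expect_equal(scan$skipped[1], "fewer than 2 calls in a group")
  expect_equal(scan$skipped[3], "monomorphic in both groups")
  expect_true(is.na(scan$fst[1]) && is.na(scan$fst[3]))
  expect_false(is.na(scan$fst[2]))  # all-het site is estimable
})

test_that("SNPs and SVs share one estimator path", {
  set.seed(4)
  geno <- matrix(rbinom(50 * 10, 2, 0.4), 50, 10)
  colnames(geno) <- paste0("s", 1:10)
  snp <- snp_from_geno(geno, pos = seq(1000, by = 2000, length.out = 50))
  sv <- make_sv_set(type = rep("DEL", 50), chrom = "chr1",
                    start = seq(1000, by = 2000, length.out = 50),
                    length = rep(100, 50), geno = geno)
  design <- two_group_design(colnames(geno), 5)
  a <- suppressMessages(fst_scan(snp, design, "g1", "g2"))
  b <- suppressMessages(fst_scan(sv, design, "g1", "g2"))
  expect_equal(a$fst, b$fst)
  expect_equal(a$pos, b$pos)
})

test_that("windowed FST/Pi matches brute-force recomputation and banding", {
  set.seed(5)
  layout <- genome_layout("chr1", 1e6)
  n_sites <- 500
  pos <- sort(sample(0:(1e6 - 1), n_sites))
  geno <- matrix(rbinom(n_sites * 20, 2, runif(n_sites, 0.05, 0.95)),
                 n_sites, 20)
  snp <- snp_from_geno(geno, pos = pos)
  design <- two_group_design(snp$samples, 10)
  win <- suppressMessages(windowed_fst_pi(snp, design, "g1", "g2", layout,
                                          window_bp = 1e5))
  scan <- suppressMessages(fst_scan(snp, design, "g1", "g2"))
  for (i in sample(nrow(win), 5)) {
    sel <- scan$pos >= win$start[i] & scan$pos < win$end[i]
    expect_equal(win$n_sites[i], sum(sel))
    if (any(sel & !is.na(scan$fst))) {
      expect_equal(win$mean_fst[i], mean(scan$fst[sel], na.rm = TRUE),
                   tolerance = 1e-12)
      ok <- sel & !is.na(scan$a)
      expect_equal(win$weighted_fst[i],
                   sum(scan$a[ok]) / sum(scan$a[ok] + scan$b[ok] +
                                           scan$c[ok]),
                   tolerance = 1e-12)
    }
    # Pi oracle for group 1
    p <- scan$p1[sel]
    n <- scan$n1[sel]
    expect_equal(win$pi_a[i],
                 sum(2 * p * (1 - p) * (2 * n / (2 * n - 1))) /
                   (win$end[i] - win$start[i]),
                 tolerance = 1e-12)
  }
  expect_equal(unique(win$band[!is.na(win$mean_fst) & win$mean_fst < 0.05]),
               "minimal")
  # fixed-difference window is significant with mean = weighted = 1
  gfix <- matrix(c(rep(2L, 10), rep(0L, 10)), 1)
  snpf <- snp_from_geno(gfix, pos = 5)
  winf <- suppressMessages(windowed_fst_pi(snpf, design, "g1", "g2",
                                           layout, window_bp = 1e5))
  expect_equal(winf$mean_fst[1], 1)
  expect_equal(winf$weighted_fst[1], 1)
  expect_equal(winf$band[1], "significant")
  # windows with no sites carry Pi 0 and NA band
  expect_true(all(winf$pi_a[-1] == 0))
  expect_true(all(is.na(winf$band[-1])))
})

test_that("Pi is invariant to allele label swap", {
  set.seed(6)
  layout <- genome_layout("chr1", 1e5)
  geno <- matrix(rbinom(50 * 12, 2, 0.3), 50, 12)
  snp1 <- snp_from_geno(geno, pos = seq(100, by = 500, length.out = 50))
  snp2 <- snp_from_geno(2L - geno, pos = seq(100, by = 500,
                                             length.out = 50))
  design <- two_group_design(snp1$samples, 6)
  w1 <- suppressMessages(windowed_fst_pi(snp1, design, "g1", "g2", layout))
  w2 <- suppressMessages(windowed_fst_pi(snp2, design, "g1", "g2", layout))
  expect_equal(w1$pi_a, w2$pi_a, tolerance = 1e-12)
  expect_equal(w1$pi_b, w2$pi_b, tolerance = 1e-12)
})

test_that("gene flank profile equals the site subset mean", {
  set.seed(7)
  pos <- seq(0, 49000, by = 1000)
  geno <- matrix(rbinom(50 * 16, 2, runif(50, 0.1, 0.9)), 50, 16)
  snp <- snp_from_geno(geno, pos = pos)
  design <- two_group_design(snp$samples, 8)
  gene <- list(gene_id = "g", chrom = "chr1", start = 10000, end = 20000)
  prof <- gene_flank_fst(snp, design, "g1", "g2", gene, flank_bp = 2000)
  scan <- suppressMessages(fst_scan(snp, design, "g1", "g2"))
  sel <- scan$pos >= 8000 & scan$pos < 22000
  expect_equal(prof$n_sites, sum(sel))
  expect_equal(prof$mean_fst, mean(scan$fst[sel], na.rm = TRUE),
               tolerance = 1e-12)
  empty_gene <- list(gene_id = "e", chrom = "chr1", start = 60000,
                     end = 70000)
  expect_warning(p0 <- gene_flank_fst(snp, design, "g1", "g2", empty_gene),
                 "no sites")
  expect_equal(p0$n_sites, 0L)
})

test_that("marker-class comparison produces the planted Venn counts", {
  layout <- genome_layout("chr1", 1e6)
  base <- data.frame(chrom = "chr1", start = seq(0, 9e5, by = 1e5),
                     end = seq(1e5, 1e6, by = 1e5), stringsAsFactors = FALSE)
  mk <- function(sig_idx) {
    w <- base
    w$n_sites <- 10L
    w$n_est <- 10L
    w$mean_fst <- ifelse(seq_len(10) %in% sig_idx, 0.5, 0.01)
    w$weighted_fst <- w$mean_fst
    w$pi_a <- 0.001
    w$pi_b <- 0.001
    w$band <- ifelse(seq_len(10) %in% sig_idx, "significant", "minimal")
    structure(w, class = c("fst_windows", "data.frame"), window_bp = 1e5,
              bands = c(0.05, 0.15))
  }
  # 3 shared + 2 SNP-only + 4 SV-only
  snp_w <- mk(c(1, 2, 3, 4, 5))
  sv_w <- mk(c(1, 2, 3, 6, 7, 8, 9))
  cfg <- sim_config(seed = 8, n_chromosomes = 1, chromosome_length = 1e6,
                    n_genes = 60, n_differential = 0)
  set.seed(8)
  genes <- simulate_genes(cfg, layout)
  cmp <- compare_marker_classes(snp_w, sv_w, genes)
  expect_equal(unname(cmp$windows[c("shared", "snp_only", "sv_only")]),
               c(3L, 2L, 4L))
  # identical window sets share their whole gene set
  cmp2 <- compare_marker_classes(snp_w, snp_w, genes)
  expect_setequal(cmp2$genes_shared, cmp2$genes_snp)
  # mismatched tilings error
  other <- mk(1)
  other$start <- other$start + 10
  expect_error(compare_marker_classes(snp_w, other, genes), "tiling")
})

test_that("Balding-Nichols simulation recovers the planted F", {
  inside <- 0
  for (seed in 1:5) {
    snp <- simulate_balding_nichols(runif(5000, 0.1, 0.9), F = 0.15,
                                    group_sizes = c(13, 14),
                                    n_loci = 5000, seed = seed)
    design <- attr(snp, "design")
    fst <- global_weighted_fst(snp, design, "pop_1", "pop_2")
    inside <- inside + (fst >= 0.12 && fst <= 0.18)
  }
  expect_equal(inside, 5)
  # near-zero F gives near-zero FST; large F approaches fixation
  snp0 <- simulate_balding_nichols(0.5, F = 1e-6, group_sizes = c(15, 15),
                                   n_loci = 2000, seed = 1)
  expect_lt(abs(global_weighted_fst(snp0, attr(snp0, "design"),
                                    "pop_1", "pop_2")), 0.02)
  snp9 <- simulate_balding_nichols(0.5, F = 0.9, group_sizes = c(15, 15),
                                   n_loci = 2000, seed = 1)
  expect_gt(global_weighted_fst(snp9, attr(snp9, "design"),
                                "pop_1", "pop_2"), 0.5)
  expect_error(simulate_balding_nichols(0.5, 0, c(5, 5), 10), "strictly")
})
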