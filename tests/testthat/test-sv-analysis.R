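# SV landscape summaries, genomic-context annotation and hotspot scan.

test_that("summary counts types, carriers and conserves the grand total", {
  geno <- rbind(matrix(1L, 3, 4),        # 3 DELs carried by everyone
                matrix(0L, 1, 4))        # 1 DUP carried by no one
  colnames(geno) <- paste0("s", 1:4)
  sv <- make_sv_set(type = c("DEL", "DEL", "DEL", "DUP"), chrom = "chr1",
                    start = c(100, 500, 900, 1300), length = rep(60, 4),
                    geno = geno)
  ss <- sv_summary(sv)
  expect_equal(unname(ss$type_totals), c(3L, 1L, 0L))
  expect_equal(ss$total, sum(ss$type_totals))
  expect_equal(ss$per_sample$count, rep(3L, 4))
  expect_equal(ss$per_sample$del_fraction, rep(1, 4))
  # random fixture: per-sample counts match a direct genotype scan
  set.seed(12)
  g2 <- matrix(rbinom(200 * 6, 2, 0.3), 200, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  sv2 <- make_sv_set(type = sample(c("DEL", "DUP", "INS"), 200, TRUE),
                     chrom = "chr1", start = seq(1e3, by = 2e3,
                                                 length.out = 200),
                     length = rep(80, 200), geno = g2)
  ss2 <- sv_summary(sv2)
  expect_equal(ss2$per_sample$count,
               unname(apply(sv2$geno, 2, function(z) sum(z > 0))))
  expect_equal(ss2$total, 200L)
})

test_that("context annotation follows genic > flank > intergenic", {
  genes <- pangenpop:::new_gene_models(
    c("gA", "gB"), c("chr1", "chr1"), c("+", "+"),
    c(10000, 50000), c(12000, 53000),
    list(cbind(start = 10000, end = 12000),
         cbind(start = 50000, end = 53000)))
  sv <- make_sv_set(
    type = c("INS", "DEL", "DEL", "DUP", "DEL"),
    chrom = "chr1",
    start = c(11000,   # INS inside gA -> genic
              8500,    # DEL [8500,8600) in gA upstream flank
              30000,   # DEL far from both genes -> intergenic
              11900,   # DUP overlapping gA end -> genic
              53999),  # DEL starting 1999 bp after gB end -> flank
    length = c(50, 100, 200, 300, 400))
  ctx <- annotate_context(sv, genes)
  got <- ctx$context[match(sprintf("sv%03d", 1:5), ctx$sv_id)]
  expect_equal(got, c("genic", "flank_2kb", "intergenic", "genic",
                      "flank_2kb"))
  expect_equal(ctx$genes[match("sv001", ctx$sv_id)], "gA")
})

test_that("context annotation equals quadratic brute force", {
  cfg <- sim_config(seed = 13, n_chromosomes = 2, chromosome_length = 2e6,
                    n_genes = 50, n_differential = 0)
  set.seed(13)
  layout <- simulate_layout(cfg)
  genes <- simulate_genes(cfg, layout)
  n <- 300
  type <- sample(c("DEL", "DUP", "INS"), n, TRUE)
  chrom <- sample(layout$chrom, n, TRUE)
  start <- floor(runif(n, 0, 1.9e6))
  sv <- make_sv_set(type = type, chrom = chrom, start = start,
                    length = sample(60:5000, n, TRUE))
  ctx <- annotate_context(sv, genes)
  r <- sv$records
  for (i in sample(n, 50)) {
    s <- r$start[i]
    e <- if (r$type[i] == "INS") r$start[i] + 1 else r$end[i]
    g <- genes[genes$chrom == r$chrom[i], ]
    genic <- any(s < g$end & g$start < e)
    flank <- any((s < g$start & g$start - 2000 < e) |
                   (s < g$end + 2000 & g$end < e))
    want <- if (genic) "genic" else if (flank) "flank_2kb" else "intergenic"
    expect_equal(ctx$context[ctx$sv_id == r$sv_id[i]], want)
  }
})

test_that("hand-placed 12-SV fixture yields the enumerated hotspots", {
  # 2 Mb chromosome, 200 kb windows, 100 kb steps -> 20 windows; top 5%
  # is ceiling(1) = 1 window plus ties. 10 SVs cluster tightly around
  # 1.05 Mb so windows [0.9,1.1) and [1.0,1.2) tie at 20 breakpoints;
  # 2 SVs sit isolated near 0.3 Mb.
  layout <- genome_layout("chr1", 2e6)
  sv <- make_sv_set(
    type = rep("DEL", 12), chrom = "chr1",
    start = c(seq(1040000, 1058000, by = 2000), 300000, 310000),
    length = c(rep(1000, 10), 5000, 5000))
  hs <- hotspot_scan(sv, layout)
  # both tied windows are hotspots and merge into one region
  expect_equal(nrow(hs$regions), 1)
  expect_equal(hs$regions$start, 900000)
  expect_equal(hs$regions$end, 1200000)
  expect_equal(hs$regions$n_windows, 2L)
  expect_equal(hs$capture_fraction, 10 / 12)
  expect_equal(hs$genome_fraction, 300000 / 2e6)
  expect_setequal(hs$regions$sv_ids[[1]], sprintf("sv%03d", 1:10))
  # window counts match direct counting for the two cluster windows
  w <- hs$windows
  expect_equal(w$count[w$start == 1000000][1], 20L)
  expect_equal(w$count[w$start == 900000][1], 20L)
})

test_that("all SVs in one span are captured by a single region", {
  layout <- genome_layout(c("chr1", "chr2"), c(10e6, 10e6))
  sv <- make_sv_set(type = rep("DEL", 40), chrom = "chr1",
                    start = seq(5000000, 5150000, length.out = 40),
                    length = rep(500, 40))
  hs <- hotspot_scan(sv, layout)
  expect_equal(hs$capture_fraction, 1.0)
  expect_equal(length(unique(vapply(seq_len(nrow(hs$regions)),
                                    function(i) hs$regions$chrom[i], ""))),
               1)
  # every captured SV appears in exactly one region list
  all_ids <- unlist(hs$regions$sv_ids)
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("uniform breakpoints give top-5% coverage and sane capture", {
  set.seed(14)
  layout <- genome_layout("chr1", 20e6)
  n <- 2000
  sv <- make_sv_set(type = rep("DEL", n), chrom = "chr1",
                    start = floor(runif(n, 0, 20e6 - 1000)),
                    length = rep(200, n))
  hs <- hotspot_scan(sv, layout)
  # ~5% of windows become hotspots (ties can add a few)
  expect_gte(nrow(hs$windows[hs$windows$hotspot, ]), 10)
  expect_lt(hs$genome_fraction, 0.15)
  expect_gt(hs$capture_fraction, 0.05)
  expect_lt(hs$capture_fraction, 0.20)
})

test_that("breakpoint counting ignores genotypes entirely", {
  set.seed(15)
  layout <- genome_layout("chr1", 5e6)
  g1 <- matrix(rbinom(100 * 8, 2, 0.4), 100, 8,
               dimnames = list(NULL, paste0("s", 1:8)))
  starts <- floor(runif(100, 0, 4.9e6))
  sv1 <- make_sv_set(type = rep("DUP", 100), chrom = "chr1",
                     start = starts, length = rep(300, 100), geno = g1)
  sv2 <- make_sv_set(type = rep("DUP", 100), chrom = "chr1",
                     start = starts, length = rep(300, 100),
                     geno = g1[sample(100), ])
  h1 <- hotspot_scan(sv1, layout)
  h2 <- hotspot_scan(sv2, layout)
  expect_equal(h1$windows$count, h2$windows$count)
  expect_equal(h1$regions[c("chrom", "start", "end")],
               h2$regions[c("chrom", "start", "end")])
})
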