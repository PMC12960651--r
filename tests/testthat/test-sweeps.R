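# XP-CLR window means, top-percentile calling, gap-tolerant merging and
# gene-to-region mapping.

test_that("window means follow the half-open tiling convention", {
  layout <- genome_layout("chr1", 50000)
  track <- structure(
    data.frame(chrom = "chr1", pos = c(1000, 5000, 10000),
               score = c(10, 20, 30), stringsAsFactors = FALSE),
    class = c("score_track", "data.frame"))
  w <- window_scores(track, layout, 10000)
  expect_equal(w$mean_score[w$start == 0], 15)       # sites 1000, 5000
  expect_equal(w$mean_score[w$start == 10000], 30)   # boundary site
  expect_equal(nrow(w), 2)                           # empty windows absent
  # site beyond the chromosome errors with its name
  bad <- track
  bad$pos[1] <- 60000
  expect_error(window_scores(bad, layout, 10000), "chr1")
})

test_that("window means equal brute-force per-window recomputation", {
  set.seed(10)
  layout <- genome_layout(c("chrA", "chrB"), c(2e6, 1e6))
  n <- 1000
  chrom <- sample(layout$chrom, n, replace = TRUE, prob = c(2, 1))
  track <- structure(
    data.frame(chrom = chrom,
               pos = floor(runif(n, 0, ifelse(chrom == "chrA", 2e6, 1e6))),
               score = rexp(n), stringsAsFactors = FALSE),
    class = c("score_track", "data.frame"))
  track <- track[order(track$chrom, track$pos), ]
  w <- window_scores(track, layout, 10000)
  oracle <- oracle_window_means(track, 10000)
  expect_equal(w$mean_score, as.vector(oracle[paste0(w$chrom, ":", w$start)]),
               tolerance = 1e-12)
  expect_equal(sum(w$n_sites), n)
})

test_that("merge rule bridges single top-10% gaps and nothing wider", {
  # 100 windows; craft scores so windows 8 and 10 (1-based) are top-5%
  # while window 9 is top-10% only: T5 = {8,10,30,40,50} (cut 60),
  # next ranks 45,40,40,40,40 put the T10 cut at 40, so window 9 (45)
  # is an eligible bridge
  scores <- seq(0.001, 0.1, length.out = 100)
  scores[c(8, 10, 30, 40, 50)] <- c(100, 90, 80, 70, 60)
  scores[9] <- 45
  scores[60:63] <- 40
  w <- make_windows(scores)
  reg <- call_and_merge(w)
  spanning <- reg[reg$start == 7 * 10000, ]
  expect_equal(nrow(spanning), 1)
  expect_equal(spanning$end, 10 * 10000)        # windows 8..10 merged
  expect_equal(spanning$score, 100)             # max member mean
  # two-window gap does not merge even when both gap windows rank high
  scores2 <- seq(0.001, 0.1, length.out = 100)
  scores2[c(8, 11, 30, 40, 50)] <- c(100, 90, 80, 70, 60)
  scores2[9:10] <- 45
  reg2 <- call_and_merge(make_windows(scores2))
  expect_true((7 * 10000) %in% reg2$start)
  expect_true((10 * 10000) %in% reg2$start)
  expect_equal(reg2$end[reg2$start == 7 * 10000], 8 * 10000)
  # single isolated T5 window forms its own region with its own score
  scores3 <- seq(0.001, 0.1, length.out = 100)
  scores3[42] <- 50
  reg3 <- call_and_merge(make_windows(scores3))
  expect_true((41 * 10000) %in% reg3$start)
  expect_equal(reg3$score[reg3$start == 41 * 10000], 50)
  expect_equal(reg3$end[reg3$start == 41 * 10000], 42 * 10000)
})

test_that("merging matches the literal enumeration oracle on random tracks", {
  set.seed(99)
  for (i in 1:50) {
    n <- 200
    scores <- rexp(n)
    keep <- NULL
    if (i %% 3 == 0) scores <- round(scores, 1)          # ties
    if (i %% 4 == 0) keep <- sort(sample(n, n - 10))     # empty windows
    w <- make_windows(scores, keep = keep)
    reg <- call_and_merge(w)
    orc <- oracle_merge(w, 10000)
    expect_equal(reg[c("chrom", "start", "end", "score")], orc,
                 ignore_attr = TRUE)
  }
})

test_that("merging is idempotent", {
  set.seed(123)
  w <- make_windows(rexp(200))
  reg <- call_and_merge(w)
  # rebuild windows restricted to region members; their merge is unchanged
  members <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    w[w$chrom == reg$chrom[i] & w$start >= reg$start[i] &
        w$start < reg$end[i], ]
  }))
  members <- structure(members, class = c("stat_windows", "data.frame"),
                       window_bp = 10000)
  reg2 <- suppressWarnings(call_and_merge(members,
                                          top_signal_fraction = 1,
                                          gap_fraction = 1))
  expect_equal(reg2[c("chrom", "start", "end")],
               reg[c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("T5 is contained in T10 and sized ceil(0.05 n) up to ties", {
  set.seed(5)
  scores <- rexp(400)
  w <- make_windows(scores)
  cut5 <- sort(scores, decreasing = TRUE)[ceiling(0.05 * 400)]
  cut10 <- sort(scores, decreasing = TRUE)[ceiling(0.10 * 400)]
  expect_gte(cut5, cut10)
  expect_equal(sum(scores >= cut5), 20)  # continuous scores: no ties
})

test_that("gene mapping respects the +/-2 kb flank half-open boundary", {
  regions <- data.frame(chrom = "chr1", start = 50000, end = 60000)
  gene_near <- pangenpop:::new_gene_models(
    "near", "chr1", "+", 46000, 48500,
    list(cbind(start = 46000, end = 48500)))   # ends 1500 bp before
  gene_touch <- pangenpop:::new_gene_models(
    "touch", "chr1", "+", 44000, 48000,
    list(cbind(start = 44000, end = 48000)))   # flank exactly touches
  expect_equal(genes_in_regions(regions, gene_near)$gene_id, "near")
  expect_equal(nrow(genes_in_regions(regions, gene_touch)), 0)
})

test_that("gene mapping equals brute-force all-pairs intersection", {
  set.seed(21)
  layout <- genome_layout("chr1", 5e6)
  cfg <- sim_config(seed = 21, n_chromosomes = 1, chromosome_length = 5e6,
                    n_genes = 200, n_differential = 0)
  genes <- simulate_genes(cfg, layout)
  starts <- sort(sample(seq(0, 4.8e6, by = 1000), 10))
  regions <- data.frame(chrom = "chr1", start = starts,
                        end = starts + 150000)
  got <- genes_in_regions(regions, genes, flank_bp = 2000)
  want <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    hits <- vapply(seq_len(nrow(genes)), function(g) {
      gs <- genes$start[g] - 2000
      ge <- genes$end[g] + 2000
      gs < regions$end[i] && regions$start[i] < ge
    }, TRUE)
    if (!any(hits)) return(NULL)
    data.frame(region = i, gene_id = genes$gene_id[hits])
  }))
  expect_equal(got[c("region", "gene_id")], want, ignore_attr = TRUE)
})

test_that("planted sweep peaks are recovered with few false regions", {
  ok <- 0
  n_rep <- 10
  for (seed in seq_len(n_rep)) {
    cfg <- sim_config(seed = seed, n_genes = 50, n_svs = 50)
    set.seed(seed)
    layout <- simulate_layout(cfg)
    sc <- simulate_score_track(cfg, layout)
    w <- window_scores(sc$track, layout, 10000)
    reg <- call_and_merge(w)
    hits <- sum(vapply(seq_len(nrow(sc$peaks)), function(i) {
      p <- sc$peaks[i, ]
      any(reg$chrom == p$chrom & reg$start < p$end & p$start < reg$end)
    }, TRUE))
    false_regions <- sum(vapply(seq_len(nrow(reg)), function(i) {
      r <- reg[i, ]
      !any(sc$peaks$chrom == r$chrom & sc$peaks$start < r$end &
             r$start < sc$peaks$end)
    }, TRUE))
    ok <- ok + (hits >= 7 && false_regions <= 1)
  }
  expect_gte(ok, ceiling(0.9 * n_rep))
})
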