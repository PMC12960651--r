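# Independent oracle implementations used to cross-check the package's
# estimators. Each oracle is a literal, unoptimized transcription of the
# definition, kept deliberately separate from the code paths it checks.

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, using binomial coefficients directly
oracle_fisher_p <- function(a, n_a, b, n_b) {
  k <- a + b
  n <- n_a + n_b
  denom <- choose(n, k)
  support <- max(0, k - n_b):min(n_a, k)
  pr <- choose(n_a, support) * choose(n_b, k - support) / denom
  p_obs <- choose(n_a, a) * choose(n_b, k - a) / denom
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Weir & Cockerham (1984) two-population variance components, transcribed
# independently as an explicit loop over populations
oracle_wc_fst <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n <- numeric(r); p <- numeric(r); h <- numeric(r)
  for (i in seq_len(r)) {
    g <- geno_by_pop[[i]][!is.na(geno_by_pop[[i]])]
    n[i] <- length(g)
    p[i] <- sum(g) / (2 * length(g))
    h[i] <- sum(g == 1) / length(g)
  }
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c, fst = a / (a + b + c))
}

# brute-force per-window means of a score track (named vector keyed by
# "chrom:start")
oracle_window_means <- function(track, window_bp) {
  key <- paste0(track$chrom, ":", (track$pos %/% window_bp) * window_bp)
  tapply(track$score, key, mean)
}

# literal enumeration of the sweep merge rule: mark the top-5%/top-10%
# sets, link signal windows pairwise (adjacent, or one-apart across a
# ranked top-10% window), then take connected components
oracle_merge <- function(windows, window_bp, top = 0.05, gap = 0.10) {
  n <- nrow(windows)
  cut5 <- sort(windows$mean_score, decreasing = TRUE)[
    max(1, ceiling(top * n))]
  cut10 <- sort(windows$mean_score, decreasing = TRUE)[
    max(1, ceiling(gap * n))]
  t5 <- which(windows$mean_score >= cut5)
  linked <- matrix(FALSE, length(t5), length(t5))
  for (i in seq_along(t5)) for (j in seq_along(t5)) {
    wi <- windows[t5[i], ]
    wj <- windows[t5[j], ]
    if (wi$chrom != wj$chrom) next
    d <- (wj$start - wi$start) / window_bp
    if (abs(d) == 1) linked[i, j] <- TRUE
    if (abs(d) == 2) {
      mid_start <- min(wi$start, wj$start) + window_bp
      mid <- which(windows$chrom == wi$chrom & windows$start == mid_start)
      if (length(mid) == 1 && windows$mean_score[mid] >= cut10) {
        linked[i, j] <- TRUE
      }
    }
  }
  diag(linked) <- TRUE
  # connected components by boolean closure
  repeat {
    nxt <- (linked %*% linked) > 0
    if (identical(nxt, linked)) break
    linked <- nxt
  }
  comp <- rep(NA_integer_, length(t5))
  cid <- 0
  for (i in seq_along(t5)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[which(linked[i, ])] <- cid
    }
  }
  regs <- lapply(split(t5, comp), function(members) {
    w <- windows[members, ]
    span <- c(min(w$start), max(w$end))
    in_span <- windows$chrom == w$chrom[1] & windows$start >= span[1] &
      windows$start < span[2]
    data.frame(chrom = w$chrom[1], start = span[1], end = span[2],
               score = max(windows$mean_score[in_span]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regs)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force Jaccard distances from explicit presence sets
oracle_jaccard <- function(pav) {
  n <- ncol(pav)
  d <- matrix(0, n, n)
  sets <- lapply(seq_len(n), function(j) which(pav[, j] > 0))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    un <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- if (un == 0) 0 else
      1 - length(intersect(sets[[i]], sets[[j]])) / un
  }
  d
}

# partition equality up to label permutation
same_partition <- function(a, b) {
  sig <- function(x) {
    blocks <- split(seq_along(x), x)
    paste(sort(vapply(blocks, paste, "", collapse = ",")), collapse = ";")
  }
  sig(a) == sig(b)
}
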