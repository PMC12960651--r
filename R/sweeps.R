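# Selective-sweep post-processing of per-SNP XP-CLR score tracks:
# fixed-width window means, top-percentile signal calling, gap-tolerant
# merging with max-score assignment, and gene-to-region mapping. The
# XP-CLR likelihood itself is computed upstream; any per-site sweep
# statistic can be consumed here.

#' Average per-site scores in non-overlapping windows
#'
#' Tiles each chromosome from coordinate 0 with `window_bp`-wide
#' non-overlapping windows (the terminal window may be shorter) and
#' averages the scores of the sites falling in each window (half-open:
#' a site at exactly a window boundary belongs to the next window).
#' Windows containing no sites are not returned and therefore never
#' ranked.
#'
#' @param track A `score_track` data frame (`chrom`, `pos` 0-based,
#'   `score`); see [read_score_track()].
#' @param layout A `genome_layout`.
#' @param window_bp Window size in bp (default 10000).
#' @return A `stat_windows` data frame: `chrom`, `start`, `end`,
#'   `n_sites`, `mean_score`, `terminal` flag and `percentile` of the mean
#'   score among non-empty windows; attribute `window_bp`.
#' @export
window_scores <- function(track, layout, window_bp = 10000) {
  stopifnot(window_bp > 0)
  len <- layout_length(layout, track$chrom)
  bad <- track$pos < 0 | track$pos >= len
  if (any(bad)) {
    i <- which(bad)[1]
    stop("site beyond chromosome length: ", track$chrom[i], ":",
         track$pos[i] + 1)
  }
  if (nrow(track) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sites = integer(),
                      mean_score = numeric(), terminal = logical(),
                      percentile = numeric())
    return(structure(out, class = c("stat_windows", "data.frame"),
                     window_bp = window_bp))
  }
  wstart <- (track$pos %/% window_bp) * window_bp
  key <- paste0(track$chrom, ":", wstart)
  agg <- rowsum(cbind(score = track$score, n = 1), key, reorder = FALSE)
  uk <- !duplicated(key)
  out <- data.frame(
    chrom = track$chrom[uk], start = wstart[uk], stringsAsFactors = FALSE
  )
  out$end <- pmin(out$start + window_bp, layout_length(layout, out$chrom))
  idx <- match(paste0(out$chrom, ":", out$start), rownames(agg))
  out$n_sites <- as.integer(agg[idx, "n"])
  out$mean_score <- agg[idx, "score"] / out$n_sites
  out$terminal <- out$end - out$start < window_bp
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$percentile <- rank(out$mean_score, ties.method = "max") / nrow(out)
  rownames(out) <- NULL
  structure(out, class = c("stat_windows", "data.frame"),
            window_bp = window_bp)
}

# score threshold putting a window in the top `fraction` (ties inclusive):
# the value at descending rank ceiling(fraction * n)
.top_cut <- function(scores, fraction) {
  sort(scores, decreasing = TRUE)[max(1L, ceiling(fraction * length(scores)))]
}

#' Call top-scoring windows and merge them into sweep regions
#'
#' Windows whose mean score lies in the top `top_signal_fraction`
#' genome-wide (ties at the cut included) are strong signals. Signal
#' windows that are adjacent, or separated by exactly one window whose
#' score lies in the top `gap_fraction`, are merged into a single region;
#' the maximum member mean score is assigned to the merged region. A gap
#' window with no sites is never ranked and therefore never bridges.
#'
#' @param windows A `stat_windows` data frame from [window_scores()].
#' @param top_signal_fraction Fraction defining strong signals
#'   (default 0.05).
#' @param gap_fraction Fraction defining scores eligible to bridge a
#'   single-window gap (default 0.10).
#' @return A `sweep_regions` data frame: `chrom`, `start`, `end`,
#'   `score` (max member window mean), `n_windows` (ranked windows in the
#'   span) and `n_signal` (signal windows merged).
#' @export
call_and_merge <- function(windows, top_signal_fraction = 0.05,
                           gap_fraction = 0.10) {
  window_bp <- attr(windows, "window_bp")
  if (is.null(window_bp)) stop("windows must come from window_scores()")
  n <- nrow(windows)
  if (n == 0) {
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), score = numeric(),
                                n_windows = integer(), n_signal = integer()),
                     class = c("sweep_regions", "data.frame")))
  }
  if (n < 20) {
    warning("fewer than 20 ranked windows; percentile thresholds are ",
            "degenerate")
  }
  cut5 <- .top_cut(windows$mean_score, top_signal_fraction)
  cut10 <- .top_cut(windows$mean_score, gap_fraction)
  t5 <- windows$mean_score >= cut5
  t10 <- windows$mean_score >= cut10

  regions <- list()
  for (ch in unique(windows$chrom[t5])) {
    on_ch <- windows$chrom == ch
    sig <- which(on_ch & t5)
    sig <- sig[order(windows$start[sig])]
    # bridge lookup: start -> is the ranked window at this start in T10?
    ch_starts <- windows$start[on_ch]
    ch_t10 <- t10[on_ch]
    cur_members <- sig[1]
    flush <- function(members) {
      span_start <- windows$start[members[1]]
      span_end <- windows$end[members[length(members)]]
      in_span <- which(on_ch & windows$start >= span_start &
                         windows$start < span_end)
      data.frame(chrom = ch, start = span_start, end = span_end,
                 score = max(windows$mean_score[in_span]),
                 n_windows = length(in_span),
                 n_signal = length(members), stringsAsFactors = FALSE)
    }
    for (w in sig[-1]) {
      prev <- cur_members[length(cur_members)]
      gap_windows <- (windows$start[w] - windows$start[prev]) / window_bp - 1
      bridge <- FALSE
      if (gap_windows == 0) {
        bridge <- TRUE
      } else if (gap_windows == 1) {
        mid <- match(windows$start[prev] + window_bp, ch_starts)
        bridge <- !is.na(mid) && ch_t10[mid]
      }
      if (bridge) {
        cur_members <- c(cur_members, w)
      } else {
        regions[[length(regions) + 1]] <- flush(cur_members)
        cur_members <- w
      }
    }
    regions[[length(regions) + 1]] <- flush(cur_members)
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sweep_regions", "data.frame"),
            window_bp = window_bp)
}

#' Map genes (with flanks) onto regions
#'
#' A gene is assigned to a region when its span extended by `flank_bp` on
#' both sides intersects the region interval (half-open: a flank that
#' merely touches a region boundary does not intersect). A gene may map to
#' several regions.
#'
#' @param regions Data frame with `chrom`, `start`, `end` (e.g.
#'   `sweep_regions`).
#' @param genes A `gene_models` data frame.
#' @param flank_bp Flank size in bp added to both gene ends
#'   (default 2000).
#' @return Data frame with one row per (region, gene) assignment:
#'   `region`, `chrom`, `start`, `end`, `gene_id`.
#' @export
genes_in_regions <- function(regions, genes, flank_bp = 2000) {
  stopifnot(flank_bp >= 0)
  hits <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    g <- genes[genes$chrom == r$chrom &
                 (genes$start - flank_bp) < r$end &
                 r$start < (genes$end + flank_bp), , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    data.frame(region = i, chrom = r$chrom, start = r$start, end = r$end,
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(region = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      gene_id = character())
  }
  rownames(out) <- NULL
  out
}
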