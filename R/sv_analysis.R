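# Structural-variant landscape statistics: per-type and per-sample
# tallies, genomic-context annotation (genic > 2 kb flank > intergenic),
# and sliding-window hotspot detection by breakpoint density.

#' Summarize an SV set
#'
#' @param sv An `sv_set` (typically already filtered by
#'   [read_sv_vcf()]).
#' @return List with `type_totals` (named, DEL/DUP/INS), `total` (their
#'   sum), and `per_sample` (data frame: SVs carried — at least one alt
#'   allele — per sample, with per-type counts and deletion fraction).
#' @export
sv_summary <- function(sv) {
  stopifnot(inherits(sv, "sv_set"))
  types <- c("DEL", "DUP", "INS")
  type_totals <- vapply(types, function(t) sum(sv$records$type == t), 0L)
  carried <- !is.na(sv$geno) & sv$geno > 0
  per_type <- sapply(types, function(t) {
    colSums(carried[sv$records$type == t, , drop = FALSE])
  })
  count <- colSums(carried)
  per_sample <- data.frame(
    sample = sv$samples, count = count,
    del = per_type[, "DEL"], dup = per_type[, "DUP"], ins = per_type[, "INS"],
    del_fraction = ifelse(count > 0, per_type[, "DEL"] / count, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(type_totals = type_totals, total = sum(type_totals),
       per_sample = per_sample)
}

#' Annotate the genomic context of each SV
#'
#' Assigns exactly one context per SV with precedence genic > 2 kb flank >
#' intergenic: genic when the SV interval intersects any gene span;
#' otherwise flank when it intersects the `flank_bp` region immediately
#' up- or downstream of any gene; otherwise intergenic. DEL/DUP use their
#' full interval; INS uses the insertion point.
#'
#' @param sv An `sv_set`.
#' @param genes A `gene_models` data frame.
#' @param flank_bp Flank width in bp (default 2000).
#' @return Data frame with one row per SV: `sv_id`, `type`, `context`
#'   (`genic`/`flank_2kb`/`intergenic` — named after the default flank)
#'   and `genes` (comma-joined ids justifying the call, `NA` for
#'   intergenic).
#' @export
annotate_context <- function(sv, genes, flank_bp = 2000) {
  stopifnot(inherits(sv, "sv_set"), flank_bp >= 0)
  r <- sv$records
  s <- r$start
  e <- ifelse(r$type == "INS", r$start + 1, r$end)  # point for insertions
  context <- character(nrow(r))
  hit_genes <- rep(NA_character_, nrow(r))
  for (ch in unique(r$chrom)) {
    gi <- which(genes$chrom == ch)
    vi <- which(r$chrom == ch)
    if (length(gi) == 0) {
      context[vi] <- "intergenic"
      next
    }
    gs <- genes$start[gi]
    ge <- genes$end[gi]
    ids <- genes$gene_id[gi]
    for (v in vi) {
      genic <- s[v] < ge & gs < e[v]
      if (any(genic)) {
        context[v] <- "genic"
        hit_genes[v] <- paste(ids[genic], collapse = ",")
        next
      }
      up <- s[v] < gs & (gs - flank_bp) < e[v]
      down <- s[v] < (ge + flank_bp) & ge < e[v]
      flank <- up | down
      if (any(flank)) {
        context[v] <- "flank_2kb"
        hit_genes[v] <- paste(ids[flank], collapse = ",")
      } else {
        context[v] <- "intergenic"
      }
    }
  }
  data.frame(sv_id = r$sv_id, type = r$type, context = context,
             genes = hit_genes, row.names = NULL, stringsAsFactors = FALSE)
}

# breakpoint positions of an SV set: both interval endpoints for DEL/DUP
# (the right endpoint as the last affected base), the single point for INS
sv_breakpoints <- function(sv) {
  r <- sv$records
  two_ended <- r$type %in% c("DEL", "DUP")
  data.frame(
    sv_id = c(r$sv_id, r$sv_id[two_ended]),
    chrom = c(r$chrom, r$chrom[two_ended]),
    pos = c(r$start, pmax(r$end[two_ended] - 1, r$start[two_ended])),
    stringsAsFactors = FALSE
  )
}

#' Detect SV hotspots by windowed breakpoint density
#'
#' Counts SV breakpoints (both endpoints of DEL/DUP, the single point of
#' INS) in sliding windows of `window_bp` advanced by `step_bp`; a
#' breakpoint is counted in every window containing it. Windows are ranked
#' by breakpoint count; the top `top_fraction` (ties at the cut included)
#' are hotspot windows, and overlapping or abutting hotspot windows are
#' merged into maximal hotspot regions. Each SV with a breakpoint in a
#' hotspot region is assigned to exactly one region (that of its leftmost
#' captured breakpoint).
#'
#' @param sv An `sv_set`.
#' @param layout A `genome_layout`.
#' @param window_bp Window size in bp (default 200000).
#' @param step_bp Step size in bp (default 100000; must divide
#'   `window_bp`, and be no larger).
#' @param top_fraction Fraction of windows designated hotspots
#'   (default 0.05).
#' @return List with `regions` (data frame: `chrom`, `start`, `end`,
#'   `n_windows`, `n_breakpoints`, `sv_ids` list-column of captured SV
#'   ids), `windows` (all windows with counts and hotspot flag),
#'   `capture_fraction` (fraction of SVs with >= 1 breakpoint in a
#'   region) and `genome_fraction` (bp covered by regions / genome bp).
#' @export
hotspot_scan <- function(sv, layout, window_bp = 200000, step_bp = 100000,
                         top_fraction = 0.05) {
  stopifnot(inherits(sv, "sv_set"), top_fraction > 0, top_fraction <= 1)
  if (step_bp > window_bp) stop("window smaller than step")
  if (window_bp %% step_bp != 0) stop("step must divide the window evenly")
  bp <- sv_breakpoints(sv)
  len <- layout_length(layout, bp$chrom)
  if (any(bp$pos < 0 | bp$pos >= len)) stop("breakpoint beyond chromosome")

  wins <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    starts <- seq(0, layout$length[i] - 1, by = step_bp)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + window_bp, layout$length[i]),
               stringsAsFactors = FALSE)
  }))
  # each breakpoint falls in every window whose start is in
  # (pos - window_bp, pos], i.e. window_bp/step_bp candidate starts
  k <- window_bp %/% step_bp
  counts <- integer(nrow(wins))
  wkey <- paste0(wins$chrom, ":", wins$start)
  for (j in seq_len(k) - 1L) {
    wstart <- ((bp$pos %/% step_bp) - j) * step_bp
    ok <- wstart >= 0
    idx <- match(paste0(bp$chrom, ":", wstart)[ok], wkey)
    tab <- table(idx)
    counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
      as.integer(tab)
  }
  wins$count <- counts
  cut <- sort(counts, decreasing = TRUE)[
    max(1L, ceiling(top_fraction * nrow(wins)))]
  # a window with no breakpoints is never a hotspot, even when sparse
  # genomes push the percentile cut to zero
  wins$hotspot <- counts >= cut & counts > 0L
  # deterministic report order: count desc, then chrom, start
  ord <- order(-wins$count, wins$chrom, wins$start)
  ranked <- wins[ord, , drop = FALSE]

  hs <- wins[wins$hotspot, , drop = FALSE]
  hs <- hs[order(hs$chrom, hs$start), , drop = FALSE]
  regions <- list()
  if (nrow(hs) > 0) {
    cur <- hs[1, c("chrom", "start", "end")]
    cur$n_windows <- 1L
    for (i in seq_len(nrow(hs))[-1]) {
      if (hs$chrom[i] == cur$chrom && hs$start[i] <= cur$end) {
        cur$end <- max(cur$end, hs$end[i])
        cur$n_windows <- cur$n_windows + 1L
      } else {
        regions[[length(regions) + 1]] <- cur
        cur <- hs[i, c("chrom", "start", "end")]
        cur$n_windows <- 1L
      }
    }
    regions[[length(regions) + 1]] <- cur
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_windows = integer())
  rownames(regions) <- NULL

  # assign each SV to the region of its leftmost captured breakpoint
  bp <- bp[order(bp$chrom, bp$pos), , drop = FALSE]
  region_of <- rep(NA_integer_, nrow(bp))
  for (i in seq_len(nrow(regions))) {
    inr <- bp$chrom == regions$chrom[i] & bp$pos >= regions$start[i] &
      bp$pos < regions$end[i]
    region_of[inr & is.na(region_of)] <- i
  }
  first_hit <- tapply(region_of, bp$sv_id, function(z) {
    z <- z[!is.na(z)]
    if (length(z)) z[1] else NA_integer_
  })
  captured <- first_hit[!is.na(first_hit)]
  regions$sv_ids <- lapply(seq_len(nrow(regions)), function(i) {
    names(captured)[captured == i]
  })
  regions$n_breakpoints <- vapply(seq_len(nrow(regions)), function(i) {
    sum(region_of == i, na.rm = TRUE)
  }, 0L)

  list(
    regions = regions,
    windows = ranked,
    capture_fraction = length(captured) / nrow(sv$records),
    genome_fraction = sum(regions$end - regions$start) / sum(layout$length)
  )
}
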