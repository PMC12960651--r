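# Gene-frequency selection screen on the PAV matrix: two-sided Fisher's
# exact test per gene between two trait groups, Benjamini-Hochberg FDR,
# and a log2 fold-change gate; plus hypergeometric term enrichment on
# user-supplied annotation tables.

#' Two-sided Fisher exact p-value for a 2x2 presence table
#'
#' Conditional on both margins, sums the probabilities of all tables whose
#' hypergeometric probability does not exceed that of the observed table
#' (the standard two-sided convention, as in `stats::fisher.test`; a small
#' relative tolerance guards ties against floating-point noise).
#'
#' @param a,n_a Presence count and group size in group A.
#' @param b,n_b Presence count and group size in group B. All four
#'   arguments are vectorized.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
fisher_two_sided_p <- function(a, n_a, b, n_b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0),
            all(a <= n_a), all(b <= n_b))
  n_a <- rep_len(n_a, length(a))
  n_b <- rep_len(n_b, length(a))
  mapply(function(ai, nai, bi, nbi) {
    k <- ai + bi
    support <- max(0, k - nbi):min(nai, k)
    d <- stats::dhyper(support, nai, nbi, k)
    obs <- d[match(ai, support)]
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, a, n_a, b, n_b)
}

#' Gene-frequency contrast between two trait groups
#'
#' For each gene, tests whether its presence frequency differs between the
#' two groups with a two-sided Fisher exact test on the 2x2 table
#' `[[a, nA-a], [b, nB-b]]`, adjusts p-values across tested genes by
#' Benjamini-Hochberg, and computes a Haldane-Anscombe-stabilized log2 fold
#' change of presence frequencies,
#' `log2((a+0.5)/(nA+1)) - log2((b+0.5)/(nB+1))`, so groups with zero
#' presences still yield finite values. A gene is flagged significant when
#' `fdr < fdr_cutoff` and `|log2_fold_change| > lfc_cutoff`.
#'
#' Genes fixed present or fixed absent across *all* contrasted samples are
#' untestable: they are reported with `p_value = 1`, excluded from the BH
#' adjustment (`fdr = NA`) and logged.
#'
#' @param pav A `pav_matrix`.
#' @param design Design data frame (`sample`, `group`), see
#'   [read_design()].
#' @param group_a,group_b The two group labels to contrast (log2 fold
#'   change is A relative to B).
#' @param fdr_cutoff FDR threshold of the significance gate
#'   (default 0.001).
#' @param lfc_cutoff Absolute log2-fold-change threshold of the gate
#'   (default 1).
#' @return Data frame with one row per gene: `gene_id`, `a`, `n_a`, `b`,
#'   `n_b`, `p_value`, `fdr`, `log2_fold_change`, `tested`, `significant`.
#' @export
fisher_presence_test <- function(pav, design, group_a, group_b,
                                 fdr_cutoff = 0.001, lfc_cutoff = 1) {
  stopifnot(inherits(pav, "pav_matrix"))
  grp <- design_groups(design, group_a, group_b, colnames(pav))
  if (length(grp$a) < 2 || length(grp$b) < 2) {
    stop("both groups need at least 2 samples")
  }
  n_a <- length(grp$a)
  n_b <- length(grp$b)
  a <- rowSums(pav[, grp$a, drop = FALSE])
  b <- rowSums(pav[, grp$b, drop = FALSE])

  tested <- !((a == n_a & b == n_b) | (a == 0 & b == 0))
  if (any(!tested)) {
    message("fisher_presence_test: ", sum(!tested),
            " gene(s) fixed across all contrasted samples excluded from FDR")
  }
  p <- rep(1, length(a))
  if (any(tested)) {
    # many genes share the same 2x2 table; compute each unique table once
    key <- paste(a[tested], b[tested])
    uk <- !duplicated(key)
    pu <- fisher_two_sided_p(a[tested][uk], n_a, b[tested][uk], n_b)
    p[tested] <- pu[match(key, key[uk])]
  }
  fdr <- rep(NA_real_, length(a))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  lfc <- log2((a + 0.5) / (n_a + 1)) - log2((b + 0.5) / (n_b + 1))
  data.frame(
    gene_id = rownames(pav), a = a, n_a = n_a, b = b, n_b = n_b,
    p_value = p, fdr = fdr, log2_fold_change = lfc, tested = tested,
    significant = tested & !is.na(fdr) & fdr < fdr_cutoff &
      abs(lfc) > lfc_cutoff,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, tests over-representation of the term among a
#' gene set relative to a background universe with the upper-tail
#' hypergeometric probability of observing at least the seen number of
#' hits, then adjusts across terms by Benjamini-Hochberg.
#'
#' @param gene_set Character vector of genes of interest (must be a subset
#'   of `background`).
#' @param term_table Data frame mapping genes to terms, columns `gene` and
#'   `term` (optionally `term_name`).
#' @param background Character vector: the gene universe. Defaults to all
#'   genes in `term_table`; a typical choice is all genes of the PAV
#'   matrix.
#' @return Data frame with one row per term: `term`, hits `k`, set size
#'   `K`, background hits `m`, background size `M`, `p_value`, `fdr`.
#' @export
hypergeometric_enrichment <- function(gene_set, term_table,
                                      background = NULL) {
  stopifnot(all(c("gene", "term") %in% names(term_table)))
  if (is.null(background)) background <- unique(term_table$gene)
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of background")
  }
  tt <- term_table[term_table$gene %in% background, , drop = FALSE]
  terms <- unique(tt$term)
  M <- length(background)
  K <- length(gene_set)
  res <- do.call(rbind, lapply(terms, function(tm) {
    genes_tm <- unique(tt$gene[tt$term == tm])
    m <- length(genes_tm)
    k <- length(intersect(gene_set, genes_tm))
    data.frame(term = tm, k = k, K = K, m = m, M = M,
               p_value = stats::phyper(k - 1, m, M - m, K,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if ("term_name" %in% names(tt)) {
    res$term_name <- tt$term_name[match(res$term, tt$term)]
  }
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value), , drop = FALSE]
}
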