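# Gene presence/absence (PAV) calling and pan-genome classification.
#
# The presence rule mirrors SGSGeneLoss-style calling: a gene is present in
# an accession when reads at or above a minimum depth (minCov, typically 2)
# cover strictly more than a cutoff fraction (lostCutoff, typically 0.2) of
# its exon bases. This module consumes the per-gene per-sample covered
# fraction directly; depth computation from alignments is upstream of it.

#' Call gene presence from exon-coverage fractions
#'
#' A gene is present in a sample iff its covered fraction strictly exceeds
#' `lost_cutoff` ("more than" the cutoff; a fraction exactly at the cutoff
#' is called absent).
#'
#' @param coverage Either a long data frame with columns `gene`, `sample`,
#'   `covered_fraction` (one row per gene-sample pair, complete), or a
#'   numeric genes x samples matrix of covered fractions.
#' @param lost_cutoff Presence threshold on the covered fraction
#'   (default 0.2).
#' @return A `pav_matrix`: integer 0/1 matrix, genes x samples
#'   (uncategorized; see [classify_genes()]).
#' @examples
#' cov <- matrix(c(0.5, 0.2, 0, 1), 2, 2,
#'               dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' call_presence(cov)
#' @export
call_presence <- function(coverage, lost_cutoff = 0.2) {
  stopifnot(lost_cutoff >= 0, lost_cutoff <= 1)
  if (is.data.frame(coverage)) {
    stopifnot(all(c("gene", "sample", "covered_fraction") %in%
                    names(coverage)))
    genes <- unique(coverage$gene)
    samples <- unique(coverage$sample)
    if (nrow(coverage) != length(genes) * length(samples) ||
        anyDuplicated(coverage[c("gene", "sample")])) {
      stop("coverage table must be complete: one row per gene x sample")
    }
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(coverage$gene, genes), match(coverage$sample, samples))] <-
      coverage$covered_fraction
  } else {
    m <- as.matrix(coverage)
  }
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop("covered fractions must be in [0, 1] with no missing values")
  }
  pav <- matrix(as.integer(m > lost_cutoff), nrow(m), ncol(m),
                dimnames = dimnames(m))
  structure(pav, class = c("pav_matrix", class(pav)),
            categorized = FALSE)
}

#' Construct a PAV matrix from a 0/1 matrix
#'
#' @param m Genes x samples matrix of 0/1 presence indicators with
#'   dimnames.
#' @return A `pav_matrix`.
#' @export
as_pav_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0L, 1L))) stop("PAV matrix entries must be 0/1")
  if (is.null(rownames(m))) rownames(m) <- paste0("gene_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sample_", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  structure(m, class = c("pav_matrix", class(m)), categorized = FALSE)
}

#' Classify pan-genome genes as core, dispensable or private
#'
#' With n samples, a gene present in all n is core, in exactly one is
#' private, and in 2..n-1 is dispensable — a disjoint partition of all
#' genes present in at least one sample. Genes absent from every sample
#' cannot arise from real presence calling and are dropped with a message.
#'
#' @param pav A `pav_matrix`.
#' @return The matrix (possibly with all-absent rows removed) with a
#'   `category` attribute; see [pav_category()] and [category_counts()].
#' @export
classify_genes <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"))
  n <- ncol(pav)
  if (n < 2) stop("classification needs at least 2 samples")
  occ <- rowSums(pav)
  if (any(occ == 0)) {
    message("classify_genes: dropping ", sum(occ == 0),
            " gene(s) absent from all samples")
    m <- unclass(pav)[occ > 0, , drop = FALSE]
    pav <- structure(m, class = c("pav_matrix", class(m)),
                     categorized = FALSE)
    occ <- rowSums(pav)
  }
  category <- ifelse(occ == n, "core", ifelse(occ == 1, "private",
                                              "dispensable"))
  attr(pav, "category") <- factor(category,
                                  levels = c("core", "dispensable", "private"))
  attr(pav, "categorized") <- TRUE
  pav
}

#' Per-gene category labels of a classified PAV matrix
#' @param pav A categorized `pav_matrix`.
#' @return Factor of `core`/`dispensable`/`private`, one per gene.
#' @export
pav_category <- function(pav) {
  cat <- attr(pav, "category")
  if (is.null(cat)) stop("PAV matrix is not categorized; run classify_genes()")
  cat
}

#' Category totals of a classified PAV matrix
#' @param pav A categorized `pav_matrix`.
#' @return Named integer vector (`core`, `dispensable`, `private`).
#' @export
category_counts <- function(pav) {
  table(pav_category(pav))
}

#' Per-accession gene tallies
#'
#' For each sample: total genes present plus the per-category breakdown
#' and fractions (which sum to 1 per sample).
#'
#' @param pav A categorized `pav_matrix`.
#' @return Data frame with one row per sample.
#' @export
accession_gene_counts <- function(pav) {
  cat <- pav_category(pav)
  total <- colSums(pav)
  per_cat <- sapply(levels(cat), function(lv) {
    colSums(pav[cat == lv, , drop = FALSE])
  })
  data.frame(
    sample = colnames(pav), total = total,
    core = per_cat[, "core"], dispensable = per_cat[, "dispensable"],
    private = per_cat[, "private"],
    core_fraction = per_cat[, "core"] / total,
    dispensable_fraction = per_cat[, "dispensable"] / total,
    private_fraction = per_cat[, "private"] / total,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pan/core saturation curves by sample permutation
#'
#' For each random ordering of the samples, records the cumulative number
#' of distinct genes (pan) and universally shared genes (core) as samples
#' are added one at a time, then summarizes across permutations. Per
#' permutation, the pan curve is non-decreasing and the core curve
#' non-increasing; at k = n they equal the observed pan-gene total and core
#' count.
#'
#' @param pav A `pav_matrix`.
#' @param n_permutations Number of random sample orderings (default 100).
#' @param seed Integer RNG seed (required, for reproducibility).
#' @return A `saturation_curve`: list with `summary` (per k: mean and sd of
#'   pan and core counts) and `pan`/`core` per-permutation matrices
#'   (permutations x k).
#' @export
saturation_curves <- function(pav, n_permutations = 100, seed) {
  stopifnot(inherits(pav, "pav_matrix"), n_permutations >= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n <- ncol(pav)
  pan <- matrix(0L, n_permutations, n)
  core <- matrix(0L, n_permutations, n)
  present <- pav > 0
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    un <- present[, ord[1]]
    inter <- un
    pan[p, 1] <- sum(un)
    core[p, 1] <- sum(inter)
    for (k in seq_len(n)[-1]) {
      col <- present[, ord[k]]
      un <- un | col
      inter <- inter & col
      pan[p, k] <- sum(un)
      core[p, k] <- sum(inter)
    }
  }
  summary <- data.frame(
    k = seq_len(n),
    pan_mean = colMeans(pan), pan_sd = apply(pan, 2, stats::sd),
    core_mean = colMeans(core), core_sd = apply(core, 2, stats::sd)
  )
  structure(list(summary = summary, pan = pan, core = core),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  n <- nrow(x$summary)
  cat("Saturation curves over", nrow(x$pan), "permutations,",
      n, "sample sizes\n")
  cat(sprintf("  pan:  %.0f (k=1) -> %.0f (k=%d)\n",
              x$summary$pan_mean[1], x$summary$pan_mean[n], n))
  cat(sprintf("  core: %.0f (k=1) -> %.0f (k=%d)\n",
              x$summary$core_mean[1], x$summary$core_mean[n], n))
  invisible(x)
}

# guarded nlsLM fit returning a parameter list or a non-converged record
.fit_or_diag <- function(formula, data, start, lower = NULL) {
  fit <- tryCatch(
    if (is.null(lower)) {
      minpack.lm::nlsLM(formula, data = data, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(converged = FALSE, message = conditionMessage(fit)))
  }
  list(converged = TRUE, coefficients = stats::coef(fit),
       fitted = stats::fitted(fit), residuals = stats::residuals(fit))
}

#' Fit saturation-curve models
#'
#' Fits the mean pan curve with the power law `P(k) = A * k^gamma + C` and
#' the mean core curve with the exponential decay
#' `F(k) = A * exp(-k / tau) + C`, the conventional functional forms for
#' pan-genome openness. A curve that is (numerically) constant is reported
#' directly with `A = 0` rather than fitted; non-convergence is reported
#' with diagnostics, never raised as an error.
#'
#' @param curve A `saturation_curve`.
#' @return List with `pan` and `core` fit records (each with `converged`,
#'   `coefficients`, `fitted`, `residuals`, or a failure `message`).
#' @export
fit_saturation <- function(curve) {
  s <- curve$summary
  if (nrow(s) < 4) stop("need at least 4 sample sizes to fit")
  const_fit <- function(value) {
    list(converged = TRUE,
         coefficients = c(A = 0, C = value),
         fitted = rep(value, nrow(s)), residuals = rep(0, nrow(s)),
         note = "constant curve, no model fitted")
  }
  pan <- if (stats::sd(s$pan_mean) < 1e-9) const_fit(s$pan_mean[1]) else {
    rng <- s$pan_mean[nrow(s)] - s$pan_mean[1]
    .fit_or_diag(pan_mean ~ A * k^gamma + C, s,
                 start = list(A = max(rng, 1), gamma = 0.3,
                              C = s$pan_mean[1] - max(rng, 1)))
  }
  core <- if (stats::sd(s$core_mean) < 1e-9) const_fit(s$core_mean[1]) else {
    rng <- s$core_mean[1] - s$core_mean[nrow(s)]
    .fit_or_diag(core_mean ~ A * exp(-k / tau) + C, s,
                 start = list(A = max(rng, 1), tau = 3,
                              C = s$core_mean[nrow(s)]),
                 lower = c(A = 0, tau = 1e-3, C = -Inf))
  }
  list(pan = pan, core = core)
}
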