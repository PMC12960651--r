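# Population structure from the binary PAV matrix: principal components
# of the centered gene-presence profiles and an average-linkage tree on
# Jaccard distances, exported as Newick.

#' PCA of the binary PAV matrix
#'
#' Samples are observations, genes are features. Columns (genes) are
#' centered and not scaled — standard practice for binary PAV ordination.
#' Component signs are fixed deterministically: the loading of largest
#' magnitude on each component is made positive.
#'
#' @param pav A `pav_matrix` with at least 2 samples.
#' @param n_components Number of components to keep (default 5, truncated
#'   to the available rank).
#' @return A `pav_ordination`: list with `coordinates` (samples x
#'   components), `explained_variance` (fraction per kept component,
#'   non-increasing) and `loadings`.
#' @export
pav_pca <- function(pav, n_components = 5) {
  stopifnot(inherits(pav, "pav_matrix"), ncol(pav) >= 2)
  x <- t(unclass(pav)) * 1.0  # samples x genes
  n_components <- min(n_components, nrow(x) - 1, ncol(x))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  if (total_var < .Machine$double.eps) {
    coords <- matrix(0, nrow(x), n_components,
                     dimnames = list(rownames(x),
                                     paste0("PC", seq_len(n_components))))
    return(structure(list(coordinates = coords,
                          explained_variance = rep(0, n_components),
                          loadings = NULL),
                     class = "pav_ordination"))
  }
  keep <- seq_len(min(n_components, ncol(pr$rotation)))
  rot <- pr$rotation[, keep, drop = FALSE]
  coords <- pr$x[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  structure(list(coordinates = coords,
                 explained_variance = (pr$sdev^2 / total_var)[keep],
                 loadings = rot),
            class = "pav_ordination")
}

#' @export
print.pav_ordination <- function(x, ...) {
  cat("PAV ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "components\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Jaccard distance matrix between samples' presence sets
#'
#' `d(A, B) = 1 - |A ∩ B| / |A ∪ B|` over each pair's present-gene sets.
#' Two samples with empty presence sets are at distance 0 (with a
#' warning), a convention fixed because the ratio is undefined there.
#'
#' @param pav A `pav_matrix`.
#' @return Symmetric matrix of Jaccard distances, zero diagonal.
#' @export
pav_jaccard <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"))
  x <- t(unclass(pav)) * 1.0
  inter <- tcrossprod(x)
  sizes <- rowSums(x)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  if (any(un == 0)) {
    warning("sample pair(s) with empty presence sets; distance set to 0")
    d[un == 0] <- 0
  }
  diag(d) <- 0
  d
}

#' Distance-based tree of accessions from the PAV matrix
#'
#' Agglomerative clustering (average linkage by default) on the Jaccard
#' distance matrix, returned with its Newick serialization for downstream
#' tree tooling.
#'
#' @param pav A `pav_matrix` with at least 3 samples.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default "average").
#' @return A `pav_tree`: list with `dist` (matrix), `hclust`, `phylo`
#'   (ape) and `newick` (character).
#' @export
pav_distance_tree <- function(pav, linkage = "average") {
  stopifnot(inherits(pav, "pav_matrix"), ncol(pav) >= 3)
  d <- pav_jaccard(pav)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(dist = d, hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy)),
            class = "pav_tree")
}

#' @export
print.pav_tree <- function(x, ...) {
  cat("PAV distance tree over", nrow(x$dist), "samples (",
      x$hclust$method, "linkage )\n")
  invisible(x)
}

#' Write a tree to a Newick file
#' @param tree A `pav_tree` or `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "pav_tree")) tree$phylo else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}
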