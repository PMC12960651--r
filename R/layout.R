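#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosomes (or scaffolds) with
#' their lengths in base pairs. All windowing operations tile chromosomes
#' from coordinate 0 using this layout; all internal coordinates in the
#' package are 0-based, half-open.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Numeric vector of chromosome lengths in bp (all > 0).
#' @return A `genome_layout` data frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1.5e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have the same length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_layout", "data.frame")
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

# length lookup with error on unknown chromosome
layout_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in layout: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  layout$length[i]
}
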