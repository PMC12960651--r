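# Gene models, score tracks, design tables and region BED files.
# Gene models come in as GFF3 or BED12 and are normalized to 0-based
# half-open intervals with a sorted, non-overlapping exon list per gene.

new_gene_models <- function(gene_id, chrom, strand, start, end, exons) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = start, end = end, stringsAsFactors = FALSE)
  df$exons <- exons
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("overlapping exons in gene ", df$gene_id[i])
    }
    if (ex[1, 1] < df$start[i] || ex[nrow(ex), 2] > df$end[i]) {
      stop("exon outside gene span in gene ", df$gene_id[i])
    }
    df$exons[[i]] <- ex
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input uses `gene` features with `exon` children (linked by
#' `Parent`, through `mRNA` features if present); BED input uses the block
#' fields for exons (a BED6 line is one single-exon gene). Coordinates are
#' normalized to the package's internal 0-based half-open convention.
#' Genes with no exons are dropped with a warning.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return A `gene_models` data frame (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`, list-column `exons` of 2-column matrices), sorted by
#'   chromosome and start.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0) stop("no records in ", path)
    if (!is.null(gr$blocks)) {
      ex <- rtracklayer::blocks(gr)  # absolute coordinates
      exons <- lapply(seq_along(gr), function(i) {
        b <- ex[[i]]
        cbind(start = BiocGenerics::start(b) - 1, end = BiocGenerics::end(b))
      })
    } else {
      exons <- lapply(seq_along(gr), function(i) {
        cbind(start = BiocGenerics::start(gr)[i] - 1,
              end = BiocGenerics::end(gr)[i])
      })
    }
    ids <- if (is.null(gr$name)) paste0("gene_", seq_along(gr)) else gr$name
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    return(new_gene_models(ids, as.character(GenomeInfoDb::seqnames(gr)),
                           strand, BiocGenerics::start(gr) - 1,
                           BiocGenerics::end(gr), exons))
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0) stop("no gene features in ", path)
  ex <- gr[typ == "exon"]
  # map exons to genes, possibly through an mRNA level
  mrna <- gr[typ == "mRNA"]
  mrna_parent <- if (length(mrna)) {
    stats::setNames(vapply(mrna$Parent, `[`, "", 1), mrna$ID)
  } else c()
  ex_parent <- vapply(ex$Parent, `[`, "", 1)
  hit <- ex_parent %in% names(mrna_parent)
  ex_parent[hit] <- mrna_parent[ex_parent[hit]]

  ids <- genes$ID
  if (is.null(ids)) stop("GFF3 gene features lack ID attributes")
  exons <- lapply(ids, function(id) {
    sub <- ex[ex_parent == id]
    if (length(sub) == 0) return(NULL)
    cbind(start = BiocGenerics::start(sub) - 1, end = BiocGenerics::end(sub))
  })
  no_exon <- vapply(exons, is.null, TRUE)
  if (any(no_exon)) {
    warning("dropping ", sum(no_exon), " gene(s) with zero exons: ",
            paste(utils::head(ids[no_exon], 5), collapse = ", "))
  }
  keep <- !no_exon
  strand <- as.character(BiocGenerics::strand(genes))[keep]
  strand[strand == "*"] <- "+"
  new_gene_models(ids[keep], as.character(GenomeInfoDb::seqnames(genes))[keep],
                  strand, BiocGenerics::start(genes)[keep] - 1,
                  BiocGenerics::end(genes)[keep], exons[keep])
}

#' Write gene models as BED12
#'
#' Inverse of [read_gene_models()] for the BED dialect; round trips are
#' lossless on the interval set.
#'
#' @param genes A `gene_models` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    sizes <- ex[, 2] - ex[, 1]
    rel <- ex[, 1] - genes$start[i]
    paste(genes$chrom[i], format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE), genes$gene_id[i], 0,
          genes$strand[i],
          format(genes$start[i], scientific = FALSE),
          format(genes$end[i], scientific = FALSE), "0",
          nrow(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(rel, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes A `gene_models` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    out <- c(out, paste(g$chrom, "pangenpop", "gene",
                        format(g$start + 1, scientific = FALSE),
                        format(g$end, scientific = FALSE), ".", g$strand, ".",
                        paste0("ID=", g$gene_id), sep = "\t"))
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      out <- c(out, paste(g$chrom, "pangenpop", "exon",
                          format(ex[j, 1] + 1, scientific = FALSE),
                          format(ex[j, 2], scientific = FALSE), ".",
                          g$strand, ".",
                          paste0("ID=", g$gene_id, ".exon", j,
                                 ";Parent=", g$gene_id), sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a per-site score track
#'
#' Expects a TSV with header columns `chrom`, `pos` (1-based) and `score`
#' (e.g. per-SNP XP-CLR likelihood scores). Positions are converted to
#' 0-based and the track is sorted (with a warning if the input was not).
#'
#' @param path Path to the TSV.
#' @return A `score_track` data frame (`chrom`, `pos`, `score`).
#' @export
read_score_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty score track: ", path)
    return(structure(data.frame(chrom = character(), pos = numeric(),
                                score = numeric()),
                     class = c("score_track", "data.frame")))
  }
  stopifnot(all(c("chrom", "pos", "score") %in% names(df)))
  if (any(!is.finite(df$score))) stop("non-finite scores in ", path)
  df <- data.frame(chrom = as.character(df$chrom), pos = df$pos - 1,
                   score = df$score, stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$pos)
  if (any(ord != seq_along(ord))) {
    warning("score track not sorted; sorting")
  }
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("score_track", "data.frame"))
}

#' Write a score track TSV (1-based positions)
#' @param track A `score_track` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  out <- data.frame(chrom = track$chrom, pos = as.integer(track$pos + 1),
                    score = track$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group design table
#'
#' TSV with header columns `sample` and `group`. Each sample may appear at
#' most once; analyses contrast two named groups drawn from this table.
#'
#' @param path Path to the TSV.
#' @return A data frame with columns `sample` and `group`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(df)))
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample(s) in design: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  df[c("sample", "group")]
}

#' Write a design table
#' @param design Data frame with `sample` and `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# samples of the two contrasted groups, validated against available samples
design_groups <- function(design, group_a, group_b, samples) {
  a <- design$sample[design$group == group_a]
  b <- design$sample[design$group == group_b]
  if (length(a) == 0 || length(b) == 0) {
    stop("both contrast groups must be non-empty")
  }
  miss <- setdiff(c(a, b), samples)
  if (length(miss) > 0) {
    stop("design sample(s) absent from data: ", paste(miss, collapse = ", "))
  }
  list(a = a, b = b)
}

#' Write genomic regions as BED
#'
#' Emits 0-based half-open BED lines with an optional name and score column.
#'
#' @param regions Data frame with `chrom`, `start`, `end` and optionally
#'   `name` and `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  name <- if ("name" %in% names(regions)) regions$name else
    paste0("region_", seq_len(nrow(regions)))
  score <- if ("score" %in% names(regions)) regions$score else 0
  lines <- paste(regions$chrom,
                 format(regions$start, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 name, score, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of regions
#' @param path Path to a BED3+ file.
#' @return Data frame with `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

#' Read a per-gene per-sample exon-coverage table
#'
#' TSV with header columns `gene`, `sample` and `covered_fraction` (the
#' fraction of the gene's exon bases covered at or above the caller's
#' minimum read depth). This is the input to [call_presence()].
#'
#' @param path Path to the TSV.
#' @return Data frame with the three columns, values validated to `[0, 1]`.
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "sample", "covered_fraction") %in% names(df)))
  if (any(df$covered_fraction < 0 | df$covered_fraction > 1)) {
    stop("covered_fraction outside [0, 1]")
  }
  df[c("gene", "sample", "covered_fraction")]
}

#' Write a coverage table TSV
#' @param coverage Data frame with `gene`, `sample`, `covered_fraction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
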