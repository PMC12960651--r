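# Seeded generator of a complete synthetic pan-genome population study
# with planted ground truth: genome layout and gene models, a structured
# presence/absence matrix with planted differential genes, exon-coverage
# fractions, Balding-Nichols-differentiated SNPs, an XP-CLR-style score
# track with planted sweep peaks, and a deletion-dominated SV set with
# planted hotspot clusters. Every pipeline stage can therefore be
# exercised end-to-end, with recovery measured against the truth, without
# any external data.

#' Synthetic-study configuration
#'
#' Defaults emulate the scale and structure of a 27-accession fruit-tree
#' resequencing panel at desk scale: 3 subgroups of 3/3/21 accessions, an
#' 11-chromosome ~20 Mb toy genome, ~2,000 genes whose dispensable
#' fraction follows a U-shaped Beta(0.3, 0.3) frequency law, core /
#' dispensable / private proportions matching a typical plant pan-genome
#' (~76/23/1%), Balding-Nichols SNP differentiation at F = 0.15 between
#' two 13/14 trait groups, 8 planted sweep peaks with 10x score elevation,
#' and a deletion-dominated SV mix (~77.5% DEL, 22.4% DUP, 0.15% INS)
#' with 10 planted hotspot clusters holding 85% of breakpoints.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_samples Number of accessions.
#' @param subgroup_sizes Sizes of the planted subgroups (sum to
#'   `n_samples`).
#' @param n_chromosomes,chromosome_length Genome layout (bp per
#'   chromosome).
#' @param n_genes Genes excluding the planted differential genes.
#' @param category_props Proportions of core/dispensable/private genes.
#' @param dispensable_beta Beta(a, b) shape of the dispensable
#'   gene-frequency law (U-shaped by default).
#' @param pav_structure_F Balding-Nichols-style divergence of dispensable
#'   gene frequencies between subgroups (drives PAV population
#'   structure).
#' @param n_differential,p_present Planted differential genes and their
#'   presence probabilities `c(pA, pB)` in the two trait groups.
#' @param cov_present_beta Beta shape of covered fractions for present
#'   genes.
#' @param cov_present_floor Lower floor on present-gene covered fractions
#'   (keeps the truth consistent with the presence rule).
#' @param residual_max Upper bound of the uniform residual covered
#'   fraction for absent genes (0 gives noise-free coverage).
#' @param n_snps,snp_F,ancestral_range SNP count, Balding-Nichols F
#'   between the trait groups, and the uniform range of ancestral allele
#'   frequencies.
#' @param sweep_peaks,sweep_peak_width,sweep_elevation Planted sweep-peak
#'   count, width (bp) and multiplicative score elevation.
#' @param n_svs,sv_type_props SV count and DEL/DUP/INS mix.
#' @param sv_length_meanlog,sv_length_sdlog,sv_min_length Log-normal SV
#'   length law (bp), truncated below at `sv_min_length`.
#' @param hotspot_clusters,hotspot_share,hotspot_step Planted hotspot
#'   cluster count, the share of SV breakpoints they hold, and the scan
#'   step the cluster width is tied to.
#' @param trait_group_sizes Sizes of the two trait-contrast groups.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_samples = 27,
                       subgroup_sizes = c(3, 3, 21),
                       n_chromosomes = 11,
                       chromosome_length = 1.8e6,
                       n_genes = 2000,
                       category_props = c(core = 0.761,
                                          dispensable = 0.231,
                                          private = 0.008),
                       dispensable_beta = c(0.3, 0.3),
                       pav_structure_F = 0.3,
                       n_differential = 20,
                       p_present = c(0.95, 0.05),
                       cov_present_beta = c(18, 2),
                       cov_present_floor = 0.25,
                       residual_max = 0.10,
                       n_snps = 20000,
                       snp_F = 0.15,
                       ancestral_range = c(0.1, 0.9),
                       sweep_peaks = 8,
                       sweep_peak_width = 130000,
                       sweep_elevation = 10,
                       n_svs = 2000,
                       sv_type_props = c(DEL = 34593, DUP = 9999,
                                         INS = 65) / 44657,
                       sv_length_meanlog = log(500),
                       sv_length_sdlog = 1,
                       sv_min_length = 51,
                       hotspot_clusters = 10,
                       hotspot_share = 0.85,
                       hotspot_step = 100000,
                       trait_group_sizes = c(13, 14)) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  if (sum(cfg$subgroup_sizes) != cfg$n_samples) {
    stop("subgroup sizes must sum to n_samples")
  }
  if (abs(sum(cfg$category_props) - 1) > 1e-8) {
    stop("category proportions must sum to 1")
  }
  if (sum(cfg$trait_group_sizes) != cfg$n_samples) {
    stop("trait group sizes must sum to n_samples")
  }
  n_priv <- round(cfg$category_props[["private"]] * cfg$n_genes)
  if (n_priv > cfg$n_samples * 50) {
    stop("infeasible config: too many private genes for the sample count")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study config: ", x$n_samples, " samples (subgroups ",
      paste(x$subgroup_sizes, collapse = "/"), "), ",
      x$n_chromosomes, " x ", format(x$chromosome_length, big.mark = ","),
      " bp, ", x$n_genes, "+", x$n_differential, " genes, ",
      x$n_snps, " SNPs, ", x$n_svs, " SVs, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

sample_names <- function(n) sprintf("acc%02d", seq_len(n))

#' @rdname simulate_study
#' @export
simulate_layout <- function(config) {
  genome_layout(sprintf("chr%02d", seq_len(config$n_chromosomes)),
                rep(config$chromosome_length, config$n_chromosomes))
}

#' @rdname simulate_study
#' @param layout A `genome_layout` from [simulate_layout()].
#' @export
simulate_genes <- function(config, layout) {
  n_total <- config$n_genes + config$n_differential
  per_chrom <- diff(round(seq(0, n_total,
                              length.out = nrow(layout) + 1)))
  rows <- list()
  gi <- 0
  for (ci in seq_len(nrow(layout))) {
    nc <- per_chrom[ci]
    if (nc == 0) next
    slot <- (layout$length[ci] - 20000) / nc
    for (j in seq_len(nc)) {
      gi <- gi + 1
      glen <- sample(1500:4000, 1)
      start <- round(10000 + (j - 1) * slot +
                       stats::runif(1, 0, max(slot - glen - 1, 1)))
      end <- start + glen
      n_ex <- sample(1:3, 1)
      cuts <- sort(sample(seq(start + 50, end - 50, by = 10),
                          2 * n_ex - 2))
      bounds <- c(start, cuts, end)
      ex <- cbind(start = bounds[seq(1, length(bounds), by = 2)],
                  end = bounds[seq(2, length(bounds), by = 2)])
      rows[[gi]] <- list(gene_id = sprintf("gene%05d", gi),
                         chrom = layout$chrom[ci],
                         strand = sample(c("+", "-"), 1),
                         start = start, end = end, exons = ex)
    }
  }
  new_gene_models(
    vapply(rows, `[[`, "", "gene_id"),
    vapply(rows, `[[`, "", "chrom"),
    vapply(rows, `[[`, "", "strand"),
    vapply(rows, `[[`, 0, "start"),
    vapply(rows, `[[`, 0, "end"),
    lapply(rows, `[[`, "exons")
  )
}

# Balding-Nichols subgroup frequency around an ancestral frequency
.bn_freq <- function(p, F) {
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# structured presence matrix + planted differential genes
simulate_pav_truth <- function(config, gene_ids) {
  n <- config$n_samples
  samples <- sample_names(n)
  subgroup <- rep(seq_along(config$subgroup_sizes), config$subgroup_sizes)
  names(subgroup) <- samples
  trait <- rep(c("trait_a", "trait_b"), config$trait_group_sizes)[
    sample.int(n)]
  names(trait) <- samples

  n_total <- config$n_genes + config$n_differential
  stopifnot(length(gene_ids) == n_total)
  n_core <- round(config$category_props[["core"]] * config$n_genes)
  n_priv <- round(config$category_props[["private"]] * config$n_genes)
  n_disp <- config$n_genes - n_core - n_priv

  m <- matrix(0L, n_total, n, dimnames = list(gene_ids, samples))
  slots <- sample.int(n_total)  # shuffle category placement over gene ids
  i_core <- slots[seq_len(n_core)]
  i_disp <- slots[n_core + seq_len(n_disp)]
  i_priv <- slots[n_core + n_disp + seq_len(n_priv)]
  i_diff <- slots[n_core + n_disp + n_priv + seq_len(config$n_differential)]

  m[i_core, ] <- 1L
  m[cbind(i_priv, sample.int(n, n_priv, replace = TRUE))] <- 1L
  if (n_disp > 0) {
    fb <- stats::rbeta(n_disp, config$dispensable_beta[1],
                       config$dispensable_beta[2])
    f <- (2 + fb * (n - 3)) / n  # overall frequency in [2/n, (n-1)/n]
    Fp <- config$pav_structure_F
    for (g in seq_along(config$subgroup_sizes)) {
      cols <- which(subgroup == g)
      fg <- .bn_freq(f, Fp)
      m[i_disp, cols] <- matrix(
        stats::rbinom(n_disp * length(cols), 1, rep(fg, length(cols))),
        n_disp, length(cols))
    }
  }
  if (config$n_differential > 0) {
    a_cols <- which(trait == "trait_a")
    b_cols <- which(trait == "trait_b")
    m[i_diff, a_cols] <- matrix(
      stats::rbinom(length(i_diff) * length(a_cols), 1,
                    config$p_present[1]),
      length(i_diff), length(a_cols))
    m[i_diff, b_cols] <- matrix(
      stats::rbinom(length(i_diff) * length(b_cols), 1,
                    config$p_present[2]),
      length(i_diff), length(b_cols))
  }
  list(presence = m, subgroup = subgroup, trait = trait,
       differential_ids = gene_ids[i_diff])
}

# covered fractions: present genes high (Beta, floored), absent genes a
# small uniform residual
simulate_coverage_table <- function(presence, config) {
  n <- length(presence)
  frac <- numeric(n)
  pres <- presence > 0
  frac[pres] <- pmax(stats::rbeta(sum(pres), config$cov_present_beta[1],
                                  config$cov_present_beta[2]),
                     config$cov_present_floor)
  if (config$residual_max > 0) {
    frac[!pres] <- stats::runif(sum(!pres), 0, config$residual_max)
  }
  data.frame(
    gene = rep(rownames(presence), ncol(presence)),
    sample = rep(colnames(presence), each = nrow(presence)),
    covered_fraction = frac,
    stringsAsFactors = FALSE
  )
}

#' Simulate Balding-Nichols differentiated diploid genotypes
#'
#' Draws, per population, allele frequencies from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`, then
#' diploid genotypes as `Binomial(2, freq)`. The expected Weir-Cockerham
#' FST between the populations is approximately `F`.
#'
#' @param p_ancestral Ancestral allele frequency (scalar or per-locus
#'   vector, recycled to `n_loci`).
#' @param F Divergence parameter, strictly between 0 and 1.
#' @param group_sizes Integer vector of diploid sample counts per
#'   population.
#' @param n_loci Number of unlinked loci.
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`).
#' @return A `snp_matrix` on a single synthetic chromosome (`sim1`, one
#'   locus per kb) with a `design` attribute assigning samples to
#'   `pop_1`, `pop_2`, ... groups.
#' @export
simulate_balding_nichols <- function(p_ancestral, F, group_sizes, n_loci,
                                     seed = NULL) {
  if (F <= 0 || F >= 1) stop("F must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  p <- rep_len(p_ancestral, n_loci)
  stopifnot(all(p > 0 & p < 1), all(group_sizes >= 1))
  geno <- matrix(NA_integer_, n_loci, sum(group_sizes))
  grp <- rep(seq_along(group_sizes), group_sizes)
  for (g in seq_along(group_sizes)) {
    fg <- .bn_freq(p, F)
    cols <- which(grp == g)
    geno[, cols] <- stats::rbinom(n_loci * length(cols), 2,
                                  rep(fg, length(cols)))
  }
  samples <- sprintf("ind%03d", seq_len(sum(group_sizes)))
  colnames(geno) <- samples
  sites <- data.frame(chrom = "sim1", pos = (seq_len(n_loci) - 1) * 1000,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  snp <- new_snp_matrix(sites, geno)
  attr(snp, "design") <- data.frame(sample = samples,
                                    group = paste0("pop_", grp),
                                    stringsAsFactors = FALSE)
  snp
}

# SNPs across the study layout: BN differentiation between trait groups
simulate_snps <- function(config, layout, trait) {
  n_loci <- config$n_snps
  p <- stats::runif(n_loci, config$ancestral_range[1],
                    config$ancestral_range[2])
  chrom <- sample(layout$chrom, n_loci, replace = TRUE,
                  prob = layout$length)
  pos <- floor(stats::runif(n_loci, 0, layout_length(layout, chrom)))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  samples <- names(trait)
  geno <- matrix(NA_integer_, n_loci, length(samples),
                 dimnames = list(NULL, samples))
  for (tg in unique(trait)) {
    fg <- .bn_freq(p, config$snp_F)[ord]
    cols <- which(trait == tg)
    geno[, cols] <- stats::rbinom(n_loci * length(cols), 2,
                                  rep(fg, length(cols)))
  }
  new_snp_matrix(data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                            stringsAsFactors = FALSE), geno)
}

#' @rdname simulate_study
#' @export
simulate_score_track <- function(config, layout) {
  n <- config$n_snps
  chrom <- sample(layout$chrom, n, replace = TRUE, prob = layout$length)
  pos <- floor(stats::runif(n, 0, layout_length(layout, chrom)))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  score <- stats::rexp(n, 1)

  width <- config$sweep_peak_width
  peak_chrom <- sample(layout$chrom, config$sweep_peaks,
                       replace = config$sweep_peaks > nrow(layout))
  peaks <- data.frame(chrom = peak_chrom, stringsAsFactors = FALSE)
  peaks$start <- floor(stats::runif(nrow(peaks), 50000,
                                    layout_length(layout, peaks$chrom) -
                                      width - 50000))
  peaks$end <- peaks$start + width
  # redraw until peaks are pairwise disjoint (finite loop: sparse genome)
  for (tries in 1:100) {
    ov <- rep(FALSE, nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      same <- which(peaks$chrom == peaks$chrom[i])
      same <- setdiff(same, i)
      ov[i] <- any(peaks$start[same] < peaks$end[i] &
                     peaks$start[i] < peaks$end[same])
    }
    if (!any(ov)) break
    redo <- which(ov)
    peaks$start[redo] <- floor(stats::runif(
      length(redo), 50000,
      layout_length(layout, peaks$chrom[redo]) - width - 50000))
    peaks$end[redo] <- peaks$start[redo] + width
  }
  for (i in seq_len(nrow(peaks))) {
    inpk <- chrom == peaks$chrom[i] & pos >= peaks$start[i] &
      pos < peaks$end[i]
    score[inpk] <- score[inpk] * config$sweep_elevation
  }
  track <- structure(data.frame(chrom = chrom, pos = pos, score = score,
                                stringsAsFactors = FALSE),
                     class = c("score_track", "data.frame"))
  list(track = track, peaks = peaks[order(peaks$chrom, peaks$start), ,
                                    drop = FALSE])
}

# SV set with planted hotspot clusters. Clusters are centred on the
# hotspot-scan step grid (width = one step) with wide separation, so each
# planted cluster corresponds to exactly one fully-containing scan window
# and the planted truth is unambiguous.
#' @rdname simulate_study
#' @param samples Character vector of sample names.
#' @export
simulate_sv_set <- function(config, layout, samples) {
  step <- config$hotspot_step
  n_cl <- config$hotspot_clusters
  cl_chrom <- rep_len(layout$chrom, n_cl)
  n_steps <- floor(layout_length(layout, cl_chrom) / step)
  centers <- numeric(n_cl)
  for (i in seq_len(n_cl)) {
    lo <- 2
    hi <- n_steps[i] - 2
    used <- centers[which(cl_chrom[seq_len(i - 1)] == cl_chrom[i])] / step
    # prefer wide separation; relax on short chromosomes so small test
    # genomes stay feasible
    cand <- integer()
    for (sep in 4:1) {
      cand <- setdiff(lo:hi, unlist(lapply(used, function(u)
        (u - sep):(u + sep))))
      if (length(cand) > 0) break
    }
    if (length(cand) == 0) stop("infeasible hotspot cluster placement")
    centers[i] <- sample(cand, 1) * step
  }
  clusters <- data.frame(chrom = cl_chrom, start = centers - step / 2,
                         end = centers + step / 2, stringsAsFactors = FALSE)

  n <- config$n_svs
  type <- sample(names(config$sv_type_props), n, replace = TRUE,
                 prob = config$sv_type_props)
  len <- pmax(round(stats::rlnorm(n, config$sv_length_meanlog,
                                  config$sv_length_sdlog)),
              config$sv_min_length)
  clustered <- stats::runif(n) < config$hotspot_share
  chrom <- character(n)
  start <- numeric(n)
  idx_cl <- sample.int(nrow(clusters), n, replace = TRUE)
  for (v in seq_len(n)) {
    if (clustered[v]) {
      cl <- clusters[idx_cl[v], ]
      len[v] <- min(len[v], (cl$end - cl$start) / 2)
      chrom[v] <- cl$chrom
      start[v] <- floor(stats::runif(1, cl$start, cl$end - len[v] - 1))
    } else {
      chrom[v] <- sample(layout$chrom, 1, prob = layout$length)
      start[v] <- floor(stats::runif(1, 0, layout_length(layout, chrom[v]) -
                                       len[v] - 1))
    }
  }
  end <- ifelse(type == "INS", start, start + len)
  geno <- matrix(0L, n, length(samples),
                 dimnames = list(NULL, samples))
  n_carrier <- 1 + stats::rbinom(n, length(samples) - 1, 0.25)
  for (v in seq_len(n)) {
    carriers <- sample.int(length(samples), n_carrier[v])
    geno[v, carriers] <- 1L + stats::rbinom(n_carrier[v], 1, 0.3)
  }
  records <- data.frame(
    sv_id = sprintf("sv%05d", seq_len(n)), type = type, chrom = chrom,
    start = start, end = end, length = len, stringsAsFactors = FALSE
  )
  ord <- order(records$chrom, records$start)
  sv <- new_sv_set(records[ord, ], geno[ord, , drop = FALSE])
  list(sv = sv, clusters = clusters,
       clustered_ids = records$sv_id[ord][clustered[ord]])
}

# identical-frequency two-group presence matrix for null calibration of
# the gene-frequency screen; group sizes default to 50/51 (odd total) so
# Fisher's discreteness does not dominate the attained test level
#' @rdname simulate_study
#' @param n_genes,group_sizes,p_range Null-calibration dimensions: gene
#'   count, the two group sizes, and the uniform range the shared
#'   per-gene presence probability is drawn from.
#' @export
simulate_null_pav <- function(n_genes = 2000, group_sizes = c(50, 51),
                              p_range = c(0.3, 0.7), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(group_sizes)
  p <- stats::runif(n_genes, p_range[1], p_range[2])
  m <- matrix(stats::rbinom(n_genes * n, 1, rep(p, n)), n_genes, n,
              dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                              sprintf("ind%03d", seq_len(n))))
  design <- data.frame(
    sample = colnames(m),
    group = rep(c("null_a", "null_b"), group_sizes),
    stringsAsFactors = FALSE
  )
  list(pav = as_pav_matrix(m), design = design)
}

#' Simulate a complete synthetic study
#'
#' Generates the full input bundle of the pipeline — gene models (GFF3),
#' exon-coverage table, SNP VCF, XP-CLR-style score track, SV VCF and
#' design table — together with the planted truth (presence matrix,
#' subgroup and trait labels, differential gene ids, sweep peak and
#' hotspot cluster intervals, simulation F). Outputs are byte-identical
#' under an identical seed.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory for the file bundle (created if
#'   needed); `NULL` skips writing and returns in-memory objects only.
#' @return Invisibly, a list with the in-memory objects (`layout`,
#'   `genes`, `coverage`, `snp`, `track`, `sv`, `design`), the `truth`
#'   list, and `paths` when files were written.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- simulate_layout(config)
  genes <- simulate_genes(config, layout)
  pv <- simulate_pav_truth(config, genes$gene_id)
  coverage <- simulate_coverage_table(pv$presence, config)
  snp <- simulate_snps(config, layout, pv$trait)
  sc <- simulate_score_track(config, layout)
  svs <- simulate_sv_set(config, layout, names(pv$trait))
  design <- data.frame(sample = names(pv$trait), group = unname(pv$trait),
                       stringsAsFactors = FALSE)
  truth <- list(
    presence = pv$presence, subgroup = pv$subgroup, trait = pv$trait,
    differential_ids = pv$differential_ids, sweep_peaks = sc$peaks,
    hotspot_clusters = svs$clusters, clustered_sv_ids = svs$clustered_ids,
    snp_F = config$snp_F
  )
  out <- list(layout = layout, genes = genes, coverage = coverage,
              snp = snp, track = sc$track, sv = svs$sv, design = design,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_gene_models_gff3(genes, p("genes.gff3"))
    write_coverage(coverage, p("coverage.tsv"))
    write_snp_vcf(snp, layout, p("snps.vcf"))
    write_score_track(sc$track, p("xpclr.tsv"))
    write_sv_vcf(svs$sv, layout, p("svs.vcf"))
    write_design(design, p("design.tsv"))
    utils::write.table(
      data.frame(gene = rownames(pv$presence), pv$presence,
                 check.names = FALSE),
      p("truth_presence.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(subgroup = as.list(pv$subgroup), trait = as.list(pv$trait),
           differential_ids = pv$differential_ids,
           sweep_peaks = sc$peaks, hotspot_clusters = svs$clusters,
           snp_F = config$snp_F, seed = config$seed),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
    out$paths <- vapply(c("genes.gff3", "coverage.tsv", "snps.vcf",
                          "xpclr.tsv", "svs.vcf", "design.tsv",
                          "truth_presence.tsv", "truth.json"), p, "")
  }
  invisible(out)
}
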