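#!/usr/bin/env Rscript
# Population structure from the binary PAV matrix: PCA ordination and an
# average-linkage Jaccard tree, scored against the planted subgroups.

library(pangenpop)

sim <- "results/simdata"
if (!dir.exists(sim)) stop("run analysis/01_simulate_study.R first")

coverage <- read_coverage(file.path(sim, "coverage.tsv"))
pav <- classify_genes(call_presence(coverage))
truth <- jsonlite::fromJSON(file.path(sim, "truth.json"))

ord <- pav_pca(pav, n_components = 5)
coords <- data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                     subgroup = unlist(truth$subgroup)[
                       rownames(ord$coordinates)])
write.table(coords, "results/pav_pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Explained variance (first 5 PCs):",
    paste(sprintf("%.1f%%", 100 * ord$explained_variance), collapse = ", "),
    "\n")

km <- kmeans(ord$coordinates[, 1:2], 3, nstart = 25)
cat("k-means (k = 3) vs planted subgroups:\n")
print(table(cluster = km$cluster, subgroup = coords$subgroup))

tree <- pav_distance_tree(pav, linkage = "average")
write_newick(tree, "results/pav_tree.nwk")
cat("Jaccard average-linkage tree written to results/pav_tree.nwk\n")
cat("Mean within- vs between-subgroup Jaccard distance:",
    sprintf("%.3f vs %.3f\n",
            mean(tree$dist[outer(coords$subgroup, coords$subgroup, "==") &
                             upper.tri(tree$dist)]),
            mean(tree$dist[outer(coords$subgroup, coords$subgroup, "!=") &
                             upper.tri(tree$dist)])))
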