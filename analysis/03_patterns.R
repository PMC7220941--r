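#!/usr/bin/env Rscript
# Stage 3: co-expression pattern discovery in the reference compendium.
#
# Quantile-normalizes the compendium, correlates the cell-type marker genes
# and the up-regulated target probe-sets across all reference arrays,
# clusters the gene-to-gene correlation matrix (Euclidean distance, average
# linkage), assigns each gene cluster to the reference condition it marks,
# and summarizes the cohort's sample-level structure by HC and PCA.

suppressMessages(library(refmatch))

indir <- "results/synthetic"
out <- "results/patterns"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

signals <- read_expression_table(file.path(indir, "compendium_expression.tsv"))
meta <- read.delim(file.path(indir, "compendium_metadata.tsv"))
comp <- compendium(signals, meta)
qcomp <- quantile_normalize(comp)

sel <- read.delim("results/selection/selection.tsv")
up <- sel$probe_set[sel$direction == "up"]
genes <- union(up, grep("^(SF|EC|MO|MF|TC|BC)_M", rownames(signals),
                        value = TRUE))

cm <- gene_coexpression(qcomp, genes)
k <- length(unique(qcomp$meta$cell_class))
cl <- cluster_genes(cm, clustering_params(k = k))
assigned <- assign_patterns(qcomp, cl$clusters)

write_tsv(data.frame(gene = rownames(cm), cluster = cl$clusters[rownames(cm)]),
          file.path(out, "gene_clusters.tsv"))
write_tsv(assigned$assignment, file.path(out, "cluster_assignment.tsv"))
write_tsv(data.frame(gene = cl$leaf_order), file.path(out, "leaf_order.tsv"))
write_tsv(as.data.frame(assigned$score_table),
          file.path(out, "cluster_condition_scores.tsv"))

cat(sprintf("Clustered %d genes over %d reference arrays into %d clusters:\n",
            nrow(cm), ncol(qcomp$signals), k))
print(assigned$assignment, row.names = FALSE)

# sample-level structure of the cohort on the selected probe-sets
cohort <- read_expression_table(file.path(indir, "cohort_expression.tsv"))
cmeta <- read_sample_metadata(file.path(indir, "cohort_metadata.tsv"))
expr <- expression_matrix(cohort, setNames(cmeta$group, cmeta$sample_id))
st <- sample_structure(expr, sel$probe_set[sel$selected])
write_tsv(data.frame(component = seq_along(st$percent_variance),
                     percent_variance = st$percent_variance),
          file.path(out, "pca_variance.tsv"))
write_tsv(data.frame(sample_id = rownames(st$scores), group = cmeta$group,
                     st$scores),
          file.path(out, "pca_scores.tsv"))
cat(sprintf("PCA of the cohort on %d selected probe-sets: PC1-3 explain %.0f%%, %.0f%%, %.0f%% of variance.\n",
            sum(sel$selected), st$percent_variance[1],
            st$percent_variance[2], st$percent_variance[3]))
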