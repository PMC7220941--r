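#!/usr/bin/env Rscript
# Stage 4: cumulative-score quantification of the reference comparisons.
#
# Scores every stimulated-versus-control reference comparison with the same
# pairwise machinery as the target contrast, accumulates each comparison's
# scores along the target's gene ranking (and vice versa for the reverse
# analysis), and summarizes each comparison by its percent-of-target and its
# top-gene overlap with the target signature.

suppressMessages(library(refmatch))

indir <- "results/synthetic"
out <- "results/scores"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

signals <- read_expression_table(file.path(indir, "compendium_expression.tsv"))
meta <- read.delim(file.path(indir, "compendium_metadata.tsv"))
comp <- compendium(signals, meta)
refs <- score_reference_comparisons(comp)

genes <- read.delim("results/selection/target_gene_scores.tsv")
class(genes) <- c("GeneScoreTable", "data.frame")
target_up <- genes[genes$score > 0, , drop = FALSE]
target_up$rank <- seq_len(nrow(target_up))

top_n <- min(100L, nrow(target_up))
curves <- cumulative_curves(target_up, refs, top_n = top_n)
for (nm in names(curves$curves)) {
  write_tsv(curves$curves[[nm]], file.path(out, paste0("curve_", nm, ".tsv")))
}
write_tsv(curves$summary, file.path(out, "curve_summary.tsv"))

rev_n <- min(top_n, min(vapply(refs, nrow, integer(1L))))
rev <- reverse_analysis(refs, target_up, top_n = rev_n)
write_tsv(rev$summary, file.path(out, "reverse_summary.tsv"))

overlaps <- data.frame(
  reference = names(refs),
  overlap = vapply(refs, function(r) {
    top_overlap(target_up, r, top_n = min(top_n, nrow(r)))$count
  }, integer(1L)))
write_tsv(overlaps, file.path(out, "top_overlap.tsv"))

cat(sprintf("Scored %d reference comparisons against the %d-gene up signature.\n",
            length(refs), nrow(target_up)))
summ <- merge(curves$summary, overlaps, by = "reference")
summ <- summ[order(-summ$percent_max), ]
cat("Percent-of-target (max over ranks / at final rank) and top-gene overlap:\n")
print(summ, row.names = FALSE, digits = 3)
best <- summ$reference[1]
cat(sprintf("Best-matching reference comparison: %s (%.0f%% of target score).\n",
            best, summ$percent_max[1]))
cat(sprintf("Reverse analysis: %s carries %.0f%% of the target score over its own top %d genes.\n",
            best, rev$summary$percent_max[rev$summary$reference == best], rev_n))
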