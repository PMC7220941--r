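#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the default study conditions -- a six-cell-type signature panel,
# four stimulation conditions (one of which, lps_ifng, is embedded in the
# disease group), a 10 vs 10 mixed-tissue cohort, and a reference compendium
# profiling every cell type and stimulus -- and writes them as TSV under
# results/synthetic/.

suppressMessages(library(refmatch))

seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- demo_signature_spec()
stimuli <- demo_stimuli(spec)
design <- demo_cohort_design(n_per_group = 10L, seed = seed)
cohort <- generate_tissue_cohort(spec, stimuli, design, seed = seed + 1L)
comp <- generate_reference_compendium(spec, stimuli, seed = seed + 2L)

write_expression_table(cohort$expr, file.path(out, "cohort_expression.tsv"))
write_tsv(data.frame(sample_id = colnames(cohort$expr$signals),
                     group = cohort$expr$groups),
          file.path(out, "cohort_metadata.tsv"))
write_expression_table(comp$signals, file.path(out, "compendium_expression.tsv"))
write_tsv(comp$meta, file.path(out, "compendium_metadata.tsv"))

# ground truth: which genes each stimulus moves, and by how much
truth <- do.call(rbind, lapply(stimuli, function(st) {
  data.frame(stimulus = st$name, cell_type = st$base_cell_type,
             gene = names(st$response_genes),
             log2_effect = unname(st$response_genes))
}))
write_tsv(truth, file.path(out, "stimulus_truth.tsv"))

n_markers <- sum(lengths(spec$marker_blocks))
cat(sprintf(
  "Simulated %d genes (%d cell-type markers, %d background) under seed %d.\n",
  nrow(cohort$expr$signals), n_markers,
  length(spec$background_genes), seed))
cat(sprintf(
  "Cohort: %d disease + %d control samples; embedded stimulus: %s (%d response genes).\n",
  sum(cohort$expr$groups == "disease"), sum(cohort$expr$groups == "control"),
  "lps_ifng", length(stimuli$lps_ifng$response_genes)))
cat(sprintf("Compendium: %d arrays over %d conditions (%d stimulated arms).\n",
            ncol(comp$signals), length(unique(comp$meta$condition)),
            sum(!is.na(comp$meta$control_of)) / 3L))
cat("Inputs written to", out, "\n")
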