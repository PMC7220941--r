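#' Score every stimulated-versus-control reference comparison
#'
#' For each stimulated condition of the compendium (or an explicit list of
#' comparisons), runs the pairwise selection and scoring machinery on the
#' stimulated arm versus its control arm and collapses to one representative
#' probe-set per gene. All probe-sets are scored, not only the selected ones:
#' a reference comparison must be able to report a (possibly small) score for
#' any gene a target signature asks about.
#'
#' @param comp A [compendium()] whose metadata links stimulated conditions to
#'   controls via `control_of`.
#' @param comparisons Optional data frame with columns `name`, `stimulated`
#'   and `control` (condition labels). Default: one comparison per stimulated
#'   condition found in the metadata.
#' @param criteria A [selection_criteria()]; the same criteria must be used
#'   for the target contrast so scores are comparable.
#' @param gene_map Optional probe-set -> gene symbol map.
#' @return Named list of `GeneScoreTable`s, one per comparison.
#' @export
score_reference_comparisons <- function(comp, comparisons = NULL,
                                        criteria = selection_criteria(),
                                        gene_map = NULL) {
  stopifnot(inherits(comp, "Compendium"))
  if (is.null(comparisons)) {
    stim <- unique(comp$meta[!is.na(comp$meta$control_of),
                             c("condition", "control_of")])
    if (!nrow(stim)) stop("compendium has no stimulated-control links", call. = FALSE)
    comparisons <- data.frame(name = stim$condition,
                              stimulated = stim$condition,
                              control = stim$control_of,
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "stimulated", "control") %in% colnames(comparisons)))
  out <- vector("list", nrow(comparisons))
  names(out) <- comparisons$name
  for (i in seq_len(nrow(comparisons))) {
    stim_ids <- comp$meta$array_id[comp$meta$condition == comparisons$stimulated[i]]
    ctrl_ids <- comp$meta$array_id[comp$meta$condition == comparisons$control[i]]
    if (length(intersect(stim_ids, ctrl_ids))) {
      stop("comparison '", comparisons$name[i],
           "' has overlapping arms", call. = FALSE)
    }
    if (length(stim_ids) < 2L || length(ctrl_ids) < 2L) {
      stop("comparison '", comparisons$name[i],
           "' needs >= 2 arrays per arm", call. = FALSE)
    }
    ids <- c(stim_ids, ctrl_ids)
    expr <- expression_matrix(
      comp$signals[, ids, drop = FALSE],
      stats::setNames(rep(c("stimulated", "control"),
                          c(length(stim_ids), length(ctrl_ids))), ids))
    sel <- select_differential(expr, "stimulated", "control", criteria)
    out[[i]] <- collapse_to_genes(score_genes(sel, selected_only = FALSE),
                                  gene_map)
  }
  out
}

# Reference scores aligned to a given gene order; genes absent from the
# reference's universe contribute 0 and are reported.
aligned_scores <- function(genes, ref_table, clip_negative = FALSE) {
  idx <- match(genes, ref_table$gene)
  sc <- ref_table$score[idx]
  missing <- genes[is.na(idx)]
  sc[is.na(sc)] <- 0
  if (clip_negative) sc <- pmax(sc, 0)
  list(scores = sc, missing = missing)
}

#' Cumulative score curves of reference comparisons along a target ranking
#'
#' Genes are ordered by the target signature's own scores (descending); at
#' each rank the curve accumulates the reference comparison's scores for the
#' genes seen so far. The ratio of the reference's running sum to the
#' target's own running sum (the "100% line") quantifies, rank by rank, how
#' fully the reference comparison reproduces the target signature.
#'
#' @param target A `GeneScoreTable` for the target contrast (ranked,
#'   collapsed to genes).
#' @param references Named list of `GeneScoreTable`s (reference comparisons).
#' @param top_n Number of top target genes to accumulate over (must not
#'   exceed the target table length).
#' @param clip_negative If TRUE, negative reference scores are clipped to 0
#'   before accumulation; by default signed scores are summed, so discordant
#'   genes depress the curve.
#' @return Object of class `CumulativeScoreCurves`: list with `curves` (one
#'   data frame per reference: `rank`, `gene`, `target_score`, `ref_score`,
#'   `target_cumsum`, `ref_cumsum`, `ratio`), `summary` (data frame:
#'   `reference`, `percent_max`, `percent_final`, `n_missing`) and the target
#'   name.
#' @export
cumulative_curves <- function(target, references, top_n = 100L,
                              clip_negative = FALSE) {
  stopifnot(inherits(target, "GeneScoreTable") || is.data.frame(target),
            is.list(references), !is.null(names(references)))
  if (top_n <= 0) stop("top_n must be positive", call. = FALSE)
  if (top_n > nrow(target)) {
    stop("top_n (", top_n, ") exceeds target table length (", nrow(target),
         ")", call. = FALSE)
  }
  ord <- target[order(target$rank), , drop = FALSE][seq_len(top_n), ]
  target_cum <- cumsum(ord$score)
  curves <- list()
  summary <- data.frame(reference = names(references),
                        percent_max = NA_real_, percent_final = NA_real_,
                        n_missing = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(references)) {
    al <- aligned_scores(ord$gene, references[[i]], clip_negative)
    ref_cum <- cumsum(al$scores)
    ratio <- ifelse(target_cum != 0, ref_cum / target_cum, NA_real_)
    curves[[names(references)[i]]] <- data.frame(
      rank = seq_len(top_n), gene = ord$gene,
      target_score = ord$score, ref_score = al$scores,
      target_cumsum = target_cum, ref_cumsum = ref_cum, ratio = ratio,
      stringsAsFactors = FALSE)
    summary$percent_max[i] <- 100 * max(ratio, na.rm = TRUE)
    summary$percent_final[i] <- 100 * ratio[top_n]
    summary$n_missing[i] <- length(al$missing)
  }
  structure(list(curves = curves, summary = summary,
                 top_n = top_n, clip_negative = clip_negative),
            class = "CumulativeScoreCurves")
}

#' Percent-of-target summary of one cumulative curve
#'
#' Reports both readings of "reaches up to X% of the target score": the
#' maximum ratio over all ranks, and the ratio at the final rank, each times
#' 100. The maximum is never below the final value.
#'
#' @param curve One curve data frame from [cumulative_curves()] (needs a
#'   `ratio` column).
#' @return List with numeric elements `max` and `final` (percent).
#' @export
percent_of_target <- function(curve) {
  stopifnot(is.data.frame(curve), "ratio" %in% colnames(curve))
  list(max = 100 * max(curve$ratio, na.rm = TRUE),
       final = 100 * curve$ratio[nrow(curve)])
}

#' Reverse analysis: target scores along each reference's own ranking
#'
#' Role-swapped counterpart of [cumulative_curves()]: for each reference
#' comparison, its own top `top_n` genes define the rank order, and the
#' target's scores are accumulated along it. The denominator (100% line)
#' remains the target's own cumulative score over its own top `top_n` genes,
#' so the ratio answers: how much of the target signal do the reference's
#' leading genes carry, relative to the target's own leading genes?
#'
#' @param references Named list of `GeneScoreTable`s.
#' @param target A `GeneScoreTable` for the target contrast.
#' @param top_n Ranks to accumulate over (must not exceed any table length).
#' @param clip_negative Clip negative target scores to 0 before accumulation.
#' @return `CumulativeScoreCurves` as in [cumulative_curves()]; per curve,
#'   `gene`/`ref_score` columns follow the reference's ranking and
#'   `target_cumsum` is the target's own-top-gene running sum.
#' @export
reverse_analysis <- function(references, target, top_n = 100L,
                             clip_negative = FALSE) {
  stopifnot(is.list(references), !is.null(names(references)))
  if (top_n <= 0) stop("top_n must be positive", call. = FALSE)
  if (top_n > nrow(target)) {
    stop("top_n exceeds target table length", call. = FALSE)
  }
  target_own <- target[order(target$rank), , drop = FALSE][seq_len(top_n), ]
  target_cum <- cumsum(target_own$score)
  curves <- list()
  summary <- data.frame(reference = names(references),
                        percent_max = NA_real_, percent_final = NA_real_,
                        n_missing = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(references)) {
    ref <- references[[i]]
    if (top_n > nrow(ref)) {
      stop("top_n exceeds table length of reference '",
           names(references)[i], "'", call. = FALSE)
    }
    ord <- ref[order(ref$rank), , drop = FALSE][seq_len(top_n), ]
    al <- aligned_scores(ord$gene, target, clip_negative)
    ref_cum <- cumsum(al$scores)  # target scores in reference order
    ratio <- ifelse(target_cum != 0, ref_cum / target_cum, NA_real_)
    curves[[names(references)[i]]] <- data.frame(
      rank = seq_len(top_n), gene = ord$gene,
      target_score = al$scores, ref_score = ord$score,
      target_cumsum = target_cum, ref_cumsum = ref_cum, ratio = ratio,
      stringsAsFactors = FALSE)
    summary$percent_max[i] <- 100 * max(ratio, na.rm = TRUE)
    summary$percent_final[i] <- 100 * ratio[top_n]
    summary$n_missing[i] <- length(al$missing)
  }
  structure(list(curves = curves, summary = summary,
                 top_n = top_n, clip_negative = clip_negative),
            class = "CumulativeScoreCurves")
}

#' Overlap of the top-ranked genes of two score tables
#'
#' @param table_a,table_b `GeneScoreTable`s (collapsed to genes, ranked).
#' @param top_n Number of leading genes to compare from each table.
#' @return List with `count` and the overlapping `genes` (sorted).
#' @export
top_overlap <- function(table_a, table_b, top_n = 100L) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b), top_n >= 1)
  if (top_n > nrow(table_a) || top_n > nrow(table_b)) {
    stop("top_n exceeds a table length", call. = FALSE)
  }
  a <- table_a[order(table_a$rank), "gene"][seq_len(top_n)]
  b <- table_b[order(table_b$rank), "gene"][seq_len(top_n)]
  genes <- sort(intersect(a, b))
  list(count = length(genes), genes = genes)
}

#' Filter a score table or selection by gene sets
#'
#' Keeps rows whose gene symbol belongs to the union of the supplied gene
#' sets (symbols compared case-insensitively), e.g. to restrict a signature
#' to secreted-protein annotations. For a `SelectionResult`, probe-sets are
#' mapped to symbols first.
#'
#' @param x A `GeneScoreTable` or `SelectionResult`.
#' @param gene_sets A named list of character vectors (as from [read_gmt()])
#'   or a single character vector.
#' @param gene_map Probe-set -> gene map, needed for a `SelectionResult`.
#' @return List with `filtered` (same class as `x`, rows restricted;
#'   `GeneScoreTable` ranks renumbered), `n_probe_sets` and `n_genes`
#'   (distinct symbols retained).
#' @export
filter_by_gene_set <- function(x, gene_sets, gene_map = NULL) {
  members <- toupper(unique(unlist(gene_sets, use.names = FALSE)))
  if (inherits(x, "SelectionResult")) {
    genes <- map_genes(x$probe_set, gene_map)$gene
    keep <- toupper(genes) %in% members
    filtered <- x[keep, , drop = FALSE]
    return(list(filtered = filtered,
                n_probe_sets = sum(keep),
                n_genes = length(unique(toupper(genes[keep])))))
  }
  stopifnot(is.data.frame(x), "gene" %in% colnames(x))
  keep <- toupper(x$gene) %in% members
  filtered <- x[keep, , drop = FALSE]
  if ("rank" %in% colnames(filtered) && nrow(filtered)) {
    filtered <- filtered[order(filtered$rank), , drop = FALSE]
    filtered$rank <- seq_len(nrow(filtered))
    rownames(filtered) <- NULL
  }
  n_ps <- if ("probe_set" %in% colnames(filtered)) {
    length(unique(filtered$probe_set))
  } else nrow(filtered)
  list(filtered = filtered, n_probe_sets = n_ps,
       n_genes = length(unique(toupper(filtered$gene))))
}
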