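#' Selection criteria for pairwise differential-expression calls
#'
#' Parameters of the pairwise-comparison selection scheme. A probe-set is
#' selected when it changes consistently across all experimental-by-baseline
#' sample pairs: either in at least `f_major` of pairs (major criterion), or
#' in at least `f_minor` of pairs while being more homogeneously expressed in
#' the experimental than in the baseline group (minor criterion). Either
#' route additionally requires a Bonferroni-corrected one-sample t-test of
#' the pairwise signal log ratios against 0 at level `alpha`.
#'
#' @param f_major Pair fraction required by the major criterion (default 0.5).
#' @param f_minor Pair fraction required by the minor criterion (default 0.3).
#' @param slr_call_threshold Absolute log2 ratio above which a pair is called
#'   Increase/Decrease (default 0.5 log2, about 1.4-fold).
#' @param alpha Significance level applied after Bonferroni correction
#'   (default 0.05).
#' @param signal_floor Detection floor applied to signals before log2
#'   (default 1).
#' @return Object of class `SelectionCriteria`.
#' @export
selection_criteria <- function(f_major = 0.5, f_minor = 0.3,
                               slr_call_threshold = 0.5, alpha = 0.05,
                               signal_floor = 1) {
  stopifnot(f_minor > 0, f_minor <= f_major, f_major <= 1,
            slr_call_threshold >= 0, alpha > 0, alpha <= 1, signal_floor > 0)
  structure(list(f_major = f_major, f_minor = f_minor,
                 slr_call_threshold = slr_call_threshold, alpha = alpha,
                 signal_floor = signal_floor),
            class = "SelectionCriteria")
}

#' Signal log ratios over all experimental-by-baseline sample pairs
#'
#' For every ordered pair (experimental sample i, baseline sample j) and
#' every probe-set g, computes `SLR(g, i, j) = log2 signal(g, i) - log2
#' signal(g, j)`. With n experimental and m baseline samples there are
#' `n * m` pairs; the two groups must be disjoint.
#'
#' @param expr An [expression_matrix()].
#' @param experimental_group,baseline_group Group labels in `expr`.
#' @return Object of class `PairwiseComparison`: list with `slr` (probe-sets
#'   x pairs matrix, columns named `<exp>|<base>`), `pairs` (data frame of
#'   pair members) and the group labels.
#' @export
compute_pairwise_slr <- function(expr, experimental_group, baseline_group) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  exp_ids <- group_samples(expr, experimental_group)
  base_ids <- group_samples(expr, baseline_group)
  overlap <- intersect(exp_ids, base_ids)
  if (length(overlap)) {
    stop("groups overlap in sample(s): ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  if (any(expr$signals <= 0)) {
    stop("signals must be positive; apply floor_signals() first", call. = FALSE)
  }
  lg <- log2(expr$signals)
  pairs <- expand.grid(baseline = base_ids, experimental = exp_ids,
                       stringsAsFactors = FALSE)[, c("experimental", "baseline")]
  slr <- lg[, pairs$experimental, drop = FALSE] -
    lg[, pairs$baseline, drop = FALSE]
  colnames(slr) <- paste(pairs$experimental, pairs$baseline, sep = "|")
  structure(list(slr = slr, pairs = pairs,
                 experimental_group = experimental_group,
                 baseline_group = baseline_group),
            class = "PairwiseComparison")
}

#' Change calls from pairwise signal log ratios
#'
#' Each (probe-set, pair) cell is called `I` (Increase) when its SLR exceeds
#' the call threshold, `D` (Decrease) when it falls below the negated
#' threshold, and `NC` otherwise.
#'
#' @param pc A `PairwiseComparison` from [compute_pairwise_slr()].
#' @param criteria A [selection_criteria()].
#' @return Character matrix of calls, same shape as `pc$slr`.
#' @export
call_changes <- function(pc, criteria = selection_criteria()) {
  stopifnot(inherits(pc, "PairwiseComparison"),
            inherits(criteria, "SelectionCriteria"))
  th <- criteria$slr_call_threshold
  calls <- matrix("NC", nrow = nrow(pc$slr), ncol = ncol(pc$slr),
                  dimnames = dimnames(pc$slr))
  calls[pc$slr > th] <- "I"
  calls[pc$slr < -th] <- "D"
  calls
}

# Row-wise coefficient of variation of log2 signals within one sample group.
# Homogeneity measure for the minor selection criterion; sd/|mean| on the
# log2 scale, with a zero-mean guard.
group_log2_cv <- function(lg) {
  m <- rowMeans(lg)
  s <- apply(lg, 1L, stats::sd)
  ifelse(abs(m) < .Machine$double.eps, Inf, s / abs(m))
}

#' Select differentially expressed probe-sets from pairwise comparisons
#'
#' Implements the two-route pairwise selection scheme. A probe-set is
#' selected as up-regulated when its Increase frequency reaches the major
#' threshold, or reaches the minor threshold while the experimental group is
#' more homogeneous (smaller coefficient of variation of log2 signals) than
#' the baseline group; symmetrically for down-regulation with the Decrease
#' frequency. Either route must additionally pass a two-sided one-sample
#' t-test of the probe-set's pairwise SLRs against 0, Bonferroni-corrected
#' for the number of probe-sets tested. When both directions qualify the one
#' with the larger frequency wins (frequency tie: the sign of the mean SLR).
#'
#' @inheritParams compute_pairwise_slr
#' @param criteria A [selection_criteria()].
#' @return Object of class `SelectionResult`: a data frame with one row per
#'   probe-set (columns `probe_set`, `n_increase`, `n_decrease`, `n_pairs`,
#'   `freq_increase`, `freq_decrease`, `mean_slr`, `t_statistic`, `p_raw`,
#'   `p_bonferroni`, `cv_experimental`, `cv_baseline`, `selected`,
#'   `direction`, `criterion_used`) plus the `PairwiseComparison`, call
#'   matrix and criteria as attributes.
#' @export
select_differential <- function(expr, experimental_group, baseline_group,
                                criteria = selection_criteria()) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(criteria, "SelectionCriteria"))
  expr <- floor_signals(expr, criteria$signal_floor)
  exp_ids <- group_samples(expr, experimental_group)
  base_ids <- group_samples(expr, baseline_group)
  if (length(exp_ids) < 2L || length(base_ids) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  pc <- compute_pairwise_slr(expr, experimental_group, baseline_group)
  calls <- call_changes(pc, criteria)

  n_pairs <- ncol(pc$slr)
  n_inc <- rowSums(calls == "I")
  n_dec <- rowSums(calls == "D")
  freq_inc <- n_inc / n_pairs
  freq_dec <- n_dec / n_pairs

  mean_slr <- rowMeans(pc$slr)
  sd_slr <- apply(pc$slr, 1L, stats::sd)
  t_stat <- ifelse(sd_slr > 0, mean_slr / (sd_slr / sqrt(n_pairs)),
                   ifelse(mean_slr == 0, 0, Inf * sign(mean_slr)))
  p_raw <- ifelse(is.finite(t_stat),
                  2 * stats::pt(-abs(t_stat), df = n_pairs - 1L),
                  ifelse(t_stat == 0, 1, 0))
  n_tested <- nrow(pc$slr)
  p_bonf <- pmin(1, p_raw * n_tested)

  lg <- log2(expr$signals)
  cv_exp <- group_log2_cv(lg[, exp_ids, drop = FALSE])
  cv_base <- group_log2_cv(lg[, base_ids, drop = FALSE])
  more_homogeneous <- cv_exp < cv_base

  sig <- p_bonf <= criteria$alpha
  up_major <- freq_inc >= criteria$f_major
  up_minor <- freq_inc >= criteria$f_minor & more_homogeneous
  down_major <- freq_dec >= criteria$f_major
  down_minor <- freq_dec >= criteria$f_minor & more_homogeneous
  up_ok <- sig & (up_major | up_minor)
  down_ok <- sig & (down_major | down_minor)

  direction <- rep("none", n_tested)
  prefer_up <- freq_inc > freq_dec |
    (freq_inc == freq_dec & mean_slr >= 0)
  direction[up_ok & (!down_ok | prefer_up)] <- "up"
  direction[down_ok & (!up_ok | !prefer_up)] <- "down"
  selected <- direction != "none"

  criterion_used <- rep("none", n_tested)
  criterion_used[direction == "up"] <-
    ifelse(up_major[direction == "up"], "major", "minor")
  criterion_used[direction == "down"] <-
    ifelse(down_major[direction == "down"], "major", "minor")

  res <- data.frame(
    probe_set = rownames(pc$slr),
    n_increase = n_inc, n_decrease = n_dec, n_pairs = n_pairs,
    freq_increase = freq_inc, freq_decrease = freq_dec,
    mean_slr = mean_slr, t_statistic = t_stat,
    p_raw = p_raw, p_bonferroni = p_bonf,
    cv_experimental = cv_exp, cv_baseline = cv_base,
    selected = selected, direction = direction,
    criterion_used = criterion_used,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "pairwise") <- pc
  attr(res, "calls") <- calls
  attr(res, "criteria") <- criteria
  class(res) <- c("SelectionResult", "data.frame")
  res
}

#' Per-probe-set scores combining SLR magnitude and call frequency
#'
#' The score of probe-set g is `mean_SLR(g) * |n_increase(g) -
#' n_decrease(g)| / n_pairs`: the average log2 change weighted by the net
#' frequency of consistent calls. Weighting by the magnitude of the net
#' frequency keeps the score's sign equal to the sign of the mean SLR (and
#' hence to the call direction), so consistently down-regulated genes carry
#' negative scores and swapping the groups negates every score. The score is
#' dimensionless and bounded in magnitude by the mean absolute SLR.
#'
#' @param selection A `SelectionResult` from [select_differential()].
#' @param selected_only If TRUE (default) score only selected probe-sets,
#'   otherwise all.
#' @return Data frame with columns `probe_set`, `score`, `mean_slr`,
#'   `net_freq`, `direction`.
#' @export
score_genes <- function(selection, selected_only = TRUE) {
  stopifnot(inherits(selection, "SelectionResult"))
  if (any(selection$n_pairs == 0)) stop("n_pairs is 0", call. = FALSE)
  tab <- as.data.frame(selection)
  if (selected_only) tab <- tab[tab$selected, , drop = FALSE]
  net_freq <- (tab$n_increase - tab$n_decrease) / tab$n_pairs
  data.frame(probe_set = tab$probe_set,
             score = tab$mean_slr * abs(net_freq),
             mean_slr = tab$mean_slr, net_freq = net_freq,
             direction = tab$direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse probe-set scores to one representative probe-set per gene
#'
#' Per gene, keeps the probe-set with the largest absolute score (ties broken
#' by lexicographic probe-set ID, so results are stable across runs), then
#' ranks genes by descending score. Probe-sets without a gene mapping pass
#' through under their own ID and are flagged.
#'
#' @param score_table Data frame from [score_genes()] (needs `probe_set` and
#'   `score` columns).
#' @param gene_map Named character vector probe-set -> gene symbol, or NULL.
#' @return Object of class `GeneScoreTable`: data frame with columns `gene`,
#'   `probe_set` (representative), `score`, `mapped`, `rank`, ordered by
#'   rank.
#' @export
collapse_to_genes <- function(score_table, gene_map = NULL) {
  stopifnot(is.data.frame(score_table),
            all(c("probe_set", "score") %in% colnames(score_table)))
  mapping <- map_genes(score_table$probe_set, gene_map)
  tab <- data.frame(gene = mapping$gene, probe_set = score_table$probe_set,
                    score = score_table$score, mapped = mapping$mapped,
                    stringsAsFactors = FALSE)
  # representative = max |score|, tie -> lexicographically first probe-set
  tab <- tab[order(tab$gene, -abs(tab$score), tab$probe_set), , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  tab <- tab[order(-tab$score, tab$probe_set), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("GeneScoreTable", "data.frame")
  tab
}

#' Full selection-and-scoring pass for one contrast
#'
#' Convenience wrapper: [select_differential()], [score_genes()] and
#' [collapse_to_genes()] in sequence.
#'
#' @inheritParams select_differential
#' @param gene_map Optional probe-set -> gene map (defaults to the one stored
#'   in `expr`).
#' @return List with `selection` (SelectionResult), `scores` (probe-set
#'   level) and `genes` (GeneScoreTable).
#' @export
score_contrast <- function(expr, experimental_group, baseline_group,
                           criteria = selection_criteria(),
                           gene_map = expr$gene_map) {
  selection <- select_differential(expr, experimental_group, baseline_group,
                                   criteria)
  scores <- score_genes(selection)
  list(selection = selection, scores = scores,
       genes = collapse_to_genes(scores, gene_map))
}
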