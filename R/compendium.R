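#' Reference-transcriptome compendium
#'
#' A merged set of reference arrays sharing one probe-set universe, with a
#' condition label, cell-type class, provenance and (for stimulated arms) a
#' link to the matching control condition per array. Every distinct array is
#' stored exactly once; presentation layers may repeat control arrays next to
#' several stimuli, but all correlation and pattern statistics use each array
#' once.
#'
#' @param signals Numeric matrix, probe-sets x arrays, strictly positive.
#' @param meta Data frame with one row per array: columns `array_id`,
#'   `condition`, and optionally `cell_class`, `control_of` (condition label
#'   of the matching control arm, NA for controls) and `dataset_id`.
#' @param quantile_normalized Logical flag recording whether `signals` have
#'   been quantile normalized.
#' @return Object of class `Compendium`.
#' @export
compendium <- function(signals, meta, quantile_normalized = FALSE) {
  stopifnot(is.matrix(signals), is.numeric(signals), is.data.frame(meta))
  req <- c("array_id", "condition")
  missing <- setdiff(req, colnames(meta))
  if (length(missing)) {
    stop("compendium metadata lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"cell_class" %in% colnames(meta)) meta$cell_class <- meta$condition
  if (!"control_of" %in% colnames(meta)) meta$control_of <- NA_character_
  if (!"dataset_id" %in% colnames(meta)) meta$dataset_id <- "unspecified"
  if (anyDuplicated(meta$array_id)) {
    stop("duplicate array_id in compendium metadata", call. = FALSE)
  }
  if (!setequal(colnames(signals), meta$array_id)) {
    stop("metadata array_ids must match signal columns", call. = FALSE)
  }
  meta <- meta[match(colnames(signals), meta$array_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(signals = signals, meta = meta,
                 quantile_normalized = quantile_normalized),
            class = "Compendium")
}

#' @export
print.Compendium <- function(x, ...) {
  cat("Compendium:", nrow(x$signals), "probe-sets x", ncol(x$signals),
      "arrays;", length(unique(x$meta$condition)), "conditions;",
      if (x$quantile_normalized) "quantile normalized" else "not normalized",
      "\n")
  invisible(x)
}

#' Quantile normalization of reference arrays
#'
#' Harmonizes arrays from heterogeneous sources by forcing every column to
#' share one signal distribution: each column's sorted values are replaced by
#' the rank-wise mean over all columns, ties receiving the mean of their tied
#' rank targets. Backed by `limma::normalizeQuantiles`. When given a list of
#' matrices, they are first merged on the intersection of their probe-set
#' universes (no imputation across platforms).
#'
#' @param arrays A `Compendium`, a numeric matrix, or a list of numeric
#'   matrices with probe-set rownames.
#' @param meta Metadata data frame, required when merging a list into a new
#'   `Compendium` (ignored for a matrix input).
#' @return Same class as the input (`Compendium` in, `Compendium` out with
#'   the `quantile_normalized` flag set; matrix or list in, matrix out).
#' @export
quantile_normalize <- function(arrays, meta = NULL) {
  if (inherits(arrays, "Compendium")) {
    arrays$signals <- quantile_normalize(arrays$signals)
    arrays$quantile_normalized <- TRUE
    return(arrays)
  }
  if (is.list(arrays) && !is.data.frame(arrays)) {
    shared <- Reduce(intersect, lapply(arrays, rownames))
    if (!length(shared)) {
      stop("empty probe-set intersection across array sets", call. = FALSE)
    }
    arrays <- do.call(cbind, lapply(arrays, function(m) {
      m[shared, , drop = FALSE]
    }))
    if (!is.null(meta)) {
      return(compendium(quantile_normalize(arrays), meta,
                        quantile_normalized = TRUE))
    }
  }
  stopifnot(is.matrix(arrays), is.numeric(arrays))
  if (ncol(arrays) < 2L) stop("need at least 2 arrays", call. = FALSE)
  out <- limma::normalizeQuantiles(arrays, ties = TRUE)
  dimnames(out) <- dimnames(arrays)
  out
}

# z-score each row; constant rows map to all-zero and are reported in the
# "constant" attribute.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  const <- s == 0 | !is.finite(s)
  z <- (m - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  attr(z, "constant") <- rownames(m)[const]
  z
}

#' Gene-to-gene co-expression matrix over reference arrays
#'
#' Pearson correlation between the chosen probe-sets, computed over the
#' signals of all (distinct) compendium arrays. Genes that are constant
#' across arrays cannot carry a correlation; their entries are set to 0
#' (diagonal kept at 1) and their IDs are flagged with a warning.
#'
#' @param comp A [compendium()].
#' @param gene_list Probe-set IDs to correlate (must exist in the
#'   compendium); defaults to all.
#' @return Object of class `CoexpressionMatrix`: symmetric correlation
#'   matrix with unit diagonal and a `constant_genes` attribute.
#' @export
gene_coexpression <- function(comp, gene_list = rownames(comp$signals)) {
  stopifnot(inherits(comp, "Compendium"))
  unknown <- setdiff(gene_list, rownames(comp$signals))
  if (length(unknown)) {
    stop("genes absent from compendium: ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  if (ncol(comp$signals) < 3L) stop("need at least 3 arrays", call. = FALSE)
  m <- comp$signals[gene_list, , drop = FALSE]
  s <- apply(m, 1L, stats::sd)
  const <- rownames(m)[s == 0]
  r <- suppressWarnings(stats::cor(t(m), method = "pearson"))
  if (length(const)) {
    r[const, ] <- 0
    r[, const] <- 0
    warning("constant gene(s) in compendium, correlations set to 0: ",
            paste(utils::head(const, 5L), collapse = ", "), call. = FALSE)
  }
  diag(r) <- 1
  structure(r, constant_genes = const, class = c("CoexpressionMatrix", "matrix",
                                                 "array"))
}

#' Clustering parameters
#'
#' @param distance Distance measure over correlation-matrix rows; only
#'   `"euclidean"` is supported.
#' @param linkage Agglomeration rule; only `"average"` and `"complete"` are
#'   supported (default `"average"`).
#' @param k Optional number of clusters for a tree cut. The package default
#'   elsewhere is the number of distinct condition classes, an admittedly
#'   arbitrary heuristic.
#' @return Object of class `ClusteringParams`.
#' @export
clustering_params <- function(distance = "euclidean", linkage = "average",
                              k = NULL) {
  distance <- match.arg(distance, "euclidean")
  linkage <- match.arg(linkage, c("average", "complete"))
  if (!is.null(k)) stopifnot(k >= 1)
  structure(list(distance = distance, linkage = linkage, k = k),
            class = "ClusteringParams")
}

#' Hierarchical clustering of a co-expression matrix
#'
#' Rows of the gene-to-gene correlation matrix are the feature vectors:
#' genes whose correlation profiles over the compendium agree are merged
#' first (Euclidean distance, average linkage by default). The leaf order is
#' deterministic for a given input.
#'
#' @param cm A `CoexpressionMatrix` (or any numeric matrix of row features).
#' @param params A [clustering_params()].
#' @return List with `tree` (hclust), `leaf_order` (gene IDs in dendrogram
#'   order) and `clusters` (named integer vector, only when `params$k` is
#'   set).
#' @export
cluster_genes <- function(cm, params = clustering_params()) {
  stopifnot(inherits(params, "ClusteringParams"))
  if (nrow(cm) < 2L) stop("need at least 2 genes to cluster", call. = FALSE)
  d <- stats::dist(unclass(cm), method = params$distance)
  tree <- stats::hclust(d, method = params$linkage)
  clusters <- NULL
  if (!is.null(params$k)) {
    clusters <- stats::cutree(tree, k = min(params$k, nrow(cm)))
  }
  list(tree = tree, leaf_order = rownames(cm)[tree$order], clusters = clusters)
}

#' Assign gene clusters to the reference condition they mark
#'
#' Signals are log2-transformed and z-normalized per probe-set across all
#' distinct arrays; each cluster's score for a condition is the mean z-score
#' of the cluster's genes over that condition's replicate arrays. The cluster
#' is labeled with the highest-scoring condition. Clusters made of constant
#' (z = 0) genes, or with no condition scoring above zero, are labeled
#' `"unassigned"`.
#'
#' @param comp A [compendium()].
#' @param clusters Named integer/character vector gene -> cluster ID (e.g.
#'   from [cluster_genes()]).
#' @return List with `assignment` (data frame: `cluster`, `condition`,
#'   `score`, `n_genes`) and `score_table` (full cluster x condition matrix
#'   of mean z-scores).
#' @export
assign_patterns <- function(comp, clusters) {
  stopifnot(inherits(comp, "Compendium"), !is.null(names(clusters)))
  unknown <- setdiff(names(clusters), rownames(comp$signals))
  if (length(unknown)) {
    stop("cluster genes absent from compendium: ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  z <- zscore_rows(log2(comp$signals[names(clusters), , drop = FALSE]))
  conds <- unique(comp$meta$condition)
  cl_ids <- sort(unique(clusters))
  score_table <- matrix(0, nrow = length(cl_ids), ncol = length(conds),
                        dimnames = list(as.character(cl_ids), conds))
  for (ci in seq_along(cl_ids)) {
    genes <- names(clusters)[clusters == cl_ids[ci]]
    zi <- z[genes, , drop = FALSE]
    for (cond in conds) {
      arr <- comp$meta$array_id[comp$meta$condition == cond]
      score_table[ci, cond] <- mean(zi[, arr, drop = FALSE])
    }
  }
  best <- apply(score_table, 1L, which.max)
  best_score <- score_table[cbind(seq_along(cl_ids), best)]
  label <- colnames(score_table)[best]
  label[best_score <= 1e-8] <- "unassigned"
  assignment <- data.frame(
    cluster = as.character(cl_ids), condition = label,
    score = best_score,
    n_genes = as.integer(table(factor(clusters, levels = cl_ids))),
    stringsAsFactors = FALSE)
  list(assignment = assignment, score_table = score_table)
}

#' Sample-level structure: hierarchical clustering and PCA
#'
#' Restricted to a chosen probe-set list (typically the differentially
#' expressed set), signals are log2-transformed and z-normalized per
#' probe-set; samples are then clustered (Euclidean distance, average
#' linkage) and projected by PCA. Percent variance of component i is its
#' eigenvalue over the eigenvalue total, times 100.
#'
#' @param expr An [expression_matrix()] or positive numeric matrix.
#' @param selected_genes Probe-set IDs to use (default: all rows).
#' @param n_components Number of principal components to return; truncated
#'   to the matrix rank with a warning when set higher.
#' @return List with `tree` (hclust of samples), `scores` (samples x
#'   components), `loadings` (probe-sets x components), `percent_variance`
#'   (over all available components).
#' @export
sample_structure <- function(expr, selected_genes = NULL, n_components = 3L) {
  m <- if (inherits(expr, "ExpressionMatrix")) expr$signals else expr
  if (is.null(selected_genes)) selected_genes <- rownames(m)
  unknown <- setdiff(selected_genes, rownames(m))
  if (length(unknown)) {
    stop("unknown probe-set(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  if (ncol(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  z <- zscore_rows(log2(m[selected_genes, , drop = FALSE]))
  tree <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                        method = "average")
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  pct <- pca$sdev^2 / sum(pca$sdev^2) * 100
  avail <- sum(pca$sdev > 1e-10)
  if (n_components > avail) {
    warning("requested ", n_components, " components but rank is ", avail,
            "; truncating", call. = FALSE)
    n_components <- avail
  }
  keep <- seq_len(n_components)
  list(tree = tree,
       scores = pca$x[, keep, drop = FALSE],
       loadings = pca$rotation[, keep, drop = FALSE],
       percent_variance = pct)
}
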