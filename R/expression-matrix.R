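#' Expression matrix with sample group labels
#'
#' The universal input container of the pipeline: a numeric matrix of strictly
#' positive, linear-scale probe-set (or gene) signals, rows indexed by unique
#' probe-set IDs and columns by unique sample IDs, together with a group label
#' per sample and an optional probe-set-to-gene-symbol map.
#'
#' @param signals Numeric matrix, probe-sets x samples, strictly positive,
#'   with unique non-empty rownames and colnames.
#' @param groups Character vector of group labels, one per sample. Either
#'   named by sample ID or in column order.
#' @param gene_map Optional named character vector mapping probe-set IDs to
#'   gene symbols. Probe-sets absent from the map are treated as their own
#'   gene downstream.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `signals`, `groups` (named by sample) and `gene_map`.
#' @export
expression_matrix <- function(signals, groups, gene_map = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stop("`signals` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(signals)) || is.null(colnames(signals))) {
    stop("`signals` must have probe-set rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(signals))) {
    dup <- rownames(signals)[duplicated(rownames(signals))][1L]
    stop("duplicate probe-set ID: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(signals))) {
    dup <- colnames(signals)[duplicated(colnames(signals))][1L]
    stop("duplicate sample ID: ", dup, call. = FALSE)
  }
  if (any(!is.finite(signals))) {
    stop("`signals` must be finite", call. = FALSE)
  }
  if (any(signals <= 0)) {
    stop("`signals` must be strictly positive; apply floor_signals() first",
         call. = FALSE)
  }
  if (is.null(names(groups))) {
    if (length(groups) != ncol(signals)) {
      stop("`groups` must have one label per sample", call. = FALSE)
    }
    names(groups) <- colnames(signals)
  } else {
    missing <- setdiff(colnames(signals), names(groups))
    if (length(missing)) {
      stop("samples without group label: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    groups <- groups[colnames(signals)]
  }
  structure(
    list(signals = signals, groups = as.character(groups),
         gene_map = gene_map),
    names = c("signals", "groups", "gene_map"),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$signals), "probe-sets x",
      ncol(x$signals), "samples\n")
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                       collapse = ", "), "\n")
  if (!is.null(x$gene_map)) {
    cat("gene map:", length(x$gene_map), "probe-sets mapped\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$signals)

#' Floor expression signals at a detection limit
#'
#' Signals below `floor` are clipped to `floor`. Flooring before any log2
#' transformation is an explicit, recorded step: it prevents infinite or
#' unstable signal log ratios from near-zero signals.
#'
#' @param x An `ExpressionMatrix` or numeric matrix.
#' @param floor Positive detection floor on the linear scale (default 1, i.e.
#'   log2 signal 0).
#' @return Object of the same class with clipped signals.
#' @export
floor_signals <- function(x, floor = 1) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  if (inherits(x, "ExpressionMatrix")) {
    x$signals[x$signals < floor] <- floor
    return(x)
  }
  x[x < floor] <- floor
  x
}

#' Sample IDs belonging to one group
#' @param x An `ExpressionMatrix`.
#' @param group Group label.
#' @return Character vector of sample IDs.
#' @export
group_samples <- function(x, group) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ids <- colnames(x$signals)[x$groups == group]
  if (!length(ids)) stop("no samples in group '", group, "'", call. = FALSE)
  ids
}

#' Map probe-set IDs to gene symbols
#'
#' Probe-sets without a mapping keep their own ID as symbol and are flagged.
#'
#' @param probe_sets Character vector of probe-set IDs.
#' @param gene_map Named character vector (probe-set -> symbol) or NULL.
#' @return Data frame with columns `probe_set`, `gene`, `mapped`.
#' @export
map_genes <- function(probe_sets, gene_map = NULL) {
  gene <- probe_sets
  mapped <- rep(FALSE, length(probe_sets))
  if (!is.null(gene_map)) {
    hit <- probe_sets %in% names(gene_map)
    gene[hit] <- unname(gene_map[probe_sets[hit]])
    mapped <- hit
  }
  data.frame(probe_set = probe_sets, gene = gene, mapped = mapped,
             stringsAsFactors = FALSE)
}
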