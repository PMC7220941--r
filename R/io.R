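#' Read an expression table from TSV
#'
#' Expected layout: tab-separated, first column probe-set IDs, header row of
#' sample IDs, decimal-point numbers. Duplicate probe-set or sample IDs and
#' non-numeric cells are rejected with the offending coordinate named.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (probe-sets x samples).
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs an ID column and at least one sample", call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate probe-set ID in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID in ", path, ": ",
         sample_ids[duplicated(sample_ids)][1L], call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    vals <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(vals) & !is.na(raw[[j + 1L]]) & raw[[j + 1L]] != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d (probe-set %s), column %s of %s",
                   raw[[j + 1L]][bad[1L]], bad[1L], ids[bad[1L]],
                   sample_ids[j], path), call. = FALSE)
    }
    mat[, j] <- vals
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: first column `probe_set`, one column
#' per sample. Values are written with full double precision so a read
#' round-trip reproduces them bit-identically.
#'
#' @param signals Numeric matrix with dimnames, or an `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression_table <- function(signals, path) {
  if (inherits(signals, "ExpressionMatrix")) signals <- signals$signals
  df <- data.frame(probe_set = rownames(signals),
                   signals, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#'
#' Columns: `sample_id`, `group`, optionally `condition` and `control_link`.
#'
#' @param path Path to a TSV file.
#' @return Data frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "group")
  missing <- setdiff(req, colnames(meta))
  if (length(missing)) {
    stop("metadata lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L], call. = FALSE)
  }
  meta
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member symbols. Symbols are uppercased and deduplicated; empty sets
#' and lines with fewer than three fields are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set), with the set
#'   descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields", call. = FALSE)
    }
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT set '", fields[1L], "' is empty", call. = FALSE)
    nm[i] <- fields[1L]
    desc[i] <- fields[2L]
    sets[[i]] <- members
  }
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, d, toupper(sets[[nm]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 2-column probe-set-to-gene mapping TSV
#' @param path TSV with columns `probe_set` and `gene` (header required).
#' @return Named character vector, probe-set -> gene symbol.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_set", "gene") %in% colnames(df))) {
    stop("gene map needs columns `probe_set` and `gene`", call. = FALSE)
  }
  if (anyDuplicated(df$probe_set)) {
    stop("duplicate probe_set in gene map: ",
         df$probe_set[duplicated(df$probe_set)][1L], call. = FALSE)
  }
  stats::setNames(as.character(df$gene), df$probe_set)
}

#' Write a data frame as TSV
#'
#' Thin wrapper used for all tabular outputs so every result file shares one
#' dialect (tab-separated, no quoting, no row names).
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
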