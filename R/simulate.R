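#' Cell-type signature specification for synthetic expression data
#'
#' Defines the ground-truth transcriptional signatures of a panel of cell
#' types: each cell type owns a disjoint block of marker genes with positive
#' log2 offsets above a common baseline, and all remaining (background) genes
#' sit at the baseline. Signals are simulated on the log2 scale with Gaussian
#' noise, i.e. multiplicative noise on the linear scale, which matches the
#' approximately log-normal behaviour of microarray probe-set signals.
#'
#' @param cell_types Character vector of cell-type labels.
#' @param marker_blocks Named list, one element per cell type: a named numeric
#'   vector of marker gene IDs to log2 offsets. Blocks must be disjoint.
#' @param background_genes Character vector of gene IDs expressed at baseline
#'   in every cell type.
#' @param global_baseline Mean log2 signal of a background gene (default 7,
#'   i.e. linear signal 128, a mid-range microarray intensity).
#' @param noise_sd Log2-scale Gaussian noise standard deviation applied per
#'   gene and array (default 0.15, a typical replicate-level log2 sd for
#'   summarized expression arrays).
#' @return Object of class `SignatureSpec`.
#' @export
signature_spec <- function(cell_types, marker_blocks,
                           background_genes = character(),
                           global_baseline = 7, noise_sd = 0.15) {
  stopifnot(is.character(cell_types), length(cell_types) >= 1L,
            !anyDuplicated(cell_types))
  if (!is.list(marker_blocks) ||
      !setequal(names(marker_blocks), cell_types)) {
    stop("`marker_blocks` must be a named list with one element per cell type",
         call. = FALSE)
  }
  marker_blocks <- marker_blocks[cell_types]
  all_markers <- unlist(lapply(marker_blocks, names), use.names = FALSE)
  if (anyDuplicated(all_markers)) {
    stop("marker blocks must be disjoint across cell types; duplicated gene: ",
         all_markers[duplicated(all_markers)][1L], call. = FALSE)
  }
  offs <- unlist(marker_blocks, use.names = FALSE)
  if (length(offs) && any(!is.finite(offs))) {
    stop("marker offsets must be finite", call. = FALSE)
  }
  if (any(background_genes %in% all_markers)) {
    stop("background genes must not overlap marker blocks", call. = FALSE)
  }
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
            is.finite(global_baseline))
  structure(list(cell_types = cell_types, marker_blocks = marker_blocks,
                 background_genes = background_genes,
                 global_baseline = global_baseline, noise_sd = noise_sd),
            class = "SignatureSpec")
}

#' Stimulus specification
#'
#' A stimulation condition acting on one cell type of a [signature_spec()]
#' panel: a set of response genes with signed log2 effect sizes, plus the
#' number of replicate arrays per arm when the stimulus is profiled in a
#' reference experiment.
#'
#' @param name Stimulus label (also the condition label of its stimulated arm).
#' @param base_cell_type Cell type the stimulus acts on.
#' @param response_genes Named numeric vector: gene ID -> log2 effect size
#'   (positive = induced, negative = repressed).
#' @param n_replicates Replicates per arm in reference experiments (>= 2).
#' @return Object of class `StimulusSpec`.
#' @export
stimulus_spec <- function(name, base_cell_type, response_genes,
                          n_replicates = 3L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(base_cell_type), length(base_cell_type) == 1L,
            is.numeric(response_genes), length(response_genes) >= 1L,
            !is.null(names(response_genes)),
            n_replicates >= 2L)
  if (any(!is.finite(response_genes))) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  structure(list(name = name, base_cell_type = base_cell_type,
                 response_genes = response_genes,
                 n_replicates = as.integer(n_replicates)),
            class = "StimulusSpec")
}

#' Per-sample mixture design for a synthetic tissue cohort
#'
#' @param sample_ids Character vector of sample IDs.
#' @param fractions Numeric matrix, samples x cell types: simplex weights
#'   (non-negative, each row sums to 1).
#' @param groups Character vector of group labels, one per sample.
#' @param stimulus_intensity Numeric matrix, samples x stimuli, entries in
#'   \[0, 1\]: per-sample activation intensity of each stimulus (0 = absent).
#'   May be NULL when no stimuli act in the cohort.
#' @return Object of class `MixtureDesign`.
#' @export
mixture_design <- function(sample_ids, fractions, groups,
                           stimulus_intensity = NULL) {
  stopifnot(is.character(sample_ids), !anyDuplicated(sample_ids),
            is.matrix(fractions), nrow(fractions) == length(sample_ids),
            length(groups) == length(sample_ids))
  if (is.null(colnames(fractions))) {
    stop("`fractions` must have cell-type colnames", call. = FALSE)
  }
  if (any(fractions < 0) ||
      any(abs(rowSums(fractions) - 1) > 1e-8)) {
    stop("per-sample cell-type fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!is.null(stimulus_intensity)) {
    stopifnot(is.matrix(stimulus_intensity),
              nrow(stimulus_intensity) == length(sample_ids))
    if (is.null(colnames(stimulus_intensity))) {
      stop("`stimulus_intensity` must have stimulus-name colnames", call. = FALSE)
    }
    if (any(stimulus_intensity < 0) || any(stimulus_intensity > 1)) {
      stop("stimulus intensities must lie in [0, 1]", call. = FALSE)
    }
  }
  rownames(fractions) <- sample_ids
  if (!is.null(stimulus_intensity)) rownames(stimulus_intensity) <- sample_ids
  structure(list(sample_ids = sample_ids, fractions = fractions,
                 groups = as.character(groups),
                 stimulus_intensity = stimulus_intensity),
            class = "MixtureDesign")
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required: synthetic data must be reproducible", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gene universe of a signature spec, markers first, in declaration order.
spec_genes <- function(spec) {
  c(unlist(lapply(spec$marker_blocks, names), use.names = FALSE),
    spec$background_genes)
}

# Log2 expected profile of each pure cell type (genes x cell types).
cell_type_profiles <- function(spec) {
  genes <- spec_genes(spec)
  prof <- matrix(spec$global_baseline, nrow = length(genes),
                 ncol = length(spec$cell_types),
                 dimnames = list(genes, spec$cell_types))
  for (ct in spec$cell_types) {
    blk <- spec$marker_blocks[[ct]]
    if (length(blk)) prof[names(blk), ct] <- prof[names(blk), ct] + blk
  }
  prof
}

check_stimuli <- function(spec, stimuli) {
  genes <- spec_genes(spec)
  for (st in stimuli) {
    if (!inherits(st, "StimulusSpec")) {
      stop("stimuli must be StimulusSpec objects", call. = FALSE)
    }
    if (!st$base_cell_type %in% spec$cell_types) {
      stop("stimulus '", st$name, "' targets unknown cell type '",
           st$base_cell_type, "'", call. = FALSE)
    }
    unknown <- setdiff(names(st$response_genes), genes)
    if (length(unknown)) {
      stop("stimulus '", st$name, "' references genes outside the signature ",
           "spec: ", paste(utils::head(unknown, 3L), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic reference compendium
#'
#' Profiles every cell type as an unstimulated control arm and every stimulus
#' as a stimulated arm of its base cell type, with replicate arrays and
#' log2-scale Gaussian noise. Each stimulated condition is linked to its
#' control condition, mirroring the paired stimulated/control structure of
#' reference stimulation experiments.
#'
#' @param spec A [signature_spec()].
#' @param stimuli List of [stimulus_spec()] objects (may be empty).
#' @param seed Integer RNG seed (required).
#' @param n_control_replicates Replicates per unstimulated control arm.
#' @return A [compendium()] with condition labels, cell classes and
#'   stimulated-to-control links in its metadata.
#' @export
generate_reference_compendium <- function(spec, stimuli = list(), seed,
                                          n_control_replicates = 3L) {
  stopifnot(inherits(spec, "SignatureSpec"), n_control_replicates >= 2L)
  check_stimuli(spec, stimuli)
  prof <- cell_type_profiles(spec)
  genes <- rownames(prof)

  conditions <- list()  # each: label, cell_class, n_rep, log2_mean, control_of
  for (ct in spec$cell_types) {
    conditions[[paste0(ct, "_control")]] <- list(
      cell_class = ct, n_rep = as.integer(n_control_replicates),
      log2_mean = prof[, ct], control_of = NA_character_)
  }
  for (st in stimuli) {
    mu <- prof[, st$base_cell_type]
    mu[names(st$response_genes)] <- mu[names(st$response_genes)] +
      st$response_genes
    conditions[[st$name]] <- list(
      cell_class = st$base_cell_type, n_rep = st$n_replicates,
      log2_mean = mu, control_of = paste0(st$base_cell_type, "_control"))
  }

  with_seed(seed, {
    cols <- list(); meta <- list()
    for (lab in names(conditions)) {
      cond <- conditions[[lab]]
      for (r in seq_len(cond$n_rep)) {
        array_id <- sprintf("%s_r%d", lab, r)
        noise <- stats::rnorm(length(genes), 0, spec$noise_sd)
        cols[[array_id]] <- 2^(cond$log2_mean + noise)
        meta[[array_id]] <- data.frame(
          array_id = array_id, dataset_id = "synthetic",
          condition = lab, cell_class = cond$cell_class,
          control_of = cond$control_of, stringsAsFactors = FALSE)
      }
    }
    signals <- do.call(cbind, cols)
    rownames(signals) <- genes
    compendium(signals, do.call(rbind, meta))
  })
}

#' Generate a synthetic mixed-tissue cohort with ground truth
#'
#' Each sample is a convex mixture of pure cell-type profiles on the linear
#' scale. An active stimulus scales the response genes of its base cell type's
#' component (and only that component) by `2^(intensity * effect)`, so a
#' response is diluted by the cell type's tissue fraction exactly as a
#' cell-borne transcriptional program would be in bulk tissue. Log2-scale
#' Gaussian noise is then applied per gene and sample.
#'
#' @param spec A [signature_spec()].
#' @param stimuli List of [stimulus_spec()] objects.
#' @param design A [mixture_design()]; its stimulus-intensity columns must
#'   name stimuli present in `stimuli`.
#' @param seed Integer RNG seed (required).
#' @return List with elements `expr` (an [expression_matrix()] with the
#'   design's group labels) and `truth` (class `SyntheticTruth`: the three
#'   specs, the seed, and the realized per-gene expected log2 signals).
#' @export
generate_tissue_cohort <- function(spec, stimuli = list(), design, seed) {
  stopifnot(inherits(spec, "SignatureSpec"), inherits(design, "MixtureDesign"))
  check_stimuli(spec, stimuli)
  stim_names <- vapply(stimuli, `[[`, character(1L), "name")
  if (!is.null(design$stimulus_intensity)) {
    unknown <- setdiff(colnames(design$stimulus_intensity), stim_names)
    if (length(unknown)) {
      stop("design references unknown stimuli: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  bad_ct <- setdiff(colnames(design$fractions), spec$cell_types)
  if (length(bad_ct)) {
    stop("design references unknown cell types: ",
         paste(bad_ct, collapse = ", "), call. = FALSE)
  }
  prof <- cell_type_profiles(spec)
  genes <- rownames(prof)
  lin_prof <- 2^prof  # genes x cell types

  n <- length(design$sample_ids)
  expected <- matrix(0, nrow = length(genes), ncol = n,
                     dimnames = list(genes, design$sample_ids))
  for (i in seq_len(n)) {
    for (ct in colnames(design$fractions)) {
      f <- design$fractions[i, ct]
      if (f == 0) next
      comp <- lin_prof[, ct]
      for (st in stimuli) {
        if (st$base_cell_type != ct) next
        w <- if (!is.null(design$stimulus_intensity) &&
                 st$name %in% colnames(design$stimulus_intensity)) {
          design$stimulus_intensity[i, st$name]
        } else 0
        if (w > 0) {
          rg <- names(st$response_genes)
          comp[rg] <- comp[rg] * 2^(w * st$response_genes)
        }
      }
      expected[, i] <- expected[, i] + f * comp
    }
  }

  signals <- with_seed(seed, {
    noise <- matrix(stats::rnorm(length(expected), 0, spec$noise_sd),
                    nrow = nrow(expected))
    expected * 2^noise
  })
  dimnames(signals) <- dimnames(expected)

  expr <- expression_matrix(signals, stats::setNames(design$groups,
                                                     design$sample_ids))
  truth <- structure(
    list(spec = spec, stimuli = stimuli, design = design, seed = seed,
         expected_log2 = log2(expected)),
    class = "SyntheticTruth")
  list(expr = expr, truth = truth)
}

#' Expected log2 group difference from a synthetic truth
#'
#' Per-gene difference of mean expected log2 signal between two groups of a
#' generated cohort: the realized (mixture-attenuated) effect each gene
#' carries, against which recovery of the selection stage is measured.
#'
#' @param truth A `SyntheticTruth` from [generate_tissue_cohort()].
#' @param experimental_group,baseline_group Group labels of the design.
#' @return Named numeric vector, gene -> expected log2 difference.
#' @export
truth_group_difference <- function(truth, experimental_group, baseline_group) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  g <- truth$design$groups
  a <- truth$expected_log2[, g == experimental_group, drop = FALSE]
  b <- truth$expected_log2[, g == baseline_group, drop = FALSE]
  if (!ncol(a) || !ncol(b)) stop("unknown group label", call. = FALSE)
  rowMeans(a) - rowMeans(b)
}
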