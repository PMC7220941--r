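#' Default synthetic study conditions
#'
#' A ready-made signature panel, stimulus set and cohort design emulating a
#' desk-scale inflamed-versus-degenerative tissue study: a handful of tissue
#' and immune cell types with disjoint marker blocks, one inflammatory
#' stimulus embedded in the disease group, and several decoy stimuli that are
#' profiled in the reference compendium but never active in the cohort.
#' These builders are used by the bundled analysis scripts and define the
#' package's default validation conditions.
#'
#' @param markers_per_type Number of marker genes per cell type.
#' @param n_background Number of baseline-expressed background genes.
#' @param noise_sd Log2-scale noise sd (see [signature_spec()]).
#' @return `demo_signature_spec()`: a `SignatureSpec` with six cell types.
#' @export
demo_signature_spec <- function(markers_per_type = 10L, n_background = 440L,
                                noise_sd = 0.15) {
  cell_types <- c("synovial_fibroblast", "endothelial", "monocyte",
                  "macrophage", "t_cell", "b_cell")
  tags <- c(synovial_fibroblast = "SF", endothelial = "EC", monocyte = "MO",
            macrophage = "MF", t_cell = "TC", b_cell = "BC")
  offsets <- rep_len(c(4, 3, 5, 2), markers_per_type)
  blocks <- lapply(cell_types, function(ct) {
    stats::setNames(offsets,
                    sprintf("%s_M%02d", tags[[ct]], seq_len(markers_per_type)))
  })
  names(blocks) <- cell_types
  signature_spec(
    cell_types, blocks,
    background_genes = sprintf("BG_%04d", seq_len(n_background)),
    global_baseline = 7, noise_sd = noise_sd)
}

#' @rdname demo_signature_spec
#' @param spec The `SignatureSpec` the stimuli act on (marker IDs are taken
#'   from its blocks).
#' @return `demo_stimuli()`: a named list of four `StimulusSpec` objects.
#'   `lps_ifng` (an M1-macrophage-polarizing stimulus) is the condition
#'   embedded in the demo cohort; `il4`, `tnf` and `t_activation` are decoys
#'   with response-gene sets disjoint from it.
#' @export
demo_stimuli <- function(spec = demo_signature_spec()) {
  mf <- names(spec$marker_blocks$macrophage)
  if (length(mf) < 10L) {
    stop("demo stimuli need at least 10 markers per cell type", call. = FALSE)
  }
  mo <- names(spec$marker_blocks$monocyte)
  tc <- names(spec$marker_blocks$t_cell)
  list(
    lps_ifng = stimulus_spec(
      "lps_ifng", "macrophage",
      stats::setNames(c(3, 2.5, 2, 1.5, -1.5, -2), mf[1:6])),
    il4 = stimulus_spec(
      "il4", "macrophage",
      stats::setNames(c(2, 1.5, 2.5, -1.5), mf[7:10])),
    tnf = stimulus_spec(
      "tnf", "monocyte",
      stats::setNames(c(2.5, 2, 1.5, -2), mo[1:4])),
    t_activation = stimulus_spec(
      "t_activation", "t_cell",
      stats::setNames(c(3, 2, 1.5, -1.5), tc[1:4]))
  )
}

#' @rdname demo_signature_spec
#' @param n_per_group Samples per cohort group.
#' @param embedded_stimulus Name of the stimulus active (intensity 1) in the
#'   disease group and absent from the control group.
#' @param seed RNG seed for the per-sample cell-fraction jitter.
#' @param jitter_concentration Dirichlet concentration scale for per-sample
#'   fraction jitter around the mean composition; larger values give more
#'   homogeneous tissue compositions.
#' @return `demo_cohort_design()`: a `MixtureDesign` with groups `disease`
#'   and `control` sharing one mean cell composition, so the embedded
#'   stimulus is the only systematic difference between groups.
#' @export
demo_cohort_design <- function(n_per_group = 10L,
                               embedded_stimulus = "lps_ifng",
                               seed = 1L,
                               jitter_concentration = 300) {
  base <- c(synovial_fibroblast = 0.30, endothelial = 0.10, monocyte = 0.15,
            macrophage = 0.25, t_cell = 0.12, b_cell = 0.08)
  n <- 2L * n_per_group
  sample_ids <- c(sprintf("DIS_%02d", seq_len(n_per_group)),
                  sprintf("CTL_%02d", seq_len(n_per_group)))
  groups <- rep(c("disease", "control"), each = n_per_group)
  fractions <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      g <- stats::rgamma(length(base), shape = jitter_concentration * base)
      g / sum(g)
    }, numeric(length(base))))
  })
  colnames(fractions) <- names(base)
  intensity <- matrix(rep(c(1, 0), each = n_per_group), ncol = 1,
                      dimnames = list(sample_ids, embedded_stimulus))
  mixture_design(sample_ids, fractions, groups, intensity)
}

#' Generate a null two-group cohort
#'
#' Both groups are drawn from one homogeneous tissue (a single cell type, no
#' markers, no stimuli), so any probe-set selected between them is a false
#' positive. Used to verify type-I error control of the selection stage.
#'
#' @param n_per_group Samples per group.
#' @param n_probe_sets Number of probe-sets.
#' @param noise_sd Log2-scale noise sd.
#' @param seed RNG seed.
#' @return List with `expr` and `truth` as in [generate_tissue_cohort()].
#' @export
null_cohort <- function(n_per_group = 10L, n_probe_sets = 1000L,
                        noise_sd = 0.15, seed) {
  spec <- signature_spec(
    "tissue", list(tissue = stats::setNames(numeric(0), character(0))),
    background_genes = sprintf("g%04d", seq_len(n_probe_sets)),
    global_baseline = 7, noise_sd = noise_sd)
  n <- 2L * n_per_group
  ids <- sprintf("S_%02d", seq_len(n))
  design <- mixture_design(
    ids, matrix(1, n, 1, dimnames = list(ids, "tissue")),
    rep(c("A", "B"), each = n_per_group))
  generate_tissue_cohort(spec, list(), design, seed)
}
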