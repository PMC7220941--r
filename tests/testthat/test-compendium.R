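make_comp <- function(signals) {
  meta <- data.frame(array_id = colnames(signals),
                     condition = colnames(signals),
                     stringsAsFactors = FALSE)
  compendium(signals, meta)
}

test_that("quantile normalization matches the rank-mean closed form", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  q <- quantile_normalize(m)
  expect_equal(unname(q[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "b"]), c(2.5, 3.5, 4.5))
  # identical columns are unchanged
  m2 <- cbind(a = c(2, 7, 5), b = c(2, 7, 5))
  expect_equal(quantile_normalize(m2), m2)
})

test_that("quantile normalization handles ties by tied-rank target means", {
  # 5x4 toy with a tie in column a: hand-computed rank-mean oracle.
  m <- cbind(a = c(2, 2, 5, 9, 14), b = c(1, 3, 6, 8, 12),
             c = c(4, 2, 7, 11, 13), d = c(5, 1, 6, 10, 15))
  rownames(m) <- paste0("g", 1:5)
  sorted_means <- rowMeans(apply(m, 2, sort))   # targets per rank
  q <- quantile_normalize(m)
  # untied columns take the targets in rank order
  expect_equal(unname(q[order(m[, "b"]), "b"]), unname(sorted_means))
  # the tied pair in column a shares the mean of target ranks 1 and 2
  expect_equal(unname(q[1:2, "a"]),
               rep(mean(sorted_means[1:2]), 2))
  expect_equal(unname(q[3:5, "a"]), unname(sorted_means[3:5]))
})

test_that("quantile normalization is idempotent on tie-free matrices", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(2^(rnorm(80, 7, 1)), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("a", 1:4)))
    q1 <- quantile_normalize(m)
    expect_equal(quantile_normalize(q1), q1)
  }
})

test_that("merging array sets intersects probe-set universes", {
  m1 <- matrix(1:6 + 0, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  m2 <- matrix(1:4 + 0, 2, 2, dimnames = list(c("g2", "g3"), c("c", "d")))
  meta <- data.frame(array_id = letters[1:4], condition = "x",
                     stringsAsFactors = FALSE)
  comp <- quantile_normalize(list(m1, m2), meta)
  expect_s3_class(comp, "Compendium")
  expect_true(comp$quantile_normalized)
  expect_setequal(rownames(comp$signals), c("g2", "g3"))
  m3 <- matrix(1:2 + 0, 1, 2, dimnames = list("other", c("e", "f")))
  expect_error(quantile_normalize(list(m1, m3)), "empty")
})

test_that("co-expression has unit diagonal, symmetry and textbook values", {
  set.seed(10)
  x <- rnorm(6, 7, 1)
  m <- rbind(g1 = x, g2 = 10 - x, g3 = x + rnorm(6, 0, 0.3))
  colnames(m) <- paste0("a", 1:6)
  s <- abs(m) + 1  # strictly positive signals
  cm <- gene_coexpression(make_comp(s), rownames(m))
  # recompute with the textbook Pearson formula
  expect_equal(unclass(cm), cor(t(s)), ignore_attr = TRUE)
  expect_equal(diag(unclass(cm)), c(g1 = 1, g2 = 1, g3 = 1))
  expect_true(isSymmetric(unclass(cm)))
  # gene vs its (linear) negation -> r = -1
  m2 <- rbind(g1 = x, g2 = 20 - x)
  colnames(m2) <- paste0("a", 1:6)
  cm2 <- gene_coexpression(make_comp(m2))
  expect_equal(cm2["g1", "g2"], -1)
})

test_that("constant genes are flagged with zero correlation", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = rep(5, 4), g3 = c(2, 1, 4, 3))
  colnames(m) <- paste0("a", 1:4)
  expect_warning(cm <- gene_coexpression(make_comp(m)), "constant")
  expect_equal(attr(cm, "constant_genes"), "g2")
  expect_equal(unname(cm["g2", c("g1", "g3")]), c(0, 0))
  expect_equal(cm["g2", "g2"], 1)
})

test_that("co-expression is invariant to common monotone-linear rescaling", {
  set.seed(3)
  m <- matrix(2^(rnorm(40, 7, 1)), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("a", 1:5)))
  cm1 <- gene_coexpression(make_comp(m))
  cm2 <- gene_coexpression(make_comp(3 * m + 0))
  expect_equal(unclass(cm1), unclass(cm2))
})

test_that("average-linkage clustering reproduces a hand-built dendrogram", {
  # three 1-d points at 0, 1, 5: first merge {0,1} at distance 1, then the
  # pair joins 5 at the average distance (5 + 4) / 2 = 4.5
  feats <- matrix(c(0, 1, 5), ncol = 1, dimnames = list(c("p", "q", "r"), NULL))
  cl <- cluster_genes(feats, clustering_params(k = 2))
  expect_equal(sort(cl$tree$height), c(1, 4.5))
  expect_equal(cl$clusters[["p"]], cl$clusters[["q"]])
  expect_false(cl$clusters[["p"]] == cl$clusters[["r"]])
  # identical rows merge at distance 0
  feats2 <- matrix(c(1, 1, 4, 2, 2, 9), nrow = 3,
                   dimnames = list(c("x", "y", "z"), NULL))
  cl2 <- cluster_genes(feats2, clustering_params())
  expect_equal(min(cl2$tree$height), 0)
  # determinism: identical leaf order across runs
  set.seed(8)
  cm <- cor(matrix(rnorm(90), 10, 9))
  dimnames(cm) <- list(paste0("g", 1:9), paste0("g", 1:9))
  expect_identical(cluster_genes(cm)$leaf_order, cluster_genes(cm)$leaf_order)
  expect_error(cluster_genes(cm[1, , drop = FALSE]), "at least 2")
})

test_that("marker-block clusters are assigned to their cell type", {
  spec <- demo_signature_spec(markers_per_type = 6L, n_background = 40L,
                              noise_sd = 0.15)
  comp <- generate_reference_compendium(spec, list(), seed = 4)
  markers <- unlist(lapply(spec$marker_blocks, names), use.names = FALSE)
  truth <- rep(spec$cell_types, each = 6L)
  cm <- gene_coexpression(comp, markers)
  cl <- cluster_genes(cm, clustering_params(k = length(spec$cell_types)))
  assigned <- assign_patterns(comp, cl$clusters)
  # every cluster must be labeled with the control condition of the cell
  # type whose markers dominate it
  for (i in seq_len(nrow(assigned$assignment))) {
    cid <- assigned$assignment$cluster[i]
    genes <- names(cl$clusters)[cl$clusters == cid]
    majority <- names(which.max(table(truth[match(genes, markers)])))
    expect_equal(assigned$assignment$condition[i],
                 paste0(majority, "_control"))
  }
})

test_that("stimulus-response clusters map to the stimulated arm, not its control", {
  spec <- demo_signature_spec(markers_per_type = 6L, n_background = 40L)
  # induced genes live in the background so the stimulated arm is their
  # only elevated condition
  stim <- stimulus_spec("boost", "monocyte",
                        setNames(c(3, 2.5, 2), paste0("BG_000", 1:3)))
  comp <- generate_reference_compendium(spec, list(stim), seed = 9)
  clusters <- setNames(rep(1L, 3), names(stim$response_genes))
  assigned <- assign_patterns(comp, clusters)
  expect_equal(assigned$assignment$condition, "boost")
})

test_that("uninformative clusters are left unassigned", {
  m <- matrix(64, nrow = 3, ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
  comp <- make_comp(m)
  assigned <- assign_patterns(comp, setNames(rep(1L, 3), rownames(m)))
  expect_equal(assigned$assignment$condition, "unassigned")
  expect_true(all(assigned$score_table == 0))
})

test_that("PCA percent variances match a brute-force eigen oracle", {
  set.seed(12)
  m <- matrix(2^(rnorm(15 * 8, 7, 1)), 15, 8,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:8)))
  st <- sample_structure(m, n_components = 3)
  # oracle: eigenvalues of the covariance of the z-scored log2 matrix
  z <- log2(m)
  z <- (z - rowMeans(z)) / apply(z, 1, sd)
  ev <- eigen(stats::cov(t(z)), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10]
  expect_equal(st$percent_variance[seq_along(ev)], ev / sum(ev) * 100)
  expect_true(all(diff(st$percent_variance) <= 1e-8))
  expect_lte(sum(st$percent_variance), 100 + 1e-8)
})

test_that("duplicated samples score identically and groups drive PC1", {
  spec <- demo_signature_spec(n_background = 30L)
  stimuli <- demo_stimuli(spec)
  design <- demo_cohort_design(n_per_group = 5L, seed = 3)
  out <- generate_tissue_cohort(spec, stimuli, design, seed = 3)
  sel <- select_differential(out$expr, "disease", "control")
  genes <- sel$probe_set[sel$selected]
  st <- sample_structure(out$expr, genes, n_components = 2)
  groups <- out$expr$groups
  # strong group effect: PC1 separates the groups and leads the variance
  expect_gt(st$percent_variance[1], st$percent_variance[2])
  pc1 <- st$scores[, 1]
  expect_true(max(pc1[groups == "disease"]) < min(pc1[groups == "control"]) ||
                min(pc1[groups == "disease"]) > max(pc1[groups == "control"]))
  # duplicating every sample: each copy gets identical scores
  m2 <- cbind(out$expr$signals, out$expr$signals)
  colnames(m2) <- c(colnames(out$expr$signals),
                    paste0(colnames(out$expr$signals), "_copy"))
  st2 <- sample_structure(m2, genes, n_components = 2)
  n <- ncol(out$expr$signals)
  expect_equal(unname(st2$scores[1:n, ]), unname(st2$scores[(n + 1):(2 * n), ]))
  # requesting more components than the rank truncates with a warning
  expect_warning(sample_structure(m2[, 1:3], genes, n_components = 10),
                 "rank")
})
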