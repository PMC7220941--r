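test_that("pairwise SLRs follow the log2-ratio definition", {
  m <- matrix(c(8, 2, 4, 4), nrow = 1,
              dimnames = list("g1", c("e1", "b1", "e2", "b2")))
  expr <- expression_matrix(m, c("exp", "base", "exp", "base"))
  pc <- compute_pairwise_slr(expr, "exp", "base")
  expect_equal(ncol(pc$slr), 4L)  # 2 x 2 ordered pairs
  expect_equal(pc$slr["g1", "e1|b1"], 2)           # log2(8) - log2(2)
  expect_equal(pc$slr["g1", "e2|b2"], 0)
  # identical groups -> all SLRs zero
  m2 <- matrix(rep(c(5, 9, 3), 4), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expr2 <- expression_matrix(m2, c("exp", "exp", "base", "base"))
  expect_true(all(compute_pairwise_slr(expr2, "exp", "base")$slr == 0))
})

test_that("pairwise SLRs on a 3x3 matrix equal the double-loop oracle", {
  expr <- random_expr(5, 3, 3, seed = 11)
  pc <- compute_pairwise_slr(expr, "exp", "base")
  ora <- oracle_pairwise(expr$signals, group_samples(expr, "exp"),
                         group_samples(expr, "base"))
  expect_equal(ncol(pc$slr), 9L)
  for (i in group_samples(expr, "exp")) {
    for (j in group_samples(expr, "base")) {
      expect_equal(pc$slr[, paste(i, j, sep = "|")],
                   ora$slr[, i, j])
    }
  }
})

test_that("groups must be disjoint and non-empty", {
  m <- matrix(1:6 + 0, nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expr <- expression_matrix(m, c("exp", "base", "base"))
  expect_error(compute_pairwise_slr(expr, "exp", "missing"), "no samples")
  expr$groups <- c("exp", "exp", "base")
  names(expr$groups) <- colnames(m)
  # force an overlap by duplicating a label set
  expr2 <- expr
  expr2$groups[] <- "both"
  expect_error(compute_pairwise_slr(expr2, "both", "both"), "overlap")
})

test_that("change calls apply the SLR threshold symmetrically", {
  slr <- matrix(c(0, 0.6, -0.6, 0.5, -0.5, 1.2), nrow = 2,
                dimnames = list(c("g1", "g2"), c("p1", "p2", "p3")))
  pc <- structure(list(slr = slr), class = "PairwiseComparison")
  calls <- call_changes(pc, selection_criteria(slr_call_threshold = 0.5))
  expect_equal(calls["g1", ], c(p1 = "NC", p2 = "D", p3 = "NC"))
  # g2 carries (0.6, 0.5, 1.2): exactly at the threshold is NoChange
  expect_equal(calls["g2", ], c(p1 = "I", p2 = "NC", p3 = "I"))
  expect_equal(unname(calls["g1", "p3"]), "NC")
})

test_that("random call matrices match the elementwise oracle", {
  set.seed(42)
  for (rep in 1:3) {
    slr <- matrix(rnorm(60, sd = 0.8), nrow = 10)
    dimnames(slr) <- list(paste0("g", 1:10), paste0("p", 1:6))
    pc <- structure(list(slr = slr), class = "PairwiseComparison")
    calls <- call_changes(pc, selection_criteria())
    expected <- matrix("NC", 10, 6, dimnames = dimnames(slr))
    for (i in 1:10) for (j in 1:6) {
      if (slr[i, j] > 0.5) expected[i, j] <- "I"
      if (slr[i, j] < -0.5) expected[i, j] <- "D"
    }
    expect_identical(calls, expected)
  }
})

test_that("self-comparison of identical groups selects nothing", {
  set.seed(7)
  half <- matrix(2^(7 + rnorm(50, sd = 0.4)), nrow = 10)
  m <- cbind(half, half)
  dimnames(m) <- list(paste0("g", 1:10), paste0("s", 1:10))
  expr <- expression_matrix(m, rep(c("exp", "base"), each = 5))
  sel <- select_differential(expr, "exp", "base")
  expect_equal(sum(sel$selected), 0L)
  expect_true(all(sel$direction == "none"))
})

test_that("a single four-fold shifted gene is selected with unanimous calls", {
  set.seed(3)
  m <- matrix(2^(7 + rnorm(30, sd = 0.05)), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  m["g3", 1:3] <- m["g3", 1:3] * 4
  expr <- expression_matrix(m, rep(c("exp", "base"), each = 3))
  sel <- select_differential(expr, "exp", "base")
  expect_equal(sel$probe_set[sel$selected], "g3")
  expect_equal(sel$freq_increase[sel$probe_set == "g3"], 1)  # 9/9 pairs
  expect_equal(sel$direction[sel$probe_set == "g3"], "up")
  expect_equal(sel$criterion_used[sel$probe_set == "g3"], "major")
  ora <- oracle_pairwise(expr$signals, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(sel$selected, ora$table$selected)
  expect_equal(sel$direction, ora$table$direction)
})

test_that("selection quantities match the double-loop oracle on random instances", {
  for (seed in c(1, 2, 3)) {
    expr <- random_expr(10, 4, 5, seed = seed, sd = 0.8)
    exp_ids <- group_samples(expr, "exp")
    base_ids <- group_samples(expr, "base")
    sel <- select_differential(expr, "exp", "base")
    sc <- score_genes(sel, selected_only = FALSE)
    ora <- oracle_pairwise(expr$signals, exp_ids, base_ids)
    expect_equal(sel$n_increase, ora$table$n_increase)
    expect_equal(sel$n_decrease, ora$table$n_decrease)
    expect_equal(sel$mean_slr, ora$table$mean_slr)
    expect_equal(sel$p_bonferroni, ora$table$p_bonferroni)
    expect_equal(sel$selected, ora$table$selected)
    expect_equal(sel$direction, ora$table$direction)
    expect_equal(sc$score, ora$table$score)
    expect_equal(unique(sel$n_pairs), ora$n_pairs)
  }
})

test_that("call frequencies are proper disjoint fractions", {
  for (seed in 4:6) {
    expr <- random_expr(8, 3, 3, seed = seed, sd = 1)
    sel <- select_differential(expr, "exp", "base")
    expect_true(all(sel$freq_increase >= 0 & sel$freq_increase <= 1))
    expect_true(all(sel$freq_decrease >= 0 & sel$freq_decrease <= 1))
    expect_true(all(sel$freq_increase + sel$freq_decrease <= 1))
  }
})

test_that("swapping groups negates scores and flips major-criterion directions", {
  expr <- random_expr(12, 4, 4, seed = 9, sd = 1)
  fwd <- select_differential(expr, "exp", "base")
  rev <- select_differential(expr, "base", "exp")
  sc_fwd <- score_genes(fwd, selected_only = FALSE)
  sc_rev <- score_genes(rev, selected_only = FALSE)
  expect_equal(sc_rev$score, -sc_fwd$score)
  expect_equal(rev$mean_slr, -fwd$mean_slr)
  expect_equal(rev$freq_increase, fwd$freq_decrease)
  # the major criterion is symmetric; the homogeneity (minor) route is not
  major_up <- fwd$direction == "up" & fwd$criterion_used == "major"
  expect_true(all(rev$direction[major_up] == "down"))
  major_down <- fwd$direction == "down" & fwd$criterion_used == "major"
  expect_true(all(rev$direction[major_down] == "up"))
})

test_that("score formula matches hand computations", {
  # unanimity: 9/9 Increase with SLR 1 -> score 1
  m <- matrix(2, nrow = 1, ncol = 6,
              dimnames = list("g1", paste0("s", 1:6)))
  m[1, 1:3] <- 4
  expr <- expression_matrix(m, rep(c("exp", "base"), each = 3))
  sel <- select_differential(expr, "exp", "base")
  expect_equal(score_genes(sel)$score, 1)
  # mean SLR 2 with 6 of 9 pairs Increase -> 2 * 6/9 = 4/3
  tab <- data.frame(probe_set = "g1", n_increase = 6L, n_decrease = 0L,
                    n_pairs = 9L, mean_slr = 2, selected = TRUE,
                    direction = "up")
  class(tab) <- c("SelectionResult", "data.frame")
  expect_equal(score_genes(tab)$score, 2 * 6 / 9)
  # all-zero SLRs -> score 0
  tab0 <- data.frame(probe_set = "g1", n_increase = 0L, n_decrease = 0L,
                     n_pairs = 9L, mean_slr = 0, selected = TRUE,
                     direction = "none")
  class(tab0) <- c("SelectionResult", "data.frame")
  expect_equal(score_genes(tab0)$score, 0)
  # consistent down-regulation carries a negative score
  tabd <- data.frame(probe_set = "g1", n_increase = 0L, n_decrease = 8L,
                     n_pairs = 9L, mean_slr = -1.5, selected = TRUE,
                     direction = "down")
  class(tabd) <- c("SelectionResult", "data.frame")
  expect_equal(score_genes(tabd)$score, -1.5 * 8 / 9)
})

test_that("collapse keeps the max-|score| probe-set with stable tie-breaks", {
  tab <- data.frame(
    probe_set = c("p1", "p2", "p3", "p4", "p5"),
    score = c(1.2, -0.3, 1.0, 1.0, 0.5),
    stringsAsFactors = FALSE)
  gm <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB", p4 = "GENEC", p5 = "GENED")
  out <- collapse_to_genes(tab, gm)
  expect_equal(out$score[out$gene == "GENEA"], 1.2)
  # tie between GENEB and GENEC at 1.0: ordered by probe-set ID
  tied <- out[out$score == 1.0, ]
  expect_equal(tied$probe_set, c("p3", "p4"))
  expect_equal(out$rank, seq_len(nrow(out)))
  # unmapped probe-sets pass through flagged
  out2 <- collapse_to_genes(tab, gm[1:2])
  expect_true(all(!out2$mapped[out2$gene %in% c("p3", "p4", "p5")]))
})

test_that("collapse agrees with a brute-force group-by-max oracle", {
  set.seed(21)
  n <- 60
  probe_sets <- sprintf("ps%03d", 1:n)
  gene_of <- sprintf("G%02d", sample(1:25, n, replace = TRUE))
  scores <- round(rnorm(n), 3)
  tab <- data.frame(probe_set = probe_sets, score = scores,
                    stringsAsFactors = FALSE)
  out <- collapse_to_genes(tab, setNames(gene_of, probe_sets))
  ora <- oracle_collapse(probe_sets, scores, gene_of)
  expect_equal(out$gene, ora$gene)
  expect_equal(out$probe_set, ora$probe_set)
  expect_equal(out$score, ora$score)
})

test_that("selection rejects degenerate inputs", {
  m <- matrix(1:8 + 0, nrow = 2,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expr <- expression_matrix(m, c("exp", "base", "base", "base"))
  expect_error(select_differential(expr, "exp", "base"), "2 samples")
  expect_error(selection_criteria(f_major = 0.2, f_minor = 0.3))
  expect_error(selection_criteria(slr_call_threshold = -1))
})
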