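# Literal double-loop reference implementation of the pairwise selection and
# scoring machinery. Deliberately naive (explicit loops, scalar t.test calls)
# and written only from the operation definitions, so it is an independent
# oracle for the vectorized implementation.

oracle_pairwise <- function(signals, exp_ids, base_ids,
                            f_major = 0.5, f_minor = 0.3, th = 0.5,
                            alpha = 0.05) {
  genes <- rownames(signals)
  n_pairs <- length(exp_ids) * length(base_ids)
  slr <- array(NA_real_, c(length(genes), length(exp_ids), length(base_ids)),
               dimnames = list(genes, exp_ids, base_ids))
  for (g in genes) {
    for (i in exp_ids) {
      for (j in base_ids) {
        slr[g, i, j] <- log2(signals[g, i]) - log2(signals[g, j])
      }
    }
  }
  res <- data.frame(probe_set = genes, n_increase = NA_integer_,
                    n_decrease = NA_integer_, mean_slr = NA_real_,
                    p_bonferroni = NA_real_, selected = NA,
                    direction = NA_character_, score = NA_real_,
                    stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    vals <- c()
    n_inc <- 0L; n_dec <- 0L
    for (i in exp_ids) {
      for (j in base_ids) {
        v <- slr[genes[gi], i, j]
        vals <- c(vals, v)
        if (v > th) n_inc <- n_inc + 1L
        if (v < -th) n_dec <- n_dec + 1L
      }
    }
    p <- if (stats::sd(vals) == 0) {
      if (mean(vals) == 0) 1 else 0
    } else stats::t.test(vals, mu = 0)$p.value
    p_bonf <- min(1, p * length(genes))
    lg_exp <- log2(signals[genes[gi], exp_ids])
    lg_base <- log2(signals[genes[gi], base_ids])
    cv_exp <- stats::sd(lg_exp) / abs(mean(lg_exp))
    cv_base <- stats::sd(lg_base) / abs(mean(lg_base))
    f_inc <- n_inc / n_pairs; f_dec <- n_dec / n_pairs
    up <- (f_inc >= f_major || (f_inc >= f_minor && cv_exp < cv_base)) &&
      p_bonf <= alpha
    down <- (f_dec >= f_major || (f_dec >= f_minor && cv_exp < cv_base)) &&
      p_bonf <= alpha
    dir <- "none"
    if (up && down) {
      dir <- if (f_inc > f_dec || (f_inc == f_dec && mean(vals) >= 0)) "up" else "down"
    } else if (up) dir <- "up" else if (down) dir <- "down"
    res$n_increase[gi] <- n_inc
    res$n_decrease[gi] <- n_dec
    res$mean_slr[gi] <- mean(vals)
    res$p_bonferroni[gi] <- p_bonf
    res$selected[gi] <- dir != "none"
    res$direction[gi] <- dir
    res$score[gi] <- mean(vals) * abs(n_inc - n_dec) / n_pairs
  }
  list(slr = slr, table = res, n_pairs = n_pairs)
}

# Group-by-max-|score| collapse oracle.
oracle_collapse <- function(probe_sets, scores, gene_of) {
  genes <- unique(gene_of)
  out <- data.frame(gene = genes, probe_set = NA_character_,
                    score = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    idx <- which(gene_of == genes[k])
    best <- idx[order(-abs(scores[idx]), probe_sets[idx])][1L]
    out$probe_set[k] <- probe_sets[best]
    out$score[k] <- scores[best]
  }
  out[order(-out$score, out$probe_set), ]
}

# Small positive expression matrix with two groups.
random_expr <- function(n_genes, n_exp, n_base, seed, sd = 0.5) {
  set.seed(seed)
  n <- n_exp + n_base
  m <- matrix(2^(6 + rnorm(n_genes * n, sd = sd)), nrow = n_genes,
              dimnames = list(sprintf("ps%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  expression_matrix(m, rep(c("exp", "base"), c(n_exp, n_base)))
}
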