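make_log2_panel <- function(seed = 1, n_analytes = 20, n_a = 6, n_b = 8) {
  set.seed(seed)
  toy_panel(
    matrix(rnorm((n_a + n_b) * n_analytes), n_a + n_b),
    groups = rep(c("BI-ALCL", "RS-A"), c(n_a, n_b))
  )
}

test_that("with d0 = 0 the moderated t collapses to the ordinary pooled t", {
  p <- make_log2_panel(seed = 2)
  ct <- contrast_spec("BI-ALCL", "RS-A")
  res <- moderated_t_test(p, ct, d0_override = 0)
  X <- panel_values(p)
  for (an in panel_analytes(p)) {
    oracle <- ordinary_t(X[p$group == "BI-ALCL", an], X[p$group == "RS-A", an])
    row <- res$table[res$table$analyte == an, ]
    expect_equal(row$t_mod, oracle$t, tolerance = 1e-9)
    expect_equal(row$p_raw, oracle$p, tolerance = 1e-9)
  }
})

test_that("with d0 = Inf every shrunken variance equals the prior", {
  p <- make_log2_panel(seed = 3)
  ct <- contrast_spec("BI-ALCL", "RS-A")
  res <- moderated_t_test(p, ct, d0_override = Inf)
  s0 <- res$prior$s0sq
  se <- sqrt(s0 * (1 / res$n_a + 1 / res$n_b))
  expect_equal(res$table$t_mod, res$table$logFC / se, tolerance = 1e-12)
})

test_that("shrinkage lands between the analyte and prior variances", {
  set.seed(4)
  # heterogeneous true variances so the prior df comes out finite
  X <- matrix(rnorm(14 * 20), 14) %*% diag(exp(rnorm(20, 0, 1)))
  p <- toy_panel(X, groups = rep(c("BI-ALCL", "RS-A"), each = 7))
  res <- moderated_t_test(p, contrast_spec("BI-ALCL", "RS-A"))
  d0 <- res$prior$d0
  s0 <- res$prior$s0sq
  expect_true(is.finite(d0) && d0 > 0)
  for (i in seq_len(nrow(res$table))) {
    s2 <- res$table$s2[i]
    shrunk <- (d0 * s0 + res$table$df_residual[i] * s2) / (d0 + res$table$df_residual[i])
    expect_gte(shrunk, min(s2, s0) - 1e-12)
    expect_lte(shrunk, max(s2, s0) + 1e-12)
  }
  expect_true(all(res$table$p_adj >= res$table$p_raw))
})

test_that("the moderated t matches the reference empirical-Bayes fit", {
  lp <- log2_panel(generate_panel(simulation_config(seed = 7)))
  ct <- contrast_spec("BI-ALCL", "RS")
  res <- moderated_t_test(lp, ct)
  keep <- lp$group %in% c("BI-ALCL", "RS-A", "RS-M", "RS-C")
  X <- t(panel_values(lp)[keep, ])
  grp <- factor(ifelse(lp$group[keep] == "BI-ALCL", "A", "B"), levels = c("B", "A"))
  fit <- limma::eBayes(limma::lmFit(X, stats::model.matrix(~grp)))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  mine <- res$table[match(rownames(tt), res$table$analyte), ]
  expect_equal(res$prior$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(res$prior$s0sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(mine$t_mod, tt$t, tolerance = 1e-8)
  expect_equal(mine$p_raw, tt$P.Value, tolerance = 1e-8)
  expect_equal(mine$logFC, tt$logFC, tolerance = 1e-10)
})

test_that("an analyte identical in both groups gets logFC 0, t 0, p 1", {
  p <- make_log2_panel(seed = 5)
  p$A1 <- rep(2.5, nrow(p)) # flat analyte; others keep the prior estimable
  p <- cytokine_panel(tibble::as_tibble(p), "log2_concentration")
  res <- moderated_t_test(p, contrast_spec("BI-ALCL", "RS-A"))
  row <- res$table[res$table$analyte == "A1", ]
  expect_identical(row$logFC, 0)
  expect_identical(row$t_mod, 0)
  expect_equal(row$p_raw, 1)
})

test_that("results come back sorted by decreasing log fold change", {
  res <- moderated_t_test(make_log2_panel(seed = 6), contrast_spec("BI-ALCL", "RS-A"))
  expect_true(all(diff(res$table$logFC) <= 0))
  expect_identical(tidy(res), res$table)
  g <- glance(res)
  expect_identical(g$n_a, 6L)
  expect_identical(g$n_b, 8L)
})

test_that("BH adjustment reproduces hand-computed and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(7)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) <= 1))
  }
})

test_that("volcano tiers and fold-line flags use strict inequalities", {
  p <- make_log2_panel(seed = 10, n_analytes = 4)
  res <- moderated_t_test(p, contrast_spec("BI-ALCL", "RS-A"))
  # overwrite with boundary cases and rebuild the export table
  res$table$p_adj <- c(0.009, 0.05, 0.010, 0.8)
  res$table$tier <- with(res$table, ifelse(p_adj < 0.01, "strict",
    ifelse(p_adj < 0.05, "loose", "ns")
  ))
  res$table$logFC <- c(2.0, 2.5, -3, 0.1)
  vt <- volcano_table(res)
  expect_identical(vt$tier, c("strict", "ns", "loose", "ns"))
  expect_identical(vt$beyond_fold_line, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(vt$neg_log10_p_adj, -log10(res$table$p_adj))
})

test_that("degenerate all-zero-variance panels are rejected", {
  df <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("BI-ALCL", "RS-A"), each = 3),
    A1 = c(1, 1, 1, 2, 2, 2), A2 = c(3, 3, 3, 3, 3, 3)
  )
  p <- cytokine_panel(df, "log2_concentration")
  expect_error(moderated_t_test(p, contrast_spec("BI-ALCL", "RS-A")), "zero")
})
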