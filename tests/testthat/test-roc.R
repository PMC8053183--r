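test_that("trapezoid AUC equals Mann-Whitney pair counting", {
  set.seed(31)
  for (rep in 1:20) {
    n_pos <- sample(3:10, 1)
    n_neg <- sample(3:10, 1)
    # coarse grid forces ties within and across classes
    values <- sample(1:6, n_pos + n_neg, replace = TRUE)
    labels <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    r <- roc_curve(values, labels)
    expect_equal(r$auc, mw_auc(values[labels], values[!labels]), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(32)
  values <- rlnorm(30, 1, 1)
  labels <- rep(c(TRUE, FALSE), c(12, 18))
  base <- roc_curve(values, labels)$auc
  transforms <- list(
    function(x) log(x),
    function(x) x^3,
    function(x) exp(x / 10),
    function(x) rank(x) # monotone on distinct values
  )
  for (f in transforms) {
    expect_equal(roc_curve(f(values), labels)$auc, base, tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1, Youden 1 and a degenerate CI", {
  d <- extremes_dataset(58.36, 6950, 0.35, 19.69, seed = 1)
  r <- roc_curve(d$values, d$labels)
  expect_identical(r$auc, 1)
  expect_identical(r$youden_index, 1)
  expect_identical(c(r$se_at_cutoff, r$sp_at_cutoff), c(1, 1))
  expect_identical(c(r$ci_low, r$ci_high), c(1, 1))
  expect_true("degenerate_ci" %in% r$flags)
  # the optimal cutoff is the midpoint of the between-class gap
  expect_equal(r$youden_cutoff, (19.69 + 58.36) / 2)
  expect_equal(glance(r)$cutoff_reported, 39.03)
})

test_that("Youden optimum matches an exhaustive threshold scan", {
  set.seed(33)
  for (rep in 1:10) {
    values <- round(rnorm(16), 1)
    labels <- rep(c(TRUE, FALSE), each = 8)
    r <- roc_curve(values, labels)
    grid <- sort(unique(values))
    cand <- (grid[-1] + grid[-length(grid)]) / 2
    j <- vapply(cand, function(t) {
      mean(values[labels] > t) + mean(values[!labels] <= t) - 1
    }, numeric(1))
    expect_equal(r$youden_index, max(j), tolerance = 1e-12)
    expect_equal(r$youden_cutoff, cand[which(j >= max(j) - 1e-12)[1]])
  }
})

test_that("sens falls and spec rises with the threshold", {
  set.seed(34)
  r <- roc_curve(rnorm(40), rep(c(TRUE, FALSE), 20))
  expect_true(all(diff(r$sens) <= 1e-12))
  expect_true(all(diff(r$spec) >= -1e-12))
  expect_identical(c(r$sens[1], r$spec[1]), c(1, 0)) # threshold -Inf
  expect_identical(c(utils::tail(r$sens, 1), utils::tail(r$spec, 1)), c(0, 1))
})

test_that("DeLong interval matches the reference implementation", {
  set.seed(35)
  values <- c(rnorm(12, 1), rnorm(20))
  labels <- rep(c(TRUE, FALSE), c(12, 20))
  ci <- auc_ci(values, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, values,
    direction = "<", quiet = TRUE
  ), method = "delong")
  expect_equal(unname(ci["low"]), as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(unname(ci["high"]), as.numeric(ref[3]), tolerance = 1e-9)

  boot <- auc_ci(values, labels, method = "bootstrap", n_boot = 500)
  r <- roc_curve(values, labels)
  expect_true(boot["low"] <= r$auc && r$auc <= boot["high"])
})

test_that("uninformative markers sit near AUC 0.5 and identical values flag", {
  set.seed(36)
  aucs <- replicate(50, {
    roc_curve(rnorm(60), rep(c(TRUE, FALSE), 30))$auc
  })
  expect_true(mean(aucs > 0.4 & aucs < 0.6) >= 0.8)

  r <- roc_curve(rep(3, 10), rep(c(TRUE, FALSE), 5))
  expect_identical(r$auc, 0.5)
  expect_true("all_values_identical" %in% r$flags)
})

test_that("ratio ROC equals the ROC of the pre-divided column", {
  set.seed(37)
  df <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:32),
    group = rep(c("BI-ALCL", "RS-A"), c(12, 20)),
    `IL-10` = rlnorm(32, 3, 1), `IL-6` = rlnorm(32, 5, 1)
  )
  p <- cytokine_panel(df, "concentration_pg_per_mL")
  r1 <- ratio_roc(p)
  r2 <- roc_curve(df$`IL-10` / df$`IL-6`, df$group == "BI-ALCL", positive = TRUE)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$youden_cutoff, r2$youden_cutoff)
  expect_identical(r1$marker, "IL-10/IL-6")

  # 10 of 12 positives above the cutoff, all negatives below: Se 83%, Sp 100%
  ratios <- c(
    0.2, 0.5, 1, 2, 3, 5, 8, 12, 16, 20.43, # 10 high positives
    0.005, 0.01, # 2 low positives
    seq(0.001, 0.10, length.out = 20) # negatives up to 0.10
  )
  labels <- rep(c(TRUE, FALSE), c(12, 20))
  rr <- roc_curve(ratios, labels)
  expect_equal(rr$se_at_cutoff, 10 / 12, tolerance = 1e-12)
  expect_identical(rr$sp_at_cutoff, 1)
  expect_equal(rr$youden_index, 10 / 12 - 0, tolerance = 1e-12)
  expect_equal(signif(rr$youden_cutoff, 3), 0.15) # midpoint of (0.10, 0.2)
})

test_that("degenerate label sets are rejected", {
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
  expect_error(auc_ci(1:4, c(TRUE, FALSE, FALSE, FALSE)), ">= 2 samples")
})
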