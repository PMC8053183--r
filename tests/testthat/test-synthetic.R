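test_that("calibration matches the closed-form log-normal moment equations", {
  spec <- calibrate_from_summary(tibble::tibble(
    analyte = "IL-10", group = "BI-ALCL",
    mean = 2601.06, sd = 2284.90, lower = 58.36, upper = 6950
  ))
  sigma2 <- log(1 + (2284.90 / 2601.06)^2)
  expect_equal(spec$sigma^2, sigma2, tolerance = 1e-12)
  expect_equal(spec$mu, log(2601.06) - sigma2 / 2, tolerance = 1e-12)

  # sd = 0 gives a point mass at the mean
  pt <- calibrate_from_summary(tibble::tibble(
    analyte = "x", group = "RS-A", mean = 5, sd = 0, lower = 4, upper = 6
  ))
  expect_identical(pt$sigma, 0)
  expect_equal(exp(pt$mu), 5)

  expect_error(
    calibrate_from_summary(tibble::tibble(
      analyte = "x", group = "RS-A", mean = 0, sd = 1, lower = 0, upper = 1
    )),
    "non-positive mean"
  )
})

test_that("untruncated draws hit the calibrated mean (Monte-Carlo oracle)", {
  spec <- calibrate_from_summary(table1_summaries())
  r <- spec[spec$analyte == "IL-10" & spec$group == "BI-ALCL", ]
  set.seed(42)
  x <- rlnorm(1e6, r$mu, r$sigma)
  expect_lt(abs(mean(x) - r$mean) / r$mean, 0.01)
  expect_lt(abs(sd(x) - r$sd) / r$sd, 0.02)
})

test_that("group means and SDs match targets within 3 Monte-Carlo SEs (untruncated)", {
  spec <- calibrate_from_summary(table1_summaries())
  spec <- spec[spec$group %in% c("BI-ALCL", "RS-A", "RS-C", "RS-M", "T-LCL"), ]
  set.seed(7)
  n <- 1e4
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    x <- rlnorm(n, r$mu, r$sigma)
    # exact asymptotic standard errors from the known log-normal moments
    raw <- function(k) exp(k * r$mu + k^2 * r$sigma^2 / 2)
    mu4 <- raw(4) - 4 * raw(3) * raw(1) + 6 * raw(2) * raw(1)^2 - 3 * raw(1)^4
    se_mean <- r$sd / sqrt(n)
    se_sd <- sqrt(max(mu4 - r$sd^4, 0) / n) / (2 * r$sd)
    expect_lt(abs(mean(x) - r$mean), 3 * se_mean)
    expect_lt(abs(sd(x) - r$sd), 3 * se_sd)
  }
})

test_that("panel generation is seed-deterministic and respects truncation", {
  cfg <- simulation_config(seed = 9)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(simulation_config(seed = 9))
  expect_identical(panel_values(p1), panel_values(p2))
  p3 <- generate_panel(simulation_config(seed = 10))
  expect_false(identical(panel_values(p1), panel_values(p3)))

  specs <- cfg$specs
  vals <- panel_values(p1)
  for (an in c("IL-10", "IL-13", "Eotaxin", "IL-6")) {
    for (g in seroma_groups) {
      r <- specs[specs$analyte == an & specs$group == g, ]
      v <- vals[p1$group == g, an]
      expect_true(all(v >= r$lower & v <= r$upper))
    }
  }
})

test_that("negligible truncation mass errors instead of hanging", {
  set.seed(1)
  expect_error(
    cytosig:::rtrunc_lnorm(5, mu = 0, sigma = 0.1, lower = 10, upper = 11),
    "negligible"
  )
  # healthy interval: every draw lies inside the bounds
  x <- cytosig:::rtrunc_lnorm(5000, mu = 0, sigma = 1, lower = 0.5, upper = 3)
  expect_true(all(x >= 0.5 & x <= 3))
})

test_that("null mode pools away all group differences", {
  cfg <- simulation_config(seed = 2, null_mode = TRUE)
  sp <- cfg$specs
  for (an in c("IL-10", "IL-13")) {
    mus <- sp$mu[sp$analyte == an & sp$group %in% seroma_groups]
    expect_equal(diff(range(mus)), 0)
  }
})

test_that("a spike scales its analyte x group cell and only that cell", {
  spike <- data.frame(analyte = "BDNF", group = "BI-ALCL", fold = 64)
  cfg <- simulation_config(seed = 2, spike = spike)
  base <- simulation_config(seed = 2)
  pick <- function(s, an, g) s$specs[s$specs$analyte == an & s$specs$group == g, ]
  expect_equal(pick(cfg, "BDNF", "BI-ALCL")$mean, 64 * pick(base, "BDNF", "BI-ALCL")$mean)
  expect_equal(pick(cfg, "BDNF", "RS-A")$mean, pick(base, "BDNF", "RS-A")$mean)
  expect_equal(pick(cfg, "EGF", "BI-ALCL")$mean, pick(base, "EGF", "BI-ALCL")$mean)
  expect_error(
    simulation_config(spike = data.frame(analyte = "nope", group = "RS-A", fold = 2)),
    "absent"
  )
})

test_that("forward_mfi reproduces the curve exactly at zero noise", {
  panel <- toy_panel(matrix(c(50, 100, 0, 200), 2),
    groups = c("BI-ALCL", "RS-A"),
    measure = "concentration_pg_per_mL", analytes = c("IL-10", "IL-6")
  )
  curves <- default_standard_curves(c("IL-10", "IL-6"))
  rec <- forward_mfi(panel, curves, noise_cv = 0)
  r1 <- rec[rec$sample_id == "s01" & rec$analyte == "IL-10" &
    rec$dilution == 1 & rec$replicate == 1, ]
  cv <- curves[curves$analyte == "IL-10", ]
  expect_equal(r1$mfi, fivepl(50, cv$a, cv$d, cv$c, cv$b, cv$g))
  # zero concentration sits at the lower asymptote
  r0 <- rec[rec$sample_id == "s01" & rec$analyte == "IL-6" & rec$dilution == 1, ]
  expect_equal(r0$mfi, rep(curves$a[curves$analyte == "IL-6"], 2))
  # duplicate wells at both dilutions
  expect_identical(nrow(rec), 2L * 2L * 2L * 2L)
})
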