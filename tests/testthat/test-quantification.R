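sample_groups_of <- function(panel) {
  tibble::tibble(sample_id = panel$sample_id, group = panel$group)
}

test_that("MFI averaging follows the duplicates-then-dilutions rule", {
  rec <- tibble::tibble(
    sample_id = "s01", analyte = "IL-6",
    replicate = c(1, 2, 1, 2), dilution = c(1, 1, 20, 20),
    mfi = c(100, 110, 80, 90)
  )
  p <- average_mfi(rec, c(s01 = "BI-ALCL"))
  expect_equal(p[["IL-6"]], 95) # (105 + 85) / 2
  expect_identical(panel_measure(p), "MFI")

  single <- rec[1, ]
  expect_equal(average_mfi(single, c(s01 = "BI-ALCL"))[["IL-6"]], 100)

  # permutation invariance over record order
  perm <- rec[c(3, 1, 4, 2), ]
  expect_equal(average_mfi(perm, c(s01 = "BI-ALCL"))[["IL-6"]], 95)
})

test_that("plate averaging matches a brute-force group-by oracle", {
  panel <- generate_panel(simulation_config(seed = 6))
  curves <- default_standard_curves(panel_analytes(panel))
  rec <- forward_mfi(panel, curves, noise_cv = 0.1, seed = 2)
  got <- average_mfi(rec, sample_groups_of(panel))
  for (cell in list(c("BI-ALCL-01", "IL-10"), c("TLBR-2", "Eotaxin"))) {
    sub <- rec[rec$sample_id == cell[1] & rec$analyte == cell[2], ]
    oracle <- mean(tapply(sub$mfi, sub$dilution, mean))
    expect_equal(got[[cell[2]]][got$sample_id == cell[1]], oracle)
  }
})

test_that("missing sample x analyte cells are reported, not imputed", {
  rec <- tibble::tibble(
    sample_id = c("s01", "s01", "s02"), analyte = c("IL-6", "IL-10", "IL-6"),
    replicate = 1, dilution = 1, mfi = c(100, 50, 80)
  )
  expect_error(
    average_mfi(rec, c(s01 = "BI-ALCL", s02 = "RS-A")),
    "missing plate records.*s02 x IL-10"
  )
})

test_that("5PL fitting recovers known parameters and nests the 4PL", {
  conc <- 10^seq(-1, 4, length.out = 10)
  mfi <- fivepl(conc, a = 50, d = 24000, c = 300, b = 1.3, g = 0.8)
  fit <- fit_standard_curve(conc, mfi, "IL-10")
  expect_equal(
    unlist(fit[c("a", "d", "c", "b", "g")]),
    c(a = 50, d = 24000, c = 300, b = 1.3, g = 0.8),
    tolerance = 1e-4
  )

  mfi4 <- fivepl(conc, a = 50, d = 24000, c = 300, b = 1.3, g = 1)
  fit4 <- fit_standard_curve(conc, mfi4, "x")
  expect_equal(fit4$g, 1, tolerance = 1e-3)

  expect_error(fit_standard_curve(conc, rep(500, 10), "x"), "constant MFI")
  expect_error(fit_standard_curve(conc[1:4], mfi[1:4], "x"), "at least 6")
  expect_error(fit_standard_curve(conc / (conc * 2) * 2, mfi, "x"), "orders of magnitude")
})

test_that("curve inversion is a flagged closed-form inverse", {
  curve <- default_standard_curves("IL-10", c_mid = 300)
  mfi50 <- fivepl(50, curve$a, curve$d, curve$c, curve$b, curve$g)
  expect_equal(invert_curve(curve, mfi50)$conc, 50, tolerance = 1e-12)
  expect_equal(invert_curve(curve, mfi50, dilution_factor = 20)$conc, 1000,
    tolerance = 1e-12
  )

  at_floor <- invert_curve(curve, curve$a)
  expect_identical(at_floor$flag, "below_range")
  expect_identical(at_floor$conc, 0)
  at_ceil <- invert_curve(curve, curve$d + 1)
  expect_identical(at_ceil$flag, "above_range")
  expect_identical(at_ceil$conc, Inf)

  # 1,000 random round trips
  set.seed(5)
  x <- 10^runif(1000, -2, 4)
  y <- fivepl(x, curve$a, curve$d, curve$c, curve$b, curve$g)
  back <- invert_curve(curve, y)$conc
  expect_lt(max(abs(back - x) / x), 1e-9)

  # strictly increasing between the asymptotes
  grid <- seq(curve$a + 1, curve$d - 1, length.out = 200)
  expect_true(all(diff(invert_curve(curve, grid)$conc) > 0))
})

test_that("zero-noise forward simulation round trips through quantification", {
  panel <- generate_panel(simulation_config(seed = 5))
  curves <- default_standard_curves(panel_analytes(panel), c_mid = 500)
  rec <- forward_mfi(panel, curves, noise_cv = 0)
  q <- quantify_concentrations(rec, curves, sample_groups_of(panel), dilution = 1)
  rel <- abs(panel_values(q) - panel_values(panel)) / panel_values(panel)
  expect_lt(max(rel), 1e-6)
})

test_that("log2 transformation shifts, tags and preserves order", {
  p <- toy_panel(matrix(c(8, 0, 3, 7), 2),
    groups = c("BI-ALCL", "RS-A"),
    measure = "MFI"
  )
  expect_equal(log2_panel(p, offset = 1)$A1, log2(c(9, 1)))
  expect_equal(log2_panel(p, offset = 1)$A1[2], 0)
  expect_identical(panel_measure(log2_panel(p, offset = 1)), "log2_MFI")
  expect_error(log2_panel(p, offset = 0), "non-positive")

  set.seed(8)
  rp <- toy_panel(matrix(rlnorm(50), 10),
    groups = rep(c("BI-ALCL", "RS-A"), 5),
    measure = "concentration_pg_per_mL"
  )
  lp <- log2_panel(rp)
  for (an in panel_analytes(rp)) {
    expect_identical(order(rp[[an]]), order(lp[[an]]))
  }
})
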