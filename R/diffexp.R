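#' Define a two-group contrast
#'
#' Groups are label sets over [seroma_groups]; `"RS"` expands to the three
#' benign subtypes. Optional explicit sample-id vectors restrict a side to a
#' subset (e.g. only the TLBR cell lines within T-LCL).
#'
#' @param group_a,group_b Group label or vector of labels for each side.
#'   The log fold change is reported as `mean(A) - mean(B)`.
#' @param alpha_strict,alpha_loose Significance tiers applied to the
#'   BH-adjusted p-value (defaults 0.01 and 0.05, the volcano-plot colours).
#' @param fold_line Fold-change reference line in log2 units (default 2,
#'   i.e. fourfold).
#' @param samples_a,samples_b Optional sample-id subsets.
#' @param name Contrast label; autogenerated if `NULL`.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(group_a, group_b, alpha_strict = 0.01,
                          alpha_loose = 0.05, fold_line = 2,
                          samples_a = NULL, samples_b = NULL, name = NULL) {
  ga <- resolve_group_labels(group_a)
  gb <- resolve_group_labels(group_b)
  if (length(intersect(ga, gb))) abort("contrast groups must be disjoint")
  if (is.null(name)) {
    name <- paste(
      paste(group_a, collapse = "+"), "vs", paste(group_b, collapse = "+")
    )
  }
  structure(
    list(
      group_a = ga, group_b = gb, alpha_strict = alpha_strict,
      alpha_loose = alpha_loose, fold_line = fold_line,
      samples_a = samples_a, samples_b = samples_b, name = name
    ),
    class = "contrast_spec"
  )
}

is_log2_panel <- function(panel) {
  m <- panel_measure(panel)
  m %in% c("log2_MFI", "log2_concentration") ||
    (m == "ratio_to_reference" && isTRUE(attr(panel, "log2")))
}

# Newton solve of trigamma(y) = x, vectorised; the inverse needed by the
# moment-matching estimate of the prior degrees of freedom.
trigamma_inverse <- function(x) {
  out <- x
  large <- x > 1e7
  out[large] <- 1 / sqrt(x[large])
  small <- x < 1e-6
  out[small] <- 1 / x[small]
  mid <- !large & !small
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

# Empirical-Bayes hyperparameters (prior df d0, prior variance s0^2) by
# moment-matching the log sample variances to their scaled-F theory:
#   e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)
#   E[e] = log s0^2 + digamma(d0/2) - log(d0/2),  Var[e] = trigamma(d_g/2) + trigamma(d0/2).
# A non-positive excess-variance estimate gives d0 = +Inf (no analyte-level
# variance heterogeneity beyond sampling noise).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) abort("all residual variances are zero: prior undefined")
  s2 <- s2[ok]
  df <- rep_len(df, length(ok))[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- if (n > 1) sum((e - emean)^2) / (n - 1) else 0
  evar <- evar - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated t-test between two groups
#'
#' For each analyte g the log fold change is the difference of group means
#' on the log2 scale; the pooled residual variance `s_g^2` (on
#' `n_A + n_B - 2` df) is shrunk towards a panel-wide prior,
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, with `(d0, s0^2)`
#' estimated once across analytes by moment matching (see source). The
#' moderated statistic `t~ = logFC / (s~ sqrt(1/n_A + 1/n_B))` is referred
#' to a Student t on `d0 + d_g` df (standard normal when `d0 = Inf`).
#' Raw p-values are Benjamini-Hochberg adjusted across the panel.
#'
#' @param panel A log2 [cytokine_panel] (or log2 ratio panel).
#' @param contrast A [contrast_spec()].
#' @param d0_override Force the prior df: `0` recovers the ordinary pooled
#'   two-sample t; `Inf` fully replaces each variance by the prior.
#' @return A `cytokine_contrast` object; `tidy()` gives the per-analyte
#'   table sorted by decreasing log fold change, `glance()` the
#'   hyperparameters.
#' @export
moderated_t_test <- function(panel, contrast, d0_override = NULL) {
  if (!is_log2_panel(panel)) {
    abort("panel must be on the log2 scale (see log2_panel())")
  }
  stopifnot(inherits(contrast, "contrast_spec"))
  in_a <- panel$group %in% contrast$group_a
  in_b <- panel$group %in% contrast$group_b
  if (!is.null(contrast$samples_a)) in_a <- in_a & panel$sample_id %in% contrast$samples_a
  if (!is.null(contrast$samples_b)) in_b <- in_b & panel$sample_id %in% contrast$samples_b
  n_a <- sum(in_a)
  n_b <- sum(in_b)
  if (n_a < 2L || n_b < 2L) {
    abort(sprintf(
      "each side needs >= 2 samples (got %d vs %d for %s)", n_a, n_b, contrast$name
    ))
  }
  X <- panel_values(panel)
  A <- X[in_a, , drop = FALSE]
  B <- X[in_b, , drop = FALSE]
  mean_a <- colMeans(A)
  mean_b <- colMeans(B)
  logFC <- mean_a - mean_b
  ss <- function(M) colSums(sweep(M, 2, colMeans(M))^2)
  df_res <- n_a + n_b - 2
  s2 <- (ss(A) + ss(B)) / df_res
  prior <- fit_variance_prior(s2, df_res)
  if (!is.null(d0_override)) prior$d0 <- d0_override
  d0 <- prior$d0
  s2_shrunk <- if (is.infinite(d0)) {
    rep(prior$s0sq, length(s2))
  } else {
    (d0 * prior$s0sq + df_res * s2) / (d0 + df_res)
  }
  if (any(s2_shrunk <= 0)) {
    abort("non-positive shrunken variance (all-zero variances with d0 = 0?)")
  }
  se <- sqrt(s2_shrunk * (1 / n_a + 1 / n_b))
  t_mod <- ifelse(logFC == 0 & se == 0, 0, logFC / se)
  df_total <- d0 + df_res
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_adj <- bh_adjust(p_raw)
  tier <- dplyr::case_when(
    p_adj < contrast$alpha_strict ~ "strict",
    p_adj < contrast$alpha_loose ~ "loose",
    TRUE ~ "ns"
  )
  tab <- tibble(
    analyte = colnames(X), logFC = unname(logFC), s2 = unname(s2),
    df_residual = df_res, t_mod = unname(t_mod),
    p_raw = unname(p_raw), p_adj = unname(p_adj), tier = tier
  )
  tab <- tab[order(-tab$logFC), ]
  structure(
    list(
      table = tab, prior = prior, contrast = contrast,
      n_a = n_a, n_b = n_b, df_total = df_total
    ),
    class = "cytokine_contrast"
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: `p_adj_(i) = min_{j >= i} min(1, m p_(j) / j)`,
#' returned in the input order. Thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Volcano-table export of a contrast
#'
#' The tabular backbone of a volcano plot: log fold change against
#' `-log10` adjusted p, with significance tier (strict `p_adj < 0.01`,
#' loose `p_adj < 0.05`, both strict inequalities) and a flag for points
#' beyond the fourfold line (`|logFC| > fold_line`, strict).
#'
#' @param result A `cytokine_contrast`.
#' @return Tibble with `analyte`, `logFC`, `neg_log10_p_adj`, `tier`,
#'   `beyond_fold_line`.
#' @export
volcano_table <- function(result) {
  stopifnot(inherits(result, "cytokine_contrast"))
  tab <- result$table
  tibble(
    analyte = tab$analyte, logFC = tab$logFC,
    neg_log10_p_adj = -log10(tab$p_adj), tier = tab$tier,
    beyond_fold_line = abs(tab$logFC) > result$contrast$fold_line
  )
}

#' @export
print.cytokine_contrast <- function(x, ...) {
  cat("<cytokine_contrast> ", x$contrast$name, " (", x$n_a, " vs ", x$n_b,
    " samples)\n",
    sep = ""
  )
  cat(sprintf(
    "  prior: d0 = %s, s0^2 = %.4g; %d/%d analytes with adjusted p < %.2g\n",
    format(x$prior$d0, digits = 4), x$prior$s0sq,
    sum(x$table$tier == "strict"), nrow(x$table), x$contrast$alpha_strict
  ))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname moderated_t_test
#' @param x A `cytokine_contrast`.
#' @param ... Unused.
#' @export
tidy.cytokine_contrast <- function(x, ...) x$table

#' @rdname moderated_t_test
#' @export
glance.cytokine_contrast <- function(x, ...) {
  tibble(
    contrast = x$contrast$name, n_a = x$n_a, n_b = x$n_b,
    d0 = x$prior$d0, s0sq = x$prior$s0sq,
    n_strict = sum(x$table$tier == "strict"),
    n_loose = sum(x$table$tier == "loose")
  )
}

#' Volcano plot of a contrast
#'
#' @param object A `cytokine_contrast`.
#' @param ... Unused.
#' @return A ggplot: logFC vs -log10 adjusted p, tiers coloured, fourfold
#'   and p = 0.01 reference lines dashed.
#' @export
autoplot.cytokine_contrast <- function(object, ...) {
  df <- volcano_table(object)
  fl <- object$contrast$fold_line
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC, y = .data$neg_log10_p_adj)) +
    ggplot2::geom_vline(xintercept = c(-fl, fl), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$contrast$alpha_strict),
      linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tier)) +
    ggplot2::scale_colour_manual(values = c(strict = "red", loose = "blue", ns = "grey60")) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 adjusted p",
      title = object$contrast$name
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
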