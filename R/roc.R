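# Round half away from zero at `digits` decimals; a small relative epsilon
# guards midpoints such as (19.69 + 58.36)/2 that float arithmetic stores a
# hair below the exact decimal .5.
round_half_up <- function(x, digits = 2) {
  scaled <- abs(x) * 10^digits
  sign(x) * floor(scaled + 0.5 + 1e-7 * pmax(scaled, 1)) / 10^digits
}

#' ROC curve with Youden-optimal cutoff
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' pooled values, plus `-Inf` and `+Inf`; a sample is called positive when
#' its value exceeds the threshold (high values indicate the positive
#' class). Sensitivity and specificity are exact count fractions; the AUC
#' is the trapezoid over the full curve, which equals the Mann-Whitney
#' estimate `(#[pos > neg] + #[ties]/2) / (n_pos n_neg)`. The optimal
#' cutoff maximizes the Youden index `sens + spec - 1` over finite
#' thresholds, ties broken towards the smallest cutoff. The 95% AUC
#' confidence interval uses the DeLong variance (see [auc_ci()]).
#'
#' @param values Per-sample marker values.
#' @param labels Per-sample class labels (any two-level vector, or logical).
#' @param positive Label of the positive class (default `"BI-ALCL"`, or
#'   `TRUE` for logical labels).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param seed Seed for the bootstrap interval.
#' @return A `roc_result` object. `tidy()` returns the threshold grid,
#'   `glance()` the summary statistics (`auc`, `ci_low`, `ci_high`,
#'   `youden_cutoff`, `youden_index`, `se_at_cutoff`, `sp_at_cutoff`).
#' @export
roc_curve <- function(values, labels, positive = "BI-ALCL",
                      ci_method = c("delong", "bootstrap"), seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (is.logical(labels)) positive <- TRUE
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) abort("both classes must be non-empty")
  if (anyNA(values) || any(!is.finite(values))) abort("values must be finite")
  pos <- values[is_pos]
  neg <- values[!is_pos]
  uv <- sort(unique(values))
  flagged <- character(0)
  mids <- if (length(uv) > 1L) (uv[-length(uv)] + uv[-1L]) / 2 else numeric(0)
  thresholds <- c(-Inf, mids, Inf)
  sens <- vapply(thresholds, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg <= t), numeric(1))
  # trapezoid over (1 - spec, sens), traced from threshold -Inf (1,1) to +Inf (0,0)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  if (length(uv) == 1L) {
    auc <- 0.5
    flagged <- c(flagged, "all_values_identical")
  }
  finite <- is.finite(thresholds)
  youden <- sens + spec - 1
  if (any(finite)) {
    jmax <- max(youden[finite])
    at <- which(finite & youden >= jmax - 1e-12)[1]
    youden_cutoff <- thresholds[at]
    youden_index <- youden[at]
    se_at <- sens[at]
    sp_at <- spec[at]
  } else {
    youden_cutoff <- NA_real_
    youden_index <- 0
    se_at <- NA_real_
    sp_at <- NA_real_
    flagged <- c(flagged, "no_finite_threshold")
  }
  ci <- auc_ci(values, labels,
    positive = positive, method = ci_method, seed = seed
  )
  structure(
    list(
      positive = positive, n_pos = length(pos), n_neg = length(neg),
      thresholds = thresholds, sens = sens, spec = spec,
      auc = auc, ci_low = ci[["low"]], ci_high = ci[["high"]],
      ci_method = ci_method,
      youden_cutoff = youden_cutoff, youden_index = youden_index,
      se_at_cutoff = se_at, sp_at_cutoff = sp_at,
      flags = c(flagged, attr(ci, "flag"))
    ),
    class = "roc_result"
  )
}

#' Youden-optimal operating point
#'
#' @param roc A `roc_result`.
#' @return Tibble with `cutoff`, `se`, `sp`, `youden_index`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  tibble(
    cutoff = roc$youden_cutoff, se = roc$se_at_cutoff, sp = roc$sp_at_cutoff,
    youden_index = roc$youden_index
  )
}

# DeLong placement variance of the Mann-Whitney AUC.
delong_variance <- function(pos, neg) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  var10 <- if (length(pos) > 1) stats::var(v10) else 0
  var01 <- if (length(neg) > 1) stats::var(v01) else 0
  var10 / length(pos) + var01 / length(neg)
}

#' Confidence interval for the AUC
#'
#' `"delong"` gives the asymptotic normal interval with the DeLong
#' placement variance, clipped to `[0, 1]`. Perfect separation has zero
#' placement variance; the interval degenerates to `[auc, auc]` and is
#' flagged (this is how a printed `95% CI 1.00-1.00` arises). The
#' `"bootstrap"` alternative is a 2,000-replicate stratified percentile
#' interval.
#'
#' @inheritParams roc_curve
#' @param method `"delong"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates.
#' @return Named vector `c(low, high)`, with a `flag` attribute when
#'   degenerate.
#' @export
auc_ci <- function(values, labels, positive = "BI-ALCL",
                   method = c("delong", "bootstrap"), level = 0.95,
                   n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (is.logical(labels)) positive <- TRUE
  is_pos <- labels == positive
  pos <- values[is_pos]
  neg <- values[!is_pos]
  if (length(pos) < 2L || length(neg) < 2L) {
    abort("both classes need >= 2 samples for a confidence interval")
  }
  mw_auc <- function(p, n) {
    (sum(outer(p, n, ">")) + 0.5 * sum(outer(p, n, "=="))) / (length(p) * length(n))
  }
  auc <- mw_auc(pos, neg)
  if (method == "delong") {
    v <- delong_variance(pos, neg)
    if (v <= 0) {
      out <- c(low = auc, high = auc)
      attr(out, "flag") <- "degenerate_ci"
      return(out)
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    out <- c(
      low = max(0, auc - z * sqrt(v)),
      high = min(1, auc + z * sqrt(v))
    )
    return(out)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    mw_auc(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
  }, numeric(1))
  q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(low = q[1], high = q[2])
}

#' ROC analysis of a cytokine ratio
#'
#' Computes the per-sample numerator/denominator ratio and runs
#' [roc_curve()] on it. Ratio cutoffs are conventionally reported at 3
#' significant figures (see `glance()`'s `cutoff_reported`).
#'
#' @param panel A raw-scale [cytokine_panel].
#' @param numerator,denominator Analyte names (default IL-10 over IL-6).
#' @param positive Positive-class group label (default `"BI-ALCL"`); every
#'   other sample in the panel is a negative.
#' @param ... Passed on to [roc_curve()].
#' @return A `roc_result` for the ratio.
#' @export
ratio_roc <- function(panel, numerator = "IL-10", denominator = "IL-6",
                      positive = "BI-ALCL", ...) {
  numerator <- match_analytes(numerator)
  denominator <- match_analytes(denominator)
  den <- panel[[denominator]]
  if (is.null(panel[[numerator]]) || is.null(den)) {
    abort("numerator/denominator analyte not in panel")
  }
  if (any(den <= 0)) {
    abort(paste0(
      "non-positive denominator for sample(s): ",
      paste(panel$sample_id[den <= 0], collapse = ", ")
    ))
  }
  ratio <- panel[[numerator]] / den
  out <- roc_curve(ratio, panel$group == positive, positive = TRUE, ...)
  out$marker <- paste0(numerator, "/", denominator)
  out$ratio_scale <- TRUE
  out
}

#' Single-analyte ROC from a panel
#'
#' @param panel A raw-scale [cytokine_panel].
#' @param analyte Analyte name.
#' @param positive Positive-class group label.
#' @param ... Passed on to [roc_curve()].
#' @return A `roc_result`.
#' @export
analyte_roc <- function(panel, analyte, positive = "BI-ALCL", ...) {
  analyte <- match_analytes(analyte)
  if (!analyte %in% panel_analytes(panel)) abort(paste0(analyte, " not in panel"))
  out <- roc_curve(panel[[analyte]], panel$group == positive, positive = TRUE, ...)
  out$marker <- analyte
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>", if (!is.null(x$marker)) x$marker else "", " (",
    x$n_pos, " positives vs ", x$n_neg, " negatives)\n",
    sep = ""
  )
  cat(sprintf(
    "  AUC %.3f (95%% CI %.3f-%.3f); cutoff %s: Se %.0f%%, Sp %.0f%%, Youden %.2f\n",
    x$auc, x$ci_low, x$ci_high, format(x$youden_cutoff, digits = 4),
    100 * x$se_at_cutoff, 100 * x$sp_at_cutoff, x$youden_index
  ))
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname roc_curve
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(threshold = x$thresholds, sens = x$sens, spec = x$spec)
}

#' @rdname roc_curve
#' @export
glance.roc_result <- function(x, ...) {
  reported <- if (isTRUE(x$ratio_scale)) {
    signif(x$youden_cutoff, 3)
  } else {
    round_half_up(x$youden_cutoff, 2)
  }
  tibble(
    marker = if (!is.null(x$marker)) x$marker else NA_character_,
    n_pos = x$n_pos, n_neg = x$n_neg,
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    youden_cutoff = x$youden_cutoff, cutoff_reported = reported,
    se_at_cutoff = x$se_at_cutoff, sp_at_cutoff = x$sp_at_cutoff,
    youden_index = x$youden_index,
    flags = paste(x$flags, collapse = ";")
  )
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the Youden-optimal point marked
#'   in red.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  opt <- youden_optimal(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(
      data = tibble(x = 1 - opt$sp, y = opt$se),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "red", size = 2
    ) +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf(
        "%s: AUC %.2f (95%% CI %.2f-%.2f)",
        if (!is.null(object$marker)) object$marker else "ROC",
        object$auc, object$ci_low, object$ci_high
      )
    ) +
    ggplot2::theme_minimal()
}
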