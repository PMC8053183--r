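#' Leave-one-out robustness of differential-expression calls
#'
#' Reruns the moderated t-test once per sample in the contrast, each time
#' with that one sample removed (empirical-Bayes hyperparameters
#' re-estimated from scratch in every round), and counts per analyte how
#' many of the `n_A + n_B` rounds reach `p < alpha`. An analyte is robust
#' when it is significant in every round. The report also carries, per
#' analyte, the number of rounds below a stricter display threshold
#' (default 0.001), the filter used when plotting the counts, which must not
#' be conflated with the counting threshold.
#'
#' @param panel A log2 [cytokine_panel].
#' @param contrast A [contrast_spec()].
#' @param alpha Counting threshold (default 0.01).
#' @param p_kind Count on `"adjusted"` (BH, the default, consistent with the
#'   main analysis) or `"raw"` p-values.
#' @param display_alpha Stricter threshold tracked for display filtering.
#' @return A `loo_report`: tibble with `analyte`, `count`, `rounds`,
#'   `robust`, `display_count`, plus contrast metadata attributes.
#' @export
loo_robustness <- function(panel, contrast, alpha = 0.01,
                           p_kind = c("adjusted", "raw"),
                           display_alpha = 0.001) {
  p_kind <- match.arg(p_kind)
  stopifnot(inherits(contrast, "contrast_spec"))
  in_a <- panel$group %in% contrast$group_a
  in_b <- panel$group %in% contrast$group_b
  if (!is.null(contrast$samples_a)) in_a <- in_a & panel$sample_id %in% contrast$samples_a
  if (!is.null(contrast$samples_b)) in_b <- in_b & panel$sample_id %in% contrast$samples_b
  if (sum(in_a) < 3L || sum(in_b) < 3L) {
    abort("each group must keep >= 2 samples after any single removal")
  }
  members <- panel$sample_id[in_a | in_b]
  rounds <- length(members)
  p_col <- if (p_kind == "adjusted") "p_adj" else "p_raw"
  analytes <- panel_analytes(panel)
  count <- stats::setNames(integer(length(analytes)), analytes)
  display_count <- count
  for (s in members) {
    sub <- panel[panel$sample_id != s, ]
    sub <- restore_panel_like(sub, panel)
    res <- moderated_t_test(sub, contrast)
    p <- stats::setNames(res$table[[p_col]], res$table$analyte)[analytes]
    count <- count + (p < alpha)
    display_count <- display_count + (p < display_alpha)
  }
  out <- tibble(
    analyte = analytes, count = as.integer(count), rounds = rounds,
    robust = as.integer(count) == rounds,
    display_count = as.integer(display_count)
  )
  structure(out,
    class = c("loo_report", class(tibble())),
    contrast = contrast$name, alpha = alpha, p_kind = p_kind,
    display_alpha = display_alpha
  )
}

# Rebuild panel class/measure attributes after row subsetting.
restore_panel_like <- function(data, template) {
  out <- cytokine_panel(as_tibble(data), measure = panel_measure(template))
  if (isTRUE(attr(template, "log2"))) attr(out, "log2") <- TRUE
  out
}

#' Histogram of leave-one-out counts
#'
#' @param object A `loo_report`.
#' @param display_filter Show only analytes whose `display_count` is
#'   positive, i.e. differentially expressed below the display threshold in
#'   at least one round (default `TRUE`, the published display convention).
#' @param ... Unused.
#' @return A ggplot bar chart of counts per analyte.
#' @export
autoplot.loo_report <- function(object, display_filter = TRUE, ...) {
  df <- as_tibble(object)
  if (display_filter) df <- df[df$display_count > 0L, ]
  df <- df[order(-df$count), ]
  df$analyte <- factor(df$analyte, levels = df$analyte)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$analyte, y = .data$count, fill = .data$robust)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = df$rounds[1], linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "rounds significant",
      title = paste0("Leave-one-out robustness: ", attr(object, "contrast"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Express every analyte relative to a reference cytokine
#'
#' Divides, per sample, every other analyte by that sample's reference
#' value (IL-6 by default: a pro-inflammatory cytokine detectable in every
#' seroma, which makes per-sample ratios comparable across assays that are
#' not calibrated to a common standard). The reference column would be
#' identically 1 and is dropped. Downstream differential analysis runs on
#' the log2 ratios, where the ratio log fold change equals the difference
#' of (log2 analyte - log2 reference) group means.
#'
#' @param panel A raw-scale [cytokine_panel] (MFI or concentrations).
#' @param reference_analyte Denominator analyte (default `"IL-6"`).
#' @return A [cytokine_panel] with measure `ratio_to_reference` and one
#'   column fewer.
#' @export
ratio_transform <- function(panel, reference_analyte = "IL-6") {
  measure <- panel_measure(panel)
  if (measure %in% c("log2_MFI", "log2_concentration", "ratio_to_reference")) {
    abort("ratio_transform expects a raw-scale panel")
  }
  reference_analyte <- match_analytes(reference_analyte)
  if (!reference_analyte %in% panel_analytes(panel)) {
    abort(paste0("reference analyte ", reference_analyte, " not in panel"))
  }
  ref <- panel[[reference_analyte]]
  bad <- ref <= 0
  if (any(bad)) {
    abort(paste0(
      "non-positive reference values for sample(s): ",
      paste(panel$sample_id[bad], collapse = ", ")
    ))
  }
  keep <- setdiff(panel_analytes(panel), reference_analyte)
  out <- panel[, c("sample_id", "group", keep)]
  for (an in keep) out[[an]] <- out[[an]] / ref
  out <- cytokine_panel(as_tibble(out), measure = "ratio_to_reference")
  attr(out, "reference") <- reference_analyte
  out
}

#' Group summaries of a per-sample cytokine ratio
#'
#' Computes the ratio sample by sample *before* aggregating (a ratio of
#' group means would not reproduce per-sample ranges), then reports
#' mean, SD (n-1 denominator) and range per group. Single-sample groups get
#' SD 0 and are flagged.
#'
#' @param panel A raw-scale [cytokine_panel].
#' @param numerator,denominator Analyte names (default IL-10 over IL-6).
#' @return Tibble: `group`, `n`, `mean`, `sd`, `min`, `max`, `flag`.
#' @export
group_ratio_summary <- function(panel, numerator = "IL-10", denominator = "IL-6") {
  numerator <- match_analytes(numerator)
  denominator <- match_analytes(denominator)
  for (an in c(numerator, denominator)) {
    if (!an %in% panel_analytes(panel)) abort(paste0(an, " not in panel"))
  }
  den <- panel[[denominator]]
  if (any(den <= 0)) {
    abort(paste0(
      "non-positive denominator for sample(s): ",
      paste(panel$sample_id[den <= 0], collapse = ", ")
    ))
  }
  ratio <- panel[[numerator]] / den
  tibble(group = panel$group, ratio = ratio) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$ratio),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$ratio), 0),
      min = min(.data$ratio),
      max = max(.data$ratio),
      flag = ifelse(dplyr::n() > 1, "ok", "single_sample"),
      .groups = "drop"
    )
}
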