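#' Default contrast set of the analysis
#'
#' The ten pairwise comparisons of the study design: BI-ALCL against all
#' reactive seromas and each subtype, the cell-line comparisons (including
#' the TLBR-only subset), and the three between-subtype comparisons.
#'
#' @param tlbr_ids Sample ids of the TLBR cell lines within T-LCL.
#' @return Named list of [contrast_spec()]s.
#' @export
default_contrasts <- function(tlbr_ids = paste0("TLBR-", 1:4)) {
  list(
    "BI-ALCL vs RS" = contrast_spec("BI-ALCL", "RS"),
    "BI-ALCL vs RS-A" = contrast_spec("BI-ALCL", "RS-A"),
    "BI-ALCL vs RS-M" = contrast_spec("BI-ALCL", "RS-M"),
    "BI-ALCL vs RS-C" = contrast_spec("BI-ALCL", "RS-C"),
    "T-LCL vs RS" = contrast_spec("T-LCL", "RS"),
    "BI-ALCL vs T-LCL" = contrast_spec("BI-ALCL", "T-LCL"),
    "BI-ALCL vs TLBR" = contrast_spec("BI-ALCL", "T-LCL",
      samples_b = tlbr_ids, name = "BI-ALCL vs TLBR"
    ),
    "RS-A vs RS-C" = contrast_spec("RS-A", "RS-C"),
    "RS-A vs RS-M" = contrast_spec("RS-A", "RS-M"),
    "RS-C vs RS-M" = contrast_spec("RS-C", "RS-M")
  )
}

#' Group summary table for selected analytes
#'
#' Mean, SD (n-1 denominator) and range per group, plus moderated-t
#' p-values for the standard comparison list (BI-ALCL vs pooled RS, each RS
#' subtype and T-LCL; T-LCL vs pooled RS). P-values are computed on the
#' log2 scale by default, matching the differential analysis; set
#' `log2_p = FALSE` to test the raw values.
#'
#' @param panel A raw-scale [cytokine_panel].
#' @param analytes Analytes to summarise (default the four biomarker
#'   candidates).
#' @param log2_p Run the moderated t on log2-transformed values.
#' @return List with `summaries` (per analyte x group) and `p_values`
#'   (per analyte x comparison) tibbles.
#' @export
summarize_groups <- function(panel, analytes = c("IL-10", "IL-6", "IL-13", "Eotaxin"),
                             log2_p = TRUE) {
  analytes <- match_analytes(analytes)
  miss <- setdiff(analytes, panel_analytes(panel))
  if (length(miss)) abort(paste0("analyte(s) not in panel: ", paste(miss, collapse = ", ")))
  groups_present <- unique(panel$group)
  long <- tidyr::pivot_longer(
    as_tibble(panel)[, c("sample_id", "group", analytes)],
    dplyr::all_of(analytes),
    names_to = "analyte", values_to = "value"
  )
  pooled <- long[long$group %in% c("RS-A", "RS-M", "RS-C"), ]
  pooled$group <- "RS-All"
  summaries <- dplyr::bind_rows(long, pooled) |>
    dplyr::group_by(.data$analyte, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
      min = min(.data$value), max = max(.data$value),
      .groups = "drop"
    )
  comparisons <- list(
    "BI-ALCL vs RS-All" = c("BI-ALCL", "RS"),
    "BI-ALCL vs RS-A" = c("BI-ALCL", "RS-A"),
    "BI-ALCL vs RS-M" = c("BI-ALCL", "RS-M"),
    "BI-ALCL vs RS-C" = c("BI-ALCL", "RS-C"),
    "BI-ALCL vs T-LCL" = c("BI-ALCL", "T-LCL"),
    "T-LCL vs RS-All" = c("T-LCL", "RS")
  )
  test_panel <- if (log2_p) log2_panel(panel) else panel
  pv <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    n_a <- sum(panel$group %in% resolve_group_labels(cmp[1]))
    n_b <- sum(panel$group %in% resolve_group_labels(cmp[2]))
    if (n_a < 2L || n_b < 2L) next
    ct <- contrast_spec(cmp[1], cmp[2], name = nm)
    res <- if (log2_p) {
      moderated_t_test(test_panel, ct)
    } else {
      moderated_t_raw(test_panel, ct)
    }
    tab <- res$table[res$table$analyte %in% analytes, c("analyte", "p_raw", "p_adj")]
    tab$comparison <- nm
    pv[[nm]] <- tab
  }
  list(summaries = summaries, p_values = dplyr::bind_rows(pv))
}

# Moderated t on untransformed values (the measure-tag escape hatch for
# summary tables quoted on the absolute concentration scale).
moderated_t_raw <- function(panel, contrast, d0_override = NULL) {
  fake <- panel
  attr(fake, "measure") <- "log2_concentration"
  moderated_t_test(fake, contrast, d0_override = d0_override)
}

#' Run the full seroma cytokine analysis
#'
#' Orchestrates every stage on a concentration (or MFI) panel: log2
#' transformation, the ten default contrasts, leave-one-out robustness for
#' the BI-ALCL vs RS-subtype comparisons, the IL-6 ratio differential
#' analysis, hierarchical clustering and MDS on the Spearman distance, ROC
#' summaries for the candidate biomarkers and the IL-10/IL-6 ratio, and a
#' group-summary table. When `out_dir` is given, every table is written as
#' a CSV stamped with a configuration hash comment, the dendrogram
#' additionally as Newick text; reruns with identical input are
#' byte-identical.
#'
#' @param panel A raw-scale [cytokine_panel].
#' @param contrasts List of [contrast_spec()]s (default [default_contrasts()],
#'   pruned to the groups present).
#' @param roc_analytes Analytes given a ROC analysis (positive class
#'   BI-ALCL vs all seroma samples; cell lines excluded).
#' @param ratio_pairs List of `c(numerator, denominator)` ratio ROCs.
#' @param loo_contrasts Names of contrasts given leave-one-out reports.
#' @param out_dir Optional output directory for CSV/Newick exports.
#' @param seed Seed recorded in the run log and used for any bootstrap.
#' @return A `cytosig_run` list with elements `contrasts`, `loo`,
#'   `ratio_contrasts`, `clustering`, `mds`, `roc`, `summary`, `log`.
#' @export
run_pipeline <- function(panel,
                         contrasts = NULL,
                         roc_analytes = c("IL-10", "IL-13", "Eotaxin", "IL-6"),
                         ratio_pairs = list(c("IL-10", "IL-6")),
                         loo_contrasts = c(
                           "BI-ALCL vs RS-A", "BI-ALCL vs RS-M",
                           "BI-ALCL vs RS-C"
                         ),
                         out_dir = NULL, seed = 1L) {
  validate_panel(panel)
  groups_present <- unique(panel$group)
  if (is.null(contrasts)) {
    contrasts <- default_contrasts()
    keep <- vapply(contrasts, function(ct) {
      all(c(ct$group_a, ct$group_b) %in% groups_present)
    }, logical(1))
    contrasts <- contrasts[keep]
  } else {
    for (ct in contrasts) {
      bad <- setdiff(c(ct$group_a, ct$group_b), groups_present)
      if (length(bad)) {
        abort(paste0(
          "contrast ", ct$name, " names group(s) absent from the panel: ",
          paste(bad, collapse = ", ")
        ))
      }
    }
  }
  logp <- log2_panel(panel)

  contrast_results <- lapply(contrasts, function(ct) moderated_t_test(logp, ct))

  loo_reports <- list()
  for (nm in intersect(loo_contrasts, names(contrasts))) {
    loo_reports[[nm]] <- loo_robustness(logp, contrasts[[nm]])
  }

  ratio_panel <- log2_panel(ratio_transform(panel))
  ratio_results <- lapply(contrasts, function(ct) {
    tryCatch(moderated_t_test(ratio_panel, ct), error = function(e) NULL)
  })
  ratio_results <- ratio_results[!vapply(ratio_results, is.null, logical(1))]

  dist <- spearman_distance(panel)
  dend <- ward_d2_linkage(dist)
  mds <- classical_mds(dist, k = 3)

  seroma_panel <- restore_panel_like(panel[panel$group != "T-LCL", ], panel)
  roc_results <- list()
  for (an in roc_analytes) {
    an_c <- match_analytes(an)
    if (!an_c %in% panel_analytes(seroma_panel)) next
    roc_results[[an_c]] <- analyte_roc(seroma_panel, an_c, seed = seed)
  }
  for (pair in ratio_pairs) {
    nm <- paste0(match_analytes(pair[1]), "/", match_analytes(pair[2]))
    roc_results[[nm]] <- ratio_roc(seroma_panel, pair[1], pair[2], seed = seed)
  }

  summary_tabs <- summarize_groups(panel)

  cfg_hash <- config_hash(list(
    samples = panel$sample_id, groups = panel$group,
    measure = panel_measure(panel), contrasts = names(contrasts),
    roc = roc_analytes, seed = seed
  ))
  run <- structure(
    list(
      contrasts = contrast_results, loo = loo_reports,
      ratio_contrasts = ratio_results, clustering = dend, mds = mds,
      roc = roc_results, summary = summary_tabs,
      log = tibble(
        field = c("package_version", "r_version", "seed", "config_hash", "n_samples"),
        value = c(
          as.character(utils::packageVersion("cytosig")),
          paste(R.version$major, R.version$minor, sep = "."),
          as.character(seed), cfg_hash, as.character(nrow(panel))
        )
      )
    ),
    class = "cytosig_run"
  )
  if (!is.null(out_dir)) export_run(run, out_dir, cfg_hash)
  run
}

# Deterministic short hash of the run configuration (polynomial rolling
# hash over the serialized fields; avoids a digest dependency).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config: ", hash), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

export_run <- function(run, out_dir, hash) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  for (nm in names(run$contrasts)) {
    write_stamped_csv(
      tidy(run$contrasts[[nm]]),
      file.path(out_dir, paste0("contrast_", slug(nm), ".csv")), hash
    )
  }
  for (nm in names(run$loo)) {
    write_stamped_csv(
      as_tibble(run$loo[[nm]]),
      file.path(out_dir, paste0("loo_", slug(nm), ".csv")), hash
    )
  }
  for (nm in names(run$ratio_contrasts)) {
    write_stamped_csv(
      tidy(run$ratio_contrasts[[nm]]),
      file.path(out_dir, paste0("ratio_contrast_", slug(nm), ".csv")), hash
    )
  }
  roc_summary <- dplyr::bind_rows(lapply(run$roc, glance))
  if (nrow(roc_summary)) {
    write_stamped_csv(roc_summary, file.path(out_dir, "roc_summary.csv"), hash)
  }
  write_stamped_csv(tidy(run$mds), file.path(out_dir, "mds_coordinates.csv"), hash)
  write_stamped_csv(run$summary$summaries, file.path(out_dir, "group_summaries.csv"), hash)
  write_stamped_csv(run$summary$p_values, file.path(out_dir, "group_p_values.csv"), hash)
  write_stamped_csv(run$log, file.path(out_dir, "run_log.csv"), hash)
  write_newick(run$clustering, file.path(out_dir, "dendrogram.nwk"))
  invisible(out_dir)
}

#' @export
print.cytosig_run <- function(x, ...) {
  cat("<cytosig_run>\n")
  cat("  contrasts: ", length(x$contrasts), "; LOO reports: ", length(x$loo),
    "; ROC analyses: ", length(x$roc), "\n",
    sep = ""
  )
  cat(
    "  MDS explained (3 axes): ",
    sprintf("%.1f%%", 100 * utils::tail(x$mds$cumulative_explained, 1)), "\n",
    sep = ""
  )
  invisible(x)
}
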