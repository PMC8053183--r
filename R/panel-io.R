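#' Read a cytokine panel from delimited text
#'
#' The canonical interchange format is a wide CSV: one row per sample with
#' `sample_id`, `group`, then one column per analyte. An optional leading
#' comment line `# measure: <kind>` carries the measurement kind; otherwise
#' it must be supplied. Long format (`sample_id, analyte, replicate,
#' dilution, mfi` raw plate records) is accepted for raw MFI input and is
#' resolved to a per-sample matrix by [average_mfi()], which requires a
#' sample-to-group map.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the extension;
#'   `.tsv` means tab).
#' @param format `"wide_csv"` or `"long_csv"`.
#' @param measure Measurement kind; overrides any metadata header line.
#' @param sample_groups For `long_csv`: data frame with `sample_id` and
#'   `group`, or named character vector of groups keyed by sample id.
#' @param label_map Optional named character vector relabelling file group
#'   values onto [seroma_groups] (names = file labels, values = canonical).
#' @param match_names Resolve analyte column names through [match_analytes()].
#' @return A [cytokine_panel].
#' @export
read_panel <- function(path, format = c("wide_csv", "long_csv"), measure = NULL,
                       sample_groups = NULL, label_map = NULL,
                       match_names = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(paste0("empty file: ", path))
  if (grepl("^#\\s*measure:", first)) {
    file_measure <- trimws(sub("^#\\s*measure:", "", first))
    if (is.null(measure)) measure <- file_measure
  }
  if (format == "long_csv") {
    records <- read_plate_records(path)
    if (is.null(sample_groups)) {
      abort("`sample_groups` is required when reading long-format plate records")
    }
    return(average_mfi(records, sample_groups = sample_groups))
  }
  if (is.null(measure)) {
    abort("`measure` must be given (no metadata header line in file)")
  }
  df <- readr::read_delim(path,
    delim = delim, comment = "#", show_col_types = FALSE,
    trim_ws = TRUE, progress = FALSE
  )
  if (nrow(df) == 0L) abort(paste0("no data rows in ", path))
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort("wide panel file must have `sample_id` and `group` columns")
  }
  if (!is.null(label_map)) {
    hit <- df$group %in% names(label_map)
    df$group[hit] <- unname(label_map[df$group[hit]])
  }
  an <- setdiff(names(df), c("sample_id", "group"))
  non_num <- an[!vapply(df[an], is.numeric, logical(1))]
  if (length(non_num)) {
    abort(paste0(
      "non-numeric analyte column(s) in ", path, ": ",
      paste(non_num, collapse = ", ")
    ))
  }
  cytokine_panel(df, measure = measure, match_names = match_names)
}

#' Write a cytokine panel to a wide CSV
#'
#' Emits a `# measure:` metadata line followed by the wide table. Values are
#' serialised with 15 significant digits so that a write/read round trip
#' reproduces the panel to within 1e-9 relative tolerance (twice round-tripped
#' files are byte-identical).
#'
#' @param panel A [cytokine_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# measure: ", panel_measure(panel)), con)
  df <- as.data.frame(panel)
  an <- panel_analytes(panel)
  for (a in an) df[[a]] <- formatC(df[[a]], digits = 15, format = "g")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read raw plate records (long format)
#'
#' Raw bead-reader exports: one row per well with `sample_id`, `analyte`,
#' `replicate` (1 or 2), `dilution` (1 or 20) and `mfi`. Duplicate
#' (sample, analyte, replicate, dilution) keys are an error.
#'
#' @param path CSV/TSV path.
#' @param column_map Optional named character vector mapping the canonical
#'   column names (`sample_id`, `analyte`, `replicate`, `dilution`, `mfi`) to
#'   the names actually present in the file, for supplement-shaped exports.
#' @return Tibble of plate records with canonical analyte names.
#' @export
read_plate_records <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path,
    delim = delim, comment = "#", show_col_types = FALSE,
    trim_ws = TRUE, progress = FALSE
  )
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      names(df)[names(df) == column_map[[canon]]] <- canon
    }
  }
  need <- c("sample_id", "analyte", "replicate", "dilution", "mfi")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("plate record file missing column(s): ", paste(miss, collapse = ", ")))
  }
  df <- as_tibble(df[, need])
  df$sample_id <- as.character(df$sample_id)
  df$analyte <- match_analytes(as.character(df$analyte))
  validate_plate_records(df)
  df
}

validate_plate_records <- function(records) {
  key <- paste(records$sample_id, records$analyte, records$replicate,
    records$dilution,
    sep = "\r"
  )
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("sample_id", "analyte", "replicate", "dilution")]
    abort(paste0(
      "duplicate plate record key, e.g. sample ", dup$sample_id[1],
      " analyte ", dup$analyte[1], " replicate ", dup$replicate[1],
      " dilution ", dup$dilution[1]
    ))
  }
  if (anyNA(records$mfi) || any(!is.finite(records$mfi)) || any(records$mfi < 0)) {
    abort("plate record MFI values must be finite and non-negative")
  }
  invisible(records)
}

#' Write plate records to CSV
#'
#' @param records Plate-record tibble (see [read_plate_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_records <- function(records, path) {
  df <- as.data.frame(records)
  df$mfi <- formatC(df$mfi, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
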