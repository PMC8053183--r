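#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

#' Seroma group labels
#'
#' The five diagnostic groups a panel sample can belong to: BI-ALCL
#' (malignant effusions), the three benign reactive-seroma subtypes
#' (acute RS-A, mixed RS-M, chronic RS-C) and T-cell lymphoma cell-line
#' supernatants (T-LCL).
#'
#' @format Character vector of length 5.
#' @export
seroma_groups <- c("BI-ALCL", "RS-A", "RS-M", "RS-C", "T-LCL")

#' The 45-analyte cytokine/chemokine/growth-factor panel
#'
#' Canonical analyte names of the 45-plex bead immunoassay panel, in the
#' order they are conventionally listed. Greek letters are spelled out
#' (`IFN-gamma`, `TNF-beta`) so identifiers stay ASCII-safe; [match_analytes()]
#' resolves common synonyms (CCL11 for Eotaxin, CCL5 for RANTES, ...) and
#' Greek-letter spellings onto these names.
#'
#' @format Character vector of length 45.
#' @export
panel_45plex <- c(
  "BDNF", "EGF", "Eotaxin", "FGF-2", "GM-CSF", "GRO-alpha", "HGF",
  "IFN-alpha", "IFN-gamma", "IL-1RA", "IL-1alpha", "IL-1beta", "IL-2",
  "IL-4", "IL-5", "IL-6", "IL-7", "IL-8", "IL-9", "IL-10", "IL-12p70",
  "IL-13", "IL-15", "IL-17A", "IL-18", "IL-21", "IL-22", "IL-23", "IL-27",
  "IL-31", "IP-10", "LIF", "MCP-1", "MIP-1alpha", "MIP-1beta", "NGF-beta",
  "PDGF-BB", "PIGF-1", "RANTES", "SCF", "SDF-1alpha", "TNF-alpha",
  "TNF-beta", "VEGF-A", "VEGF-D"
)

panel_measures <- c(
  "MFI", "concentration_pg_per_mL", "log2_MFI", "log2_concentration",
  "ratio_to_reference"
)

# Explicit synonyms that normalisation alone cannot resolve.
analyte_alias_table <- c(
  ccl11    = "Eotaxin",
  ccl5     = "RANTES",
  ccl2     = "MCP-1",
  ccl3     = "MIP-1alpha",
  ccl4     = "MIP-1beta",
  cxcl10   = "IP-10",
  cxcl12   = "SDF-1alpha",
  cxcl8    = "IP-10", # never used; kept distinct below
  tnfb     = "TNF-beta",
  tnfa     = "TNF-alpha",
  lta      = "TNF-beta",
  fgfbasic = "FGF-2",
  groa     = "GRO-alpha",
  plgf1    = "PIGF-1"
)
analyte_alias_table <- analyte_alias_table[names(analyte_alias_table) != "cxcl8"]

normalize_analyte <- function(x) {
  x <- tolower(x)
  x <- gsub("α", "alpha", x)
  x <- gsub("β", "beta", x)
  x <- gsub("γ", "gamma", x)
  gsub("[^a-z0-9]", "", x)
}

#' Resolve analyte names onto the canonical panel vocabulary
#'
#' Matching is case-insensitive, ignores punctuation, expands Greek letters,
#' and consults a built-in synonym table (chemokine nomenclature such as
#' CCL11/CCL5, and common spellings such as `TNFb`).
#'
#' @param x Character vector of analyte names as found in a file header.
#' @param strict If `TRUE` (default) unknown names are an error; otherwise
#'   they are returned unchanged.
#' @return Character vector of canonical names (see [panel_45plex]).
#' @export
match_analytes <- function(x, strict = TRUE) {
  key <- normalize_analyte(x)
  canon <- stats::setNames(panel_45plex, normalize_analyte(panel_45plex))
  out <- canon[key]
  alias_hit <- is.na(out) & key %in% names(analyte_alias_table)
  out[alias_hit] <- analyte_alias_table[key[alias_hit]]
  unknown <- is.na(out)
  if (any(unknown)) {
    if (strict) {
      abort(paste0(
        "Unknown analyte name(s): ",
        paste(unique(x[unknown]), collapse = ", ")
      ))
    }
    out[unknown] <- x[unknown]
  }
  unname(out)
}

#' Construct a cytokine panel
#'
#' A cytokine panel is a tibble with one row per sample: a `sample_id`
#' column, a `group` column (levels in [seroma_groups]), and one numeric
#' column per analyte. The measurement kind travels with the object as the
#' `measure` attribute, one of `"MFI"`, `"concentration_pg_per_mL"`,
#' `"log2_MFI"`, `"log2_concentration"` or `"ratio_to_reference"`.
#'
#' @param data Data frame with `sample_id`, `group` and analyte columns.
#' @param measure Measurement kind of the analyte columns.
#' @param analytes Optional character vector selecting/ordering the analyte
#'   columns; defaults to every column other than `sample_id` and `group`.
#' @param match_names Resolve analyte column names through [match_analytes()].
#' @return A validated `cytokine_panel` tibble.
#' @export
cytokine_panel <- function(data, measure, analytes = NULL, match_names = FALSE) {
  measure <- match.arg(measure, panel_measures)
  data <- as_tibble(data)
  if (!all(c("sample_id", "group") %in% names(data))) {
    abort("`data` must have `sample_id` and `group` columns")
  }
  if (is.null(analytes)) {
    analytes <- setdiff(names(data), c("sample_id", "group"))
  }
  if (match_names) {
    canon <- match_analytes(analytes)
    names(data)[match(analytes, names(data))] <- canon
    analytes <- canon
  }
  data <- data[, c("sample_id", "group", analytes)]
  data$sample_id <- as.character(data$sample_id)
  data$group <- as.character(data$group)
  out <- structure(data,
    class = c("cytokine_panel", class(tibble())),
    measure = measure
  )
  validate_panel(out)
  out
}

#' @rdname cytokine_panel
#' @param panel A `cytokine_panel`.
#' @export
panel_measure <- function(panel) attr(panel, "measure", exact = TRUE)

#' @rdname cytokine_panel
#' @export
panel_analytes <- function(panel) setdiff(names(panel), c("sample_id", "group"))

#' @rdname cytokine_panel
#' @export
panel_values <- function(panel) {
  m <- as.matrix(panel[, panel_analytes(panel)])
  rownames(m) <- panel$sample_id
  m
}

# Rebuild a panel from a plain tibble, carrying the measure tag.
restore_panel <- function(data, measure) {
  cytokine_panel(data, measure = measure)
}

#' Validate a cytokine panel
#'
#' Checks the structural invariants: unique sample and analyte identifiers,
#' complete finite values, non-negativity for raw measurement kinds, and
#' group labels drawn from [seroma_groups].
#'
#' @param panel A `cytokine_panel`.
#' @param allow_groups Extra group labels to tolerate (e.g. after an explicit
#'   relabelling).
#' @return `panel`, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel, allow_groups = character()) {
  measure <- panel_measure(panel)
  if (is.null(measure) || !measure %in% panel_measures) {
    abort("panel `measure` attribute missing or invalid")
  }
  if (anyDuplicated(panel$sample_id)) {
    abort(paste0(
      "duplicate sample ids: ",
      paste(unique(panel$sample_id[duplicated(panel$sample_id)]), collapse = ", ")
    ))
  }
  an <- panel_analytes(panel)
  if (length(an) == 0L) abort("panel has no analyte columns")
  if (anyDuplicated(an)) abort("duplicate analyte columns")
  ok_groups <- c(seroma_groups, allow_groups)
  bad <- setdiff(unique(panel$group), ok_groups)
  if (length(bad)) {
    abort(paste0(
      "group labels outside the allowed set (", paste(ok_groups, collapse = ", "),
      "): ", paste(bad, collapse = ", ")
    ))
  }
  m <- panel_values(panel)
  if (!is.numeric(m)) abort("analyte columns must be numeric")
  if (anyNA(m) || any(!is.finite(m))) {
    bad_cells <- which(!is.finite(m), arr.ind = TRUE)
    abort(paste0(
      "non-finite or missing values, e.g. sample ", rownames(m)[bad_cells[1, 1]],
      ", analyte ", colnames(m)[bad_cells[1, 2]]
    ))
  }
  if (!measure %in% c("log2_MFI", "log2_concentration", "ratio_to_reference") &&
    any(m < 0)) {
    abort(paste0("negative values are not allowed for measure ", measure))
  }
  invisible(panel)
}

#' Per-group sample counts
#'
#' @param panel A `cytokine_panel`.
#' @return Tibble with `group` and `n`, ordered as [seroma_groups].
#' @export
group_counts <- function(panel) {
  tb <- table(factor(panel$group, levels = seroma_groups))
  tibble(group = names(tb), n = as.integer(tb))
}

#' @export
print.cytokine_panel <- function(x, ...) {
  cat(
    "<cytokine_panel> ", nrow(x), " samples x ", length(panel_analytes(x)),
    " analytes [", panel_measure(x), "]\n",
    sep = ""
  )
  NextMethod()
}

# Resolve contrast labels: "RS" expands to the three benign subtypes.
resolve_group_labels <- function(labels) {
  out <- unlist(lapply(labels, function(l) {
    if (identical(l, "RS")) c("RS-A", "RS-M", "RS-C") else l
  }))
  bad <- setdiff(out, seroma_groups)
  if (length(bad)) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  unique(out)
}
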