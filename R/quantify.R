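#' Five-parameter logistic response curve
#'
#' `MFI(x) = d + (a - d) / (1 + (x / c)^b)^g` with lower asymptote `a`
#' (the blank-well MFI, reached as concentration x tends to 0 for b > 0),
#' upper asymptote `d`, inflection concentration `c`, slope `b` and
#' asymmetry `g` (`g = 1` reduces to the 4PL). Monotone increasing for
#' `a < d`, `b > 0`, `g > 0`.
#'
#' @param x Concentration(s), pg/mL.
#' @param a,d,c,b,g Curve parameters.
#' @return MFI value(s).
#' @export
fivepl <- function(x, a, d, c, b, g) {
  d + (a - d) / (1 + (x / c)^b)^g
}

check_curve <- function(curve) {
  with(curve, {
    if (!(c > 0) || !(b * g > 0) || a == d) {
      abort("invalid standard curve: need c > 0, b and g same-signed, a != d")
    }
  })
  invisible(curve)
}

#' Average raw plate records into an MFI panel
#'
#' Implements the averaged-MFI convention of the analysis: duplicates are
#' averaged first within each dilution, then the per-dilution means are
#' averaged, giving one MFI per sample x analyte. Missing sample x analyte
#' cells are an error (downstream statistics need complete matrices).
#'
#' @param records Plate-record tibble (see [read_plate_records()]).
#' @param sample_groups Data frame with `sample_id`, `group`, or a named
#'   character vector of group labels keyed by sample id.
#' @param dilutions Dilutions to use; default all present. Passing `1` gives
#'   the undiluted-only track used for concentration estimation.
#' @return A [cytokine_panel] with measure `"MFI"`.
#' @export
average_mfi <- function(records, sample_groups, dilutions = NULL) {
  validate_plate_records(records)
  if (!is.null(dilutions)) {
    records <- records[records$dilution %in% dilutions, ]
    if (nrow(records) == 0L) abort("no records at the requested dilution(s)")
  }
  if (!is.data.frame(sample_groups)) {
    sample_groups <- tibble(
      sample_id = names(sample_groups),
      group = unname(sample_groups)
    )
  }
  per_dil <- records |>
    dplyr::group_by(.data$sample_id, .data$analyte, .data$dilution) |>
    dplyr::summarise(mfi = mean(.data$mfi), .groups = "drop")
  cells <- per_dil |>
    dplyr::group_by(.data$sample_id, .data$analyte) |>
    dplyr::summarise(mfi = mean(.data$mfi), .groups = "drop")
  analytes <- intersect(panel_45plex, unique(cells$analyte))
  if (length(analytes) == 0L) analytes <- sort(unique(cells$analyte))
  samples <- unique(records$sample_id)
  full <- expand.grid(sample_id = samples, analyte = analytes, stringsAsFactors = FALSE)
  merged <- dplyr::left_join(as_tibble(full), cells, by = c("sample_id", "analyte"))
  if (anyNA(merged$mfi)) {
    bad <- merged[is.na(merged$mfi), ]
    abort(paste0(
      "missing plate records for ", nrow(bad), " sample x analyte cell(s), e.g. ",
      bad$sample_id[1], " x ", bad$analyte[1]
    ))
  }
  wide <- tidyr::pivot_wider(merged, names_from = "analyte", values_from = "mfi")
  wide <- dplyr::left_join(wide, as_tibble(sample_groups), by = "sample_id")
  if (anyNA(wide$group)) {
    abort(paste0(
      "no group label for sample(s): ",
      paste(wide$sample_id[is.na(wide$group)], collapse = ", ")
    ))
  }
  cytokine_panel(wide[, c("sample_id", "group", analytes)], measure = "MFI")
}

#' Fit a five-parameter logistic standard curve
#'
#' Weighted least squares (weights `1/MFI^2`, the usual relative-error model
#' for bead assays) via Levenberg-Marquardt with multiple starts over slope
#' and asymmetry. Requires at least 6 standards spanning at least 3 orders
#' of magnitude in concentration.
#'
#' @param known_conc Standard concentrations (> 0), pg/mL.
#' @param observed_mfi Observed MFI at each standard.
#' @param analyte Analyte name attached to the fit.
#' @param fix_g Optionally fix the asymmetry (e.g. `1` for a 4PL fit).
#' @return One-row tibble: `analyte`, parameters `a, d, c, b, g`, the
#'   weighted residual sum of squares `wrss`, and the standard concentration
#'   range (`conc_lo`, `conc_hi`) used for out-of-range flagging.
#' @export
fit_standard_curve <- function(known_conc, observed_mfi, analyte = "analyte",
                               fix_g = NULL) {
  if (length(known_conc) != length(observed_mfi)) abort("length mismatch")
  if (length(known_conc) < 6L) abort("need at least 6 standard points")
  if (any(known_conc <= 0)) abort("standard concentrations must be positive")
  if (max(known_conc) / min(known_conc) < 1e3) {
    abort("standards must span at least 3 orders of magnitude")
  }
  if (stats::sd(observed_mfi) == 0) {
    abort("constant MFI across standards: curve fit degenerate")
  }
  df <- data.frame(x = known_conc, y = observed_mfi)
  w <- 1 / pmax(observed_mfi, 1e-8)^2
  a0 <- min(observed_mfi)
  d0 <- max(observed_mfi)
  span <- d0 - a0
  starts <- expand.grid(
    b = c(0.5, 1, 2), g = if (is.null(fix_g)) c(0.5, 1, 2) else fix_g,
    c = exp(stats::quantile(log(known_conc), c(0.35, 0.5, 0.65)))
  )
  best <- NULL
  best_wrss <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- list(
      a = a0 - 0.02 * span, d = d0 + 0.05 * span,
      c = starts$c[i], b = starts$b[i]
    )
    if (is.null(fix_g)) st$g <- starts$g[i]
    fml <- if (is.null(fix_g)) {
      y ~ d + (a - d) / (1 + (x / c)^b)^g
    } else {
      substitute(y ~ d + (a - d) / (1 + (x / c)^b)^G, list(G = fix_g))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml,
        data = df, start = st, weights = w,
        lower = c(a = -Inf, d = -Inf, c = 1e-12, b = 1e-6, g = 1e-6)[names(st)],
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    wrss <- sum(w * stats::residuals(fit)^2)
    if (wrss < best_wrss) {
      best <- fit
      best_wrss <- wrss
    }
  }
  if (is.null(best)) {
    abort("standard-curve fit did not converge from any start")
  }
  p <- as.list(stats::coef(best))
  if (!is.null(fix_g)) p$g <- fix_g
  curve <- tibble(
    analyte = analyte, a = p$a, d = p$d, c = p$c, b = p$b, g = p$g,
    wrss = best_wrss, conc_lo = min(known_conc), conc_hi = max(known_conc)
  )
  check_curve(curve)
  curve
}

#' Invert a standard curve: MFI to concentration
#'
#' Closed-form inverse of the 5PL,
#' `x = c * (((a - d)/(mfi - d))^(1/g) - 1)^(1/b)`, multiplied by the
#' dilution factor. MFI at or below the lower asymptote is flagged
#' `"below_range"` with value 0; at or above the upper asymptote it is
#' flagged `"above_range"` with value `Inf`. No exceptions are thrown for
#' out-of-range readings.
#'
#' @param curve One-row curve tibble (see [fit_standard_curve()]).
#' @param mfi MFI value(s).
#' @param dilution_factor Dilution factor the sample was read at.
#' @return Tibble with `conc` and `flag` (`"ok"`, `"below_range"`,
#'   `"above_range"`).
#' @export
invert_curve <- function(curve, mfi, dilution_factor = 1) {
  check_curve(curve)
  a <- curve$a
  d <- curve$d
  lo <- min(a, d)
  hi <- max(a, d)
  conc <- rep(NA_real_, length(mfi))
  flag <- rep("ok", length(mfi))
  below <- mfi <= lo
  above <- mfi >= hi
  conc[below] <- 0
  flag[below] <- "below_range"
  conc[above] <- Inf
  flag[above] <- "above_range"
  inside <- !below & !above
  if (any(inside)) {
    m <- mfi[inside]
    conc[inside] <- curve$c * (((a - d) / (m - d))^(1 / curve$g) - 1)^(1 / curve$b) *
      dilution_factor
  }
  tibble(conc = conc, flag = flag)
}

#' Quantify concentrations from raw plate records
#'
#' The concentration track: duplicate wells at the chosen dilution are
#' averaged per sample x analyte, the analyte's standard curve is inverted,
#' and the result scaled by the dilution factor. Below-range readings are
#' substituted with half the lowest standard concentration (rank-preserving,
#' log-safe) and flagged.
#'
#' @param records Plate-record tibble.
#' @param curves Curve tibble, one row per analyte.
#' @param sample_groups Sample-to-group map (see [average_mfi()]).
#' @param dilution Dilution track to quantify on (default 1, undiluted).
#' @return A [cytokine_panel] with measure `concentration_pg_per_mL`; the
#'   attribute `flags` holds a tibble of flagged cells.
#' @export
quantify_concentrations <- function(records, curves, sample_groups, dilution = 1) {
  mfi_panel <- average_mfi(records, sample_groups, dilutions = dilution)
  analytes <- panel_analytes(mfi_panel)
  miss <- setdiff(analytes, curves$analyte)
  if (length(miss)) abort(paste0("no standard curve for: ", paste(miss, collapse = ", ")))
  out <- mfi_panel
  flags <- list()
  for (an in analytes) {
    curve <- curves[curves$analyte == an, ]
    inv <- invert_curve(curve, mfi_panel[[an]], dilution_factor = dilution)
    lo_sub <- if ("conc_lo" %in% names(curve)) curve$conc_lo / 2 else 0
    below <- inv$flag == "below_range"
    above <- inv$flag == "above_range"
    inv$conc[below] <- lo_sub * dilution
    inv$conc[above] <- if ("conc_hi" %in% names(curve)) curve$conc_hi * dilution else Inf
    if (any(below | above)) {
      flags[[an]] <- tibble(
        sample_id = mfi_panel$sample_id[below | above], analyte = an,
        flag = inv$flag[below | above]
      )
    }
    out[[an]] <- inv$conc
  }
  out <- cytokine_panel(out, measure = "concentration_pg_per_mL")
  attr(out, "flags") <- dplyr::bind_rows(flags)
  out
}

#' Log2-transform a panel
#'
#' Elementwise `log2(value + offset)`. The default offset is 1 for MFI
#' panels (background-subtracted MFI can sit at zero) and 0 for
#' concentration panels (below-range substitution keeps values positive).
#'
#' @param panel A [cytokine_panel] with a raw measure.
#' @param offset Non-negative shift added before taking logs.
#' @return A [cytokine_panel] with the corresponding log2 measure.
#' @export
log2_panel <- function(panel, offset = NULL) {
  measure <- panel_measure(panel)
  new_measure <- switch(measure,
    MFI = "log2_MFI",
    concentration_pg_per_mL = "log2_concentration",
    ratio_to_reference = "ratio_to_reference",
    abort(paste0("panel is already on a log scale (measure ", measure, ")"))
  )
  if (is.null(offset)) offset <- if (measure == "MFI") 1 else 0
  if (offset < 0) abort("offset must be non-negative")
  out <- panel
  for (an in panel_analytes(panel)) {
    v <- panel[[an]] + offset
    if (any(v <= 0)) {
      abort(paste0("non-positive value + offset in analyte ", an))
    }
    out[[an]] <- log2(v)
  }
  if (measure == "ratio_to_reference") {
    attr(out, "log2") <- TRUE
    return(out)
  }
  cytokine_panel(out, measure = new_measure)
}

#' Default synthetic standard curves
#'
#' Plausible bead-assay curves for simulation and round-trip testing:
#' shared lower/upper asymptotes, per-analyte inflection at the analyte's
#' typical concentration. Labelled synthetic; not fitted to any instrument.
#'
#' @param analytes Analyte names.
#' @param c_mid Inflection concentration(s); recycled.
#' @return Curve tibble compatible with [invert_curve()].
#' @export
default_standard_curves <- function(analytes = panel_45plex, c_mid = 500) {
  tibble(
    analyte = analytes, a = 30, d = 30000,
    c = rep_len(c_mid, length(analytes)), b = 1.2, g = 1,
    wrss = 0, conc_lo = 0.05, conc_hi = 50000
  )
}

#' Serialize fitted curves to JSON text
#'
#' @param curves Curve tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  jsonlite::write_json(curves, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
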