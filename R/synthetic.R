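#' Calibrate log-normal group distributions from printed summaries
#'
#' For each (analyte, group) row with mean m, standard deviation s and a
#' truncation range, the implied log-normal has `sigma2 = log(1 + s^2/m^2)`
#' and `mu = log(m) - sigma2/2`, so that the *untruncated* distribution has
#' expectation exactly m and variance exactly s^2 (moment matching on the
#' original scale). The printed range becomes a truncation interval applied
#' by rejection sampling at generation time.
#'
#' @param summary_table Data frame with columns `analyte`, `group`, `mean`,
#'   `sd`, `lower`, `upper`.
#' @return Tibble of group distribution specs with `mu`, `sigma` appended.
#' @export
calibrate_from_summary <- function(summary_table) {
  st <- as_tibble(summary_table)
  need <- c("analyte", "group", "mean", "sd", "lower", "upper")
  miss <- setdiff(need, names(st))
  if (length(miss)) abort(paste0("summary table missing column(s): ", paste(miss, collapse = ", ")))
  if (any(st$mean <= 0)) {
    abort(paste0(
      "non-positive mean for ",
      paste(st$analyte[st$mean <= 0], st$group[st$mean <= 0], collapse = "; "),
      ": log-normal calibration undefined"
    ))
  }
  if (any(st$sd < 0)) abort("negative sd")
  if (any(st$lower > st$upper)) abort("lower bound exceeds upper bound")
  if (any(st$mean < st$lower | st$mean > st$upper)) {
    abort("mean outside the truncation range")
  }
  sigma2 <- log(1 + (st$sd / st$mean)^2)
  st$sigma <- sqrt(sigma2)
  st$mu <- log(st$mean) - sigma2 / 2
  if (any(!is.finite(st$mu)) || any(!is.finite(st$sigma))) {
    abort("calibration produced non-finite log-normal parameters")
  }
  st
}

#' Published group summaries for the four Table-1 analytes
#'
#' Mean, SD and range (pg/mL) of IL-10, IL-6, IL-13 and Eotaxin per group
#' (plus the IL-10/IL-6 per-sample ratio), as printed in the study's summary
#' table. Used to calibrate the simulator and as targets for summary tests.
#'
#' @param include_ratio Keep the `IL-10/IL-6` ratio rows (default `FALSE`:
#'   the ratio is a derived quantity, not a simulated analyte).
#' @return Tibble with `analyte`, `group`, `mean`, `sd`, `lower`, `upper`.
#' @export
table1_summaries <- function(include_ratio = FALSE) {
  path <- system.file("extdata", "table1_summaries.csv", package = "cytosig")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!include_ratio) df <- df[df$analyte != "IL-10/IL-6", ]
  df
}

# Neutral, group-independent defaults for the 41 analytes the summary table
# does not constrain. These are invented fixtures: per-analyte geometric
# means log-spaced over [1, 20000] pg/mL, CV 0.6, truncation at the
# 0.001/0.999 log-normal quantiles (i.e. essentially untruncated).
default_group_specs <- function(analytes = setdiff(panel_45plex, unique(table1_summaries()$analyte)),
                                groups = seroma_groups, cv = 0.6) {
  k <- length(analytes)
  means <- exp(seq(log(1), log(20000), length.out = k))
  sigma2 <- log(1 + cv^2)
  mu <- log(means) - sigma2 / 2
  qs <- stats::qlnorm(c(0.001, 0.999))
  grid <- expand.grid(analyte = analytes, group = groups, stringsAsFactors = FALSE)
  i <- match(grid$analyte, analytes)
  tibble(
    analyte = grid$analyte, group = grid$group,
    mean = means[i], sd = cv * means[i],
    lower = exp(mu[i] + sqrt(sigma2) * stats::qnorm(0.001)),
    upper = exp(mu[i] + sqrt(sigma2) * stats::qnorm(0.999))
  )
}

#' Full 45-analyte simulation specs calibrated to the published summaries
#'
#' Combines the Table-1-calibrated specs for IL-10, IL-6, IL-13 and Eotaxin
#' (per-subtype rows; the pooled `RS-All` rows are kept for null-mode
#' pooling) with neutral invented defaults for the remaining 41 analytes.
#'
#' @return Calibrated spec tibble covering every analyte in [panel_45plex]
#'   for every group in [seroma_groups] plus pooled `RS-All` rows.
#' @export
study_specs <- function() {
  t1 <- table1_summaries()
  defaults <- default_group_specs()
  pooled_defaults <- defaults[defaults$group == "RS-A", ]
  pooled_defaults$group <- "RS-All"
  calibrate_from_summary(rbind(t1, defaults, pooled_defaults))
}

#' Build a simulation configuration
#'
#' @param specs Calibrated spec tibble (see [calibrate_from_summary()];
#'   default [study_specs()]). Must cover every analyte x group cell for the
#'   groups being generated.
#' @param n Named integer vector of group sizes. The default reproduces the
#'   study design: 12 BI-ALCL, 6 RS-A, 6 RS-M, 8 RS-C, 7 T-LCL.
#' @param seed Integer seed; identical configs generate identical panels.
#' @param spike Optional data frame with `analyte`, `group`, `fold`:
#'   multiplies that cell's mean, sd and bounds by `fold` (for power studies).
#' @param null_mode If `TRUE`, every group draws from the BI-ALCL-free pooled
#'   spec of each analyte (the `RS-All` row when present), so all group
#'   differences are null.
#' @param truncate Draw from the truncated distribution (rejection sampling).
#'   `FALSE` gives untruncated draws, used to check moment calibration.
#' @param copula_rho Equicorrelation of an optional Gaussian copula coupling
#'   analytes within a sample (0 = independent, the default).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(specs = study_specs(),
                              n = c("BI-ALCL" = 12, "RS-A" = 6, "RS-M" = 6,
                                    "RS-C" = 8, "T-LCL" = 7),
                              seed = 1L, spike = NULL, null_mode = FALSE,
                              truncate = TRUE, copula_rho = 0) {
  if (null_mode) {
    # every group draws from the analyte's BI-ALCL-free pooled spec; a spike
    # is applied afterwards, so power studies ride on a null background
    for (an in unique(specs$analyte)) {
      rows <- specs$analyte == an
      pooled <- specs[rows & specs$group == "RS-All", ]
      if (nrow(pooled) == 0L) pooled <- specs[rows & specs$group != "BI-ALCL", ][1, ]
      for (col in c("mean", "sd", "lower", "upper", "sigma", "mu")) {
        if (col %in% names(specs)) specs[rows, col] <- pooled[[col]]
      }
    }
  }
  if (!is.null(spike)) {
    spike <- as_tibble(spike)
    for (r in seq_len(nrow(spike))) {
      hit <- specs$analyte == spike$analyte[r] & specs$group == spike$group[r]
      if (!any(hit)) abort("spike names an absent analyte x group cell")
      fold <- spike$fold[r]
      specs$mean[hit] <- specs$mean[hit] * fold
      specs$sd[hit] <- specs$sd[hit] * fold
      specs$lower[hit] <- specs$lower[hit] * fold
      specs$upper[hit] <- specs$upper[hit] * fold
    }
    specs <- calibrate_from_summary(specs[, c("analyte", "group", "mean", "sd", "lower", "upper")])
  }
  groups <- names(n)
  cover <- table(specs$analyte[specs$group %in% groups], specs$group[specs$group %in% groups])
  if (any(cover != 1L)) {
    abort("specs must cover every analyte x group cell exactly once")
  }
  structure(
    list(
      specs = specs, n = n, seed = as.integer(seed), null_mode = null_mode,
      truncate = truncate, copula_rho = copula_rho
    ),
    class = "simulation_config"
  )
}

# Truncated log-normal draws by rejection sampling. Errors out rather than
# hanging when the truncation interval carries negligible mass.
rtrunc_lnorm <- function(n, mu, sigma, lower, upper) {
  if (sigma == 0) {
    x <- rep(exp(mu), n)
    if (any(x < lower | x > upper)) abort("point mass outside truncation bounds")
    return(x)
  }
  p_mass <- stats::plnorm(upper, mu, sigma) - stats::plnorm(lower, mu, sigma)
  if (p_mass < 1e-4) {
    abort(sprintf(
      "truncation interval [%g, %g] has negligible log-normal mass (%.2g)",
      lower, upper, p_mass
    ))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(max(n, ceiling((n - length(out)) / p_mass)), mu, sigma)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# Inverse CDF of the truncated log-normal (used by the copula path only).
qtrunc_lnorm <- function(p, mu, sigma, lower, upper) {
  if (sigma == 0) return(rep(exp(mu), length(p)))
  pl <- stats::plnorm(lower, mu, sigma)
  pu <- stats::plnorm(upper, mu, sigma)
  stats::qlnorm(pl + p * (pu - pl), mu, sigma)
}

#' Generate a synthetic cytokine panel
#'
#' Concentrations are drawn independently per sample x analyte from the
#' truncated log-normal of the sample's group (rejection sampling, never
#' clipping). A fixed seed gives an identical panel. In `null_mode` all
#' groups share each analyte's pooled benign spec, so any detected group
#' difference is a false positive.
#'
#' @param config A [simulation_config()].
#' @return A [cytokine_panel] with measure `concentration_pg_per_mL`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  specs <- config$specs
  n <- config$n
  groups <- names(n)
  analytes <- intersect(panel_45plex, unique(specs$analyte))
  if (length(analytes) == 0L) analytes <- sort(unique(specs$analyte))

  spec_for <- function(analyte, group) {
    row <- specs[specs$analyte == analyte & specs$group == group, ]
    if (nrow(row) != 1L) abort(paste0("no unique spec for ", analyte, " x ", group))
    row
  }

  sample_ids <- unlist(lapply(groups, function(g) {
    if (g == "T-LCL" && n[[g]] == 7L) {
      c("TLBR-1", "TLBR-2", "TLBR-3", "TLBR-4", "Mac-1", "Mac-2A", "Karpas-299")
    } else {
      sprintf("%s-%02d", g, seq_len(n[[g]]))
    }
  }))
  grp <- rep(groups, times = as.integer(n))

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    expr
  }

  values <- withr_seed({
    m <- matrix(NA_real_, nrow = length(sample_ids), ncol = length(analytes),
      dimnames = list(sample_ids, analytes))
    if (config$copula_rho > 0) {
      rho <- config$copula_rho
      for (i in seq_along(sample_ids)) {
        z0 <- stats::rnorm(1)
        z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(length(analytes))
        u <- stats::pnorm(z)
        for (j in seq_along(analytes)) {
          s <- spec_for(analytes[j], grp[i])
          lo <- if (config$truncate) s$lower else 0
          hi <- if (config$truncate) s$upper else Inf
          m[i, j] <- qtrunc_lnorm(u[j], s$mu, s$sigma, lo, hi)
        }
      }
    } else {
      for (j in seq_along(analytes)) {
        for (g in groups) {
          s <- spec_for(analytes[j], g)
          rows <- which(grp == g)
          if (config$truncate) {
            m[rows, j] <- rtrunc_lnorm(length(rows), s$mu, s$sigma, s$lower, s$upper)
          } else {
            m[rows, j] <- stats::rlnorm(length(rows), s$mu, s$sigma)
          }
        }
      }
    }
    m
  })

  df <- tibble(sample_id = sample_ids, group = grp)
  for (j in seq_along(analytes)) df[[analytes[j]]] <- values[, j]
  cytokine_panel(df, measure = "concentration_pg_per_mL")
}

#' Simulate raw plate records from a concentration panel
#'
#' The inverse of the quantification stage: passes each concentration through
#' the analyte's standard curve at dilutions 1 and 1:20, in duplicate, and
#' multiplies by mean-one log-normal measurement noise with the given
#' coefficient of variation. With `noise_cv = 0` the MFI equals the curve
#' value exactly, so quantification round trips are exact.
#'
#' @param panel Concentration [cytokine_panel].
#' @param curves Standard curves (see [default_standard_curves()]).
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param seed Integer seed for the noise draws.
#' @param dilutions Dilution factors to emit (default 1 and 20).
#' @param replicates Number of duplicate wells per dilution (default 2).
#' @return Plate-record tibble (see [read_plate_records()]).
#' @export
forward_mfi <- function(panel, curves, noise_cv = 0.05, seed = 1L,
                        dilutions = c(1, 20), replicates = 2L) {
  stopifnot(panel_measure(panel) == "concentration_pg_per_mL")
  analytes <- panel_analytes(panel)
  miss <- setdiff(analytes, curves$analyte)
  if (length(miss)) abort(paste0("no standard curve for: ", paste(miss, collapse = ", ")))
  grid <- expand.grid(
    replicate = seq_len(replicates), dilution = dilutions,
    analyte = analytes, sample_id = panel$sample_id,
    stringsAsFactors = FALSE
  )[, c("sample_id", "analyte", "replicate", "dilution")]
  vals <- panel_values(panel)
  conc <- vals[cbind(grid$sample_id, grid$analyte)]
  ci <- match(grid$analyte, curves$analyte)
  mfi <- fivepl(
    conc / grid$dilution,
    a = curves$a[ci], d = curves$d[ci], c = curves$c[ci],
    b = curves$b[ci], g = curves$g[ci]
  )
  if (noise_cv > 0) {
    sigma2 <- log(1 + noise_cv^2)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    noise <- stats::rlnorm(length(mfi), meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    mfi <- mfi * noise
  }
  out <- as_tibble(grid)
  out$mfi <- mfi
  out
}
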