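---
title: "Cytokine signatures of peri-implant seromas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytokine signatures of peri-implant seromas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosig)
```

# The problem

A late effusion around a breast implant is usually benign — an acute
(neutrophil-rich), mixed, or chronic (lymphocyte/monocyte-rich) reactive
seroma — but can be the presenting sign of breast implant-associated
anaplastic large-cell lymphoma (BI-ALCL). Because the malignant effusions
carry a distinctive soluble milieu (very high IL-10 and IL-13, high
Eotaxin, and a raised IL-10/IL-6 ratio), a multiplex bead immunoassay on
the aspirated fluid can support screening before cytology results are
available. `cytosig` packages the complete statistical path from raw
bead readouts to biomarker cutoffs.

The data model is a `cytokine_panel`: a tibble of samples by analytes
(the standard 45-plex panel, `panel_45plex`), tagged with a measurement
kind — raw MFI, concentrations in pg/mL, their log2 transforms, or
per-sample ratios to a reference cytokine. Group labels come from the
five-arm design: 12 BI-ALCL, 6 acute, 6 mixed and 8 chronic reactive
seromas, and 7 T-cell lymphoma cell lines (the four BI-ALCL-derived TLBR
lines plus Mac-1, Mac-2A and Karpas-299).

# Quantification

Bead assays read each well as a median fluorescent intensity. Samples are
run in duplicate, undiluted and at 1:20. Two tracks are exposed, because
the analysis uses both:

* **Averaged-MFI track** (`average_mfi()`): duplicates are averaged within
  each dilution, then the two dilution means are averaged. This is the
  input to the differential and unsupervised stages.
* **Concentration track** (`quantify_concentrations()`): undiluted
  duplicate means are pushed through the analyte's standard curve to
  pg/mL. This is the input to summary tables and ROC analyses.

The standard curve is the five-parameter logistic
`MFI(x) = d + (a - d) / (1 + (x/c)^b)^g`, fitted by Levenberg–Marquardt
least squares with `1/MFI^2` weights (the usual constant-CV error model
for bead readouts) from a 3×3 multi-start grid over slope, asymmetry and
inflection; `g = 1` recovers the 4PL as a nested special case. Inversion
is closed-form; readings at or beyond the asymptotes are *flagged*
(`below_range`/`above_range`) rather than thrown, and below-range values
are substituted with half the lowest standard concentration — a
rank-preserving, log-safe convention. Because every stage downstream of
quantification that feeds a ROC analysis is invariant under strictly
increasing transforms (rank-based distances, AUC), the exact weighting
and asymmetry settings of the curve fit cannot change the headline
AUC-type results; they only matter for absolute pg/mL reporting.

The log2 transform defaults to an offset of 1 for MFI (background
subtraction can leave values at zero) and 0 for concentrations (positivity
is guaranteed by the below-range substitution).

# The moderated t-test

With 6–20 samples per arm and 45 analytes, per-analyte variance estimates
are noisy; the differential analysis therefore uses the empirical-Bayes
moderated t. For analyte $g$, with pooled two-group variance $s_g^2$ on
$d_g = n_A + n_B - 2$ df, the prior $(d_0, s_0^2)$ is estimated once per
contrast by matching the first two moments of $\log s_g^2$ to the
scaled-F theory (digamma/trigamma equations; the trigamma equation is
solved by Newton iteration, and a non-positive excess-variance estimate
yields $d_0 = \infty$). The shrunken variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ gives
$\tilde t_g$ on $d_0 + d_g$ df (standard normal at $d_0 = \infty$).
The implementation is self-contained; the test suite verifies it to
\(10^{-8}\) against the reference empirical-Bayes implementation in
`limma`, and to \(10^{-9}\) against the textbook pooled t in the
$d_0 \to 0$ limit.

Design choices worth stating:

* **Per-contrast subset fitting.** Each pairwise comparison is fitted on
  its own sample subset, with hyperparameters re-estimated, rather than
  as one 5-group linear model with contrasts. This matches the
  per-comparison leave-one-out phrasing of the original analysis; whether
  residual variance was pooled across all five groups there is not
  documented, so the subset reading was adopted as the simpler and more
  conservative one.
* **Two-sided p-values**, since both up- and down-regulated cytokines are
  reported.
* **BH within contrast** across the 45 analytes (m = 45); tiers use
  strict inequalities on the adjusted p (`strict` < 0.01, `loose` < 0.05),
  and the volcano fold line sits at ±2 log2 units (fourfold).
* **Zero-variance analytes** keep $s_g^2 = 0$ and rely wholly on
  shrinkage (they are excluded from prior estimation); a panel in which
  every analyte has zero variance is an error.
* Group summary tables (`summarize_groups()`) quote means ± SD and ranges
  on the concentration scale, with moderated-t p-values computed on the
  log2 scale by default; `log2_p = FALSE` tests the raw values, since
  published summary-table p-values do not always document the scale.

# Leave-one-out robustness

`loo_robustness()` reruns the moderated t once per sample in the
contrast, each round a complete reanalysis of the reduced data set
(including hyperparameter re-estimation), and counts per analyte the
rounds with `p < 0.01`. Only analytes significant in *every* round are
flagged robust. The counting threshold defaults to the BH-adjusted p for
consistency with the main analysis; a raw-p switch exists because the
convention is not documented in the source workflow. Plots conventionally
show only analytes reaching `p < 0.001` in at least one round — a display
filter the report tracks separately (`display_count`) so it is never
conflated with the counting rule. Note that a significant full-data
analyte can be fragile (count < rounds) and, conversely, robustness is
not implied by full-data significance; the report allows both readings.

# Ratio analysis

`ratio_transform()` divides every analyte, per sample, by that sample's
IL-6 value and drops the reference column. On log2 scale this is exactly
a columnwise subtraction, so ratio log fold changes have a closed
interpretation, and the identity is tested to \(10^{-12}\). IL-6 is the
reference because it is a pro-inflammatory cytokine detectable in
essentially all seromas, and ratio markers transfer between assays that
are not calibrated to a common standard. `group_ratio_summary()`
aggregates *per-sample* ratios (never ratios of group means — only the
former reproduces per-sample ranges).

# Unsupervised structure

Sample structure uses the Spearman correlation distance
$d(i,j) = 1 - \rho_s$ across the 45-analyte profiles (range $[0, 2]$;
alternatives such as $(1-\rho_s)/2$ exist in the literature, but
$1-\rho_s$ is the most common reading and is what the package fixes).
Clustering is Ward.D2 — Lance–Williams updates on squared
dissimilarities, heights the square roots of the merge criterion — via
`stats::hclust`, verified in the tests against an exhaustive
minimum-criterion agglomeration oracle up to n = 7. Classical MDS
(`stats::cmdscale` under the hood) reports per-axis explained variance as
the eigenvalue over the sum of *positive* eigenvalues, the standard
principal-coordinates convention. The published three-axis figure of
70.4% depends on the (undocumented) dissimilarity and denominator
conventions of the original figure, so its reproduction is attempted only
on the original measured panel, not promised in simulation.

# ROC and the Youden cutoff

`roc_curve()` uses the finite candidate thresholds that matter: midpoints
between consecutive distinct pooled values, plus $\pm\infty$; a sample is
positive when its value exceeds the threshold. Sensitivity and
specificity are exact count fractions, the trapezoid AUC equals the
Mann–Whitney pair-counting estimate (ties counted half), and the
Youden-optimal cutoff maximizes $\mathrm{Se} + \mathrm{Sp} - 1$, ties
broken towards the smallest cutoff. Midpoint thresholding is what makes
published cutoffs arithmetically reproducible: with a malignant minimum
of 58.36 pg/mL against a benign maximum of 19.69 pg/mL the optimal
IL-10 cutoff is (19.69 + 58.36)/2 = 39.025, printed as 39.03 after
rounding half-away-from-zero at 2 decimals (ratio cutoffs are reported at
3 significant figures). The 95% CI uses the DeLong placement variance
with a normal interval clipped to $[0,1]$; perfect separation has zero
placement variance and degenerates, flagged, to $[\mathrm{AUC},
\mathrm{AUC}]$ — which is how a printed CI of 1.00–1.00 arises. A
2,000-replicate stratified bootstrap is available as an alternative.
A published Youden index of 0.94 alongside Se 1.00/Sp 0.85 for Eotaxin is
arithmetically inconsistent (0.94 equals that marker's AUC); the package
always reports $\mathrm{Se} + \mathrm{Sp} - 1$, i.e. 0.85 in that
configuration.

# The synthetic-panel generator

Because the study's measured panel exists only as an article supplement,
the package ships a simulator whose defaults *are* the published study
conditions. Each (analyte, group) cell is a log-normal calibrated by
moment matching — $\sigma^2 = \ln(1 + s^2/m^2)$, $\mu = \ln m -
\sigma^2/2$ — to the published group mean $m$ and SD $s$, truncated to
the published range by rejection sampling (clipping would create atoms at
the bounds and distort rank-based distances). The published summary table
constrains four analytes (IL-10, IL-6, IL-13, Eotaxin) across six row
groups; these cells are encoded verbatim in
`inst/extdata/table1_summaries.csv`. The remaining 41 analytes are
**invented neutral fixtures**: group-independent log-normals with
geometric means log-spaced over 1–20,000 pg/mL, CV 0.6, truncated at
their 0.001/0.999 quantiles — values chosen once as typical of seroma
cytokine panels and deliberately carrying no group signal. Analytes are
simulated independently by default (no covariance information is
published; independence is the honest default), with an optional
equicorrelated Gaussian-copula knob for sensitivity studies.

Group sizes default to the study design (12/6/6/8/7). A fixed seed gives
an identical panel. `null_mode` replaces every group's spec by the
analyte's pooled benign spec, making all group differences null — and a
`spike` (multiplicative fold on chosen analyte × group cells) is applied
*after* pooling, so power studies ride on a null background.
`forward_mfi()` maps a concentration panel back through synthetic 5PL
curves to duplicate/diluted plate records with mean-one log-normal noise,
closing the loop for quantification round-trip tests.

What passing simulation tests do and do not show: the generator matches
the published group *margins* for the four constrained analytes, but it
does not model cross-cytokine correlation, plate effects, bead-count
failures or carryover. Calibrated-panel results (e.g. the three signature
cytokines clearing adjusted p < 0.001, or a three-way sample separation
with adjusted Rand ≥ 0.9) therefore validate the *pipeline* under the
published marginal distributions, not the biology of any new cohort.

# Numerical choices and problem sizes

* Trigamma inversion by Newton iteration (50-iteration cap, `1e-8`
  relative tolerance); asymptotic branches guard extreme inputs.
* Rejection sampling errors out when the truncation interval holds less
  than `1e-4` log-normal mass rather than looping.
* Ward ties resolve by the deterministic scan order of the
  agglomeration (towards smaller leaf indices); Youden ties towards the
  smallest cutoff; both for reproducibility.
* Panel CSVs serialize floating values at 15 significant digits, so a
  write/read round trip is the identity to below 1e-9 relative and twice
  round-tripped files are byte-identical.
* Simulation-level tests run 500 seeds for the null size check, 200 for
  spike recovery and 100 for calibrated significance/clustering — sizes
  chosen so the binomial assertions are sharp while the whole suite
  completes in about a minute.

# Known limitations

* The pipeline expects complete matrices; missingness must be resolved at
  the plate-record stage (cells with no record at all are an error, not
  an imputation).
* Only two-group contrasts are provided — no multi-factor designs, no
  robust/trend empirical-Bayes variants, no leave-k-out or bootstrap
  generalizations of the robustness counter, no partial or multi-class
  AUC.
* Absolute pg/mL values depend on the instrument's curve-fitting
  conventions; cross-study comparability is exactly why the IL-6 ratio
  track exists.
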