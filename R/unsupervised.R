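#' Spearman correlation distance between sample profiles
#'
#' `d(i, j) = 1 - rho_s(profile_i, profile_j)`, where `rho_s` is the
#' Spearman rank correlation across the analytes (average ranks for ties),
#' so the distance lies in `[0, 2]` and is invariant under any strictly
#' increasing transform of a sample's profile (raw, log2 and monotonically
#' quantified panels give the identical matrix).
#'
#' @param panel A [cytokine_panel] with at least 2 analytes.
#' @return A symmetric zero-diagonal distance matrix with sample-id
#'   dimnames (class `dist_matrix`).
#' @export
spearman_distance <- function(panel) {
  X <- panel_values(panel)
  if (ncol(X) < 2L) abort("need at least 2 analytes per profile")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    abort(paste0(
      "constant profile (zero rank variance) for sample(s): ",
      paste(rownames(X)[sds == 0], collapse = ", ")
    ))
  }
  rho <- stats::cor(t(X), method = "spearman")
  d <- 1 - rho
  diag(d) <- 0
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

check_dist <- function(d) {
  if (!isSymmetric(unclass(d), tol = 1e-12)) abort("distance matrix is not symmetric")
  if (any(!is.finite(d))) abort("distance matrix has non-finite entries")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix diagonal is not zero")
  invisible(d)
}

#' Ward.D2 agglomerative clustering
#'
#' Hierarchical clustering with the Ward.D2 criterion: the Lance-Williams
#' update operates on squared dissimilarities and the reported merge height
#' is the square root of the criterion (the `stats::hclust` `"ward.D2"`
#' method, which this wraps). Ties are resolved deterministically by the
#' scan order of the agglomeration, i.e. towards the smallest leaf indices.
#'
#' @param dist A distance matrix (e.g. [spearman_distance()]) or `dist`.
#' @return An `hclust` object (merge matrix, heights, leaf order).
#' @export
ward_d2_linkage <- function(dist) {
  if (inherits(dist, "dist")) {
    d <- dist
  } else {
    check_dist(dist)
    d <- stats::as.dist(dist)
  }
  if (attr(d, "Size") < 2L) abort("need at least 2 samples")
  stats::hclust(d, method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' Labels are renumbered by first appearance in the dendrogram's leaf
#' order, so cluster 1 is always the leftmost cluster of the tree.
#'
#' @param dend An `hclust` tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels named by sample id.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1L || k > n) abort("k out of range")
  raw <- stats::cutree(dend, k = k)
  first_seen <- unique(raw[dend$order])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  out <- relabel[as.character(raw)]
  stats::setNames(as.integer(out), names(raw))
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centres the squared distances, eigendecomposes, and returns
#' coordinates scaled by the square roots of the top-k positive
#' eigenvalues (via `stats::cmdscale`). Explained variance per retained
#' axis is its eigenvalue over the sum of the positive eigenvalues.
#'
#' @param dist Distance matrix or `dist`.
#' @param k Number of principal coordinates to retain (default 3).
#' @return An `mds_result`: list with `coordinates` (samples x k),
#'   `eigenvalues` (full spectrum), `explained_fraction` and
#'   `cumulative_explained` over the retained axes.
#' @export
classical_mds <- function(dist, k = 3) {
  if (!inherits(dist, "dist")) {
    check_dist(dist)
    dist <- stats::as.dist(dist)
  }
  n <- attr(dist, "Size")
  if (n < k + 1L) abort("need at least k + 1 samples")
  fit <- stats::cmdscale(dist, k = k, eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  if (length(pos) == 0L) abort("no positive eigenvalues: degenerate configuration")
  k_eff <- min(k, length(pos))
  coords <- fit$points[, seq_len(k_eff), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k_eff))
  expl <- eig[seq_len(k_eff)] / sum(pos)
  structure(
    list(
      coordinates = coords, eigenvalues = eig,
      explained_fraction = expl, cumulative_explained = cumsum(expl)
    ),
    class = "mds_result"
  )
}

#' @export
print.mds_result <- function(x, ...) {
  cat("<mds_result> ", nrow(x$coordinates), " samples, ",
    ncol(x$coordinates), " retained axes\n",
    sep = ""
  )
  cat(
    "  explained: ",
    paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", "),
    " (cumulative ", sprintf("%.1f%%", 100 * utils::tail(x$cumulative_explained, 1)),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname classical_mds
#' @param x An `mds_result`.
#' @param ... Unused.
#' @export
tidy.mds_result <- function(x, ...) {
  out <- as_tibble(x$coordinates)
  out$sample_id <- rownames(x$coordinates)
  out[, c("sample_id", setdiff(names(out), "sample_id"))]
}

#' Export a dendrogram as Newick text
#'
#' @param dend An `hclust` tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned instead of written.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend)
  txt <- ape::write.tree(phy)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(txt)
}

#' MDS scatter of a panel's samples
#'
#' @param panel A [cytokine_panel].
#' @param k Number of principal coordinates (the first two are plotted).
#' @return A ggplot of the first two principal coordinates, coloured by
#'   group, with explained-variance axis labels.
#' @export
plot_mds <- function(panel, k = 3) {
  mds <- classical_mds(spearman_distance(panel), k = k)
  df <- tidy(mds)
  df$group <- panel$group[match(df$sample_id, panel$sample_id)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * mds$explained_fraction[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * mds$explained_fraction[2])
    ) +
    ggplot2::theme_minimal()
}
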