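# Independent oracles and fixture builders used across the suite.

# Small panel straight from a matrix.
toy_panel <- function(values, groups, measure = "log2_concentration",
                      analytes = NULL, sample_ids = NULL) {
  n <- nrow(values)
  if (is.null(analytes)) analytes <- paste0("A", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n))
  df <- tibble::tibble(sample_id = sample_ids, group = groups)
  for (j in seq_along(analytes)) df[[analytes[j]]] <- values[, j]
  cytokine_panel(df, measure = measure)
}

# Textbook pooled two-sample t-test, one analyte at a time.
ordinary_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2))
}

# Step-up BH from its "min over larger ranks" definition, independent of
# stats::p.adjust.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * sorted[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mann-Whitney AUC by exhaustive pair counting.
mw_auc <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Exhaustive Ward.D2 agglomeration: at every step merge the pair of active
# clusters with the smallest squared-dissimilarity criterion, updating by
# the Lance-Williams rule on squared dissimilarities; heights are square
# roots of the criterion. Returns the merge list (member sets + heights).
brute_ward <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- seq_len(n)
  d2 <- D^2
  merges <- list()
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (d2[active[i], active[j]] < best[1] - 1e-15) {
          best <- c(d2[active[i], active[j]], i, j)
        }
      }
    }
    i <- active[best[2]]
    j <- active[best[3]]
    merges[[length(merges) + 1L]] <- list(
      members = sort(c(clusters[[i]], clusters[[j]])),
      height = sqrt(best[1])
    )
    upd <- vapply(active, function(m) {
      if (m %in% c(i, j)) {
        return(NA_real_)
      }
      ((sizes[i] + sizes[m]) * d2[i, m] + (sizes[j] + sizes[m]) * d2[j, m] -
        sizes[m] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[m])
    }, numeric(1))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    d2[i, active] <- upd
    d2[active, i] <- upd
    active <- setdiff(active, j)
  }
  merges
}

# Member sets + heights out of an hclust object, in merge order.
hclust_merges <- function(h) {
  sets <- list()
  for (m in seq_len(nrow(h$merge))) {
    mem <- c()
    for (x in h$merge[m, ]) {
      mem <- c(mem, if (x < 0) -x else sets[[x]]$members)
    }
    sets[[m]] <- list(members = sort(mem), height = h$height[m])
  }
  sets
}

as_dist_matrix <- function(D) {
  structure(D, class = c("dist_matrix", "matrix", "array"))
}

# 12-vs-20 marker construction honoring published group extremes: positives
# span [pos_min, pos_max] and include pos_min; negatives span
# [neg_min, neg_max] and include neg_max.
extremes_dataset <- function(pos_min, pos_max, neg_min, neg_max, seed = 1L) {
  set.seed(seed)
  pos <- c(pos_min, runif(11, pos_min, pos_max))
  neg <- c(runif(19, neg_min, neg_max), neg_max)
  list(
    values = c(pos, neg),
    labels = rep(c(TRUE, FALSE), c(12, 20))
  )
}

# 5-vs-5 log2 panel whose analyte X is significant in exactly one
# leave-one-out round: removing the planted low outlier (sample s05) is the
# only removal that pulls adjusted p below 0.01.
outlier_panel <- function() {
  set.seed(11)
  noise <- matrix(rnorm(10 * 9), 10, 9)
  x <- c(rep(2.5, 4) + rnorm(4, 0, 0.3), -2, rnorm(5, 0, 0.3))
  df <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    group = rep(c("BI-ALCL", "RS-A"), each = 5)
  )
  df$X <- x
  for (j in 1:9) df[[paste0("N", j)]] <- noise[, j]
  cytokine_panel(df, "log2_concentration")
}
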