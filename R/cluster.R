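#' Row-wise Z-score scaling
#'
#' Standardizes each gene's transformed expression profile to mean 0 and
#' sample s.d. 1 across samples, so clustering groups genes by the shape of
#' their expression pattern rather than its level. Constant rows carry no
#' shape and are dropped with a warning.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return Matrix of Z-scores (possibly fewer rows).
#' @export
zscore_scale <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stopf("need at least 2 samples")
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
  keep <- s > 0
  if (!any(keep)) stopf("all rows are constant")
  if (!all(keep))
    warning(sprintf("dropped %d constant row(s)", sum(!keep)))
  (x[keep, , drop = FALSE] - m[keep]) / s[keep]
}

# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the nearest center already chosen.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

best_kmeans <- function(x, k, n_restarts, iter_max) {
  if (k == nrow(x))   # trivial optimum; Hartigan-Wong needs k < n
    return(list(cluster = seq_len(nrow(x)), centers = x,
                size = rep(1L, nrow(x)), tot.withinss = 0))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      tryCatch(stats::kmeans(x, centers = centers, iter.max = iter_max),
               error = function(e) NULL))
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stopf("k-means failed for k = %d", k)
  best
}

pooled_withinss <- function(x, k, nstart, iter_max) {
  if (k == 1L) return(sum(sweep(x, 2L, colMeans(x))^2))
  best_kmeans(x, k, nstart, iter_max)$tot.withinss
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the log within-cluster dispersion `log(W_k)` of the data with
#' its expectation under `B` reference datasets drawn uniformly over each
#' feature's observed range:
#' `gap(k) = mean_b log(W*_kb) - log(W_k)`, with simulation standard error
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`. The chosen `k` is the smallest
#' `k` with `gap(k) >= gap(k+1) - s_{k+1}` (the 1-SE rule).
#'
#' @param x numeric matrix, points in rows (typically Z-scored genes).
#' @param k_max largest number of clusters to examine (>= 2).
#' @param B number of reference datasets (>= 10).
#' @param seed integer seed.
#' @param nstart restarts for the observed-data curve (the decision is
#'   sensitive to under-optimized W_k, so the data gets more restarts).
#' @param ref_nstart restarts for each reference dataset.
#' @param iter_max maximum k-means iterations.
#' @return Object of class `gap_stat`: data.frame `table` (`k`, `logW`,
#'   `logW_ref`, `gap`, `s`) and `chosen_k`.
#' @export
gap_statistic <- function(x, k_max = 12, B = 50, seed = NULL,
                          nstart = 25, ref_nstart = 5, iter_max = 25) {
  x <- as.matrix(x)
  if (k_max < 2L) stopf("k_max must be >= 2")
  if (B < 10L) stopf("B must be >= 10")
  if (k_max >= nrow(x)) stopf("k_max must be smaller than the number of points")
  with_seed(seed, {
    ks <- seq_len(k_max)
    logW <- vapply(ks, function(k)
      log(pooled_withinss(x, k, nstart, iter_max)), numeric(1))
    rng_lo <- apply(x, 2L, min)
    rng_hi <- apply(x, 2L, max)
    logW_ref <- matrix(NA_real_, B, k_max)
    for (b in seq_len(B)) {
      ref <- sapply(seq_len(ncol(x)), function(j)
        stats::runif(nrow(x), rng_lo[j], rng_hi[j]))
      logW_ref[b, ] <- vapply(ks, function(k)
        log(pooled_withinss(ref, k, ref_nstart, iter_max)), numeric(1))
    }
    gap <- colMeans(logW_ref) - logW
    s <- apply(logW_ref, 2L, stats::sd) * sqrt(1 + 1 / B)
    chosen <- k_max
    for (k in seq_len(k_max - 1L)) {
      if (gap[k] >= gap[k + 1L] - s[k + 1L]) { chosen <- k; break }
    }
    structure(list(table = data.frame(k = ks, logW = logW,
                                      logW_ref = colMeans(logW_ref),
                                      gap = gap, s = s),
                   chosen_k = chosen, B = B),
              class = "gap_stat")
  })
}

#' @export
print.gap_stat <- function(x, ...) {
  cat(sprintf("Gap statistic over k = 1..%d (B = %d): chosen k = %d\n",
              max(x$table$k), x$B, x$chosen_k))
  print(x$table, digits = 4)
  invisible(x)
}

#' K-means clustering of expression profiles
#'
#' Runs [stats::kmeans()] (Hartigan-Wong) from k-means++ initial centers,
#' best of `n_restarts` seeded restarts by total within-cluster sum of
#' squares.
#'
#' @param x numeric matrix, points in rows.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @param iter_max maximum iterations per run.
#' @return Object of class `cluster_model`: `assignments` (named integer
#'   vector), `centroids` (k by sample matrix), `sizes`, `tot_withinss`.
#' @export
kmeans_cluster <- function(x, k, seed = NULL, n_restarts = 25,
                           iter_max = 50) {
  x <- as.matrix(x)
  if (k > nrow(x)) stopf("k must not exceed the number of points")
  fit <- with_seed(seed, best_kmeans(x, k, n_restarts, iter_max))
  assignments <- fit$cluster
  names(assignments) <- rownames(x)
  structure(list(assignments = assignments, centroids = fit$centers,
                 sizes = as.integer(fit$size),
                 tot_withinss = fit$tot.withinss),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means model: %d clusters over %d points (within-SS %.2f)\n",
              nrow(x$centroids), length(x$assignments), x$tot_withinss))
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Assign clusters to the four expression-pattern categories
#'
#' Aggregates each cluster centroid to per-group means (`MH`, `MA`, `F4`)
#' and labels the cluster by where the parents sit relative to the hybrid,
#' with a dead zone of half-width `delta` (Z-units): a parent more than
#' `delta` below the hybrid is "under", within `delta` is "similar".
#' Clusters fitting no category are `UNASSIGNED`.
#'
#' @param model a [cluster_model()] whose centroids are in Z-score space.
#' @param sample_groups group label per centroid column.
#' @param delta dead-zone half-width in Z-units.
#' @return `data.frame` with `cluster`, `m_MH`, `m_MA`, `m_F4`, `category`,
#'   `parent` (implicated parent or `NA`).
#' @export
categorize_clusters <- function(model, sample_groups, delta = 0.5) {
  stopifnot(inherits(model, "cluster_model"))
  check_group(sample_groups)
  if (!all(GROUPS %in% sample_groups)) stopf("all three groups required")
  gm <- sapply(GROUPS, function(g)
    rowMeans(model$centroids[, sample_groups == g, drop = FALSE]))
  if (is.null(dim(gm))) gm <- matrix(gm, 1L, dimnames = list(NULL, GROUPS))
  out <- data.frame(cluster = seq_len(nrow(gm)),
                    m_MH = gm[, "MH"], m_MA = gm[, "MA"], m_F4 = gm[, "F4"],
                    category = "UNASSIGNED", parent = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gm))) {
    d_mh <- unname(gm[i, "MH"] - gm[i, "F4"])
    d_ma <- unname(gm[i, "MA"] - gm[i, "F4"])
    under <- c(MH = d_mh < -delta, MA = d_ma < -delta)
    over <- c(MH = d_mh > delta, MA = d_ma > delta)
    near <- c(MH = abs(d_mh) <= delta, MA = abs(d_ma) <= delta)
    parents_close <- abs(gm[i, "MH"] - gm[i, "MA"]) <= delta
    if (all(under) && parents_close) {
      out$category[i] <- "UNDER_BOTH_PARENTS"
    } else if (all(over) && parents_close) {
      out$category[i] <- "OVER_BOTH_PARENTS"
    } else if (sum(under) == 1L && near[!under]) {
      out$category[i] <- "UNDER_ONE_PARENT"
      out$parent[i] <- names(under)[under]
    } else if (sum(over) == 1L && near[!over]) {
      out$category[i] <- "OVER_ONE_PARENT"
      out$parent[i] <- names(over)[over]
    }
  }
  rownames(out) <- NULL
  out
}

#' Principal component analysis of samples
#'
#' Centers each gene and decomposes the sample-by-gene matrix by SVD.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return Object of class `pca_result`: `scores` (samples by components),
#'   `loadings`, `variance_fraction`.
#' @export
pca_samples <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stopf("need at least 2 samples")
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  if (sum(fit$sdev^2) <= 1e-12)
    stopf("degenerate input: samples are identical")
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, loadings = fit$rotation,
                 variance_fraction = vf),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of samples; variance explained (%):\n")
  v <- round(100 * x$variance_fraction, 2)
  names(v) <- paste0("PC", seq_along(v))
  print(utils::head(v, 5))
  invisible(x)
}

#' Sample-to-sample distances and hierarchical leaf order
#'
#' Euclidean distances between sample expression profiles, clustered by
#' complete-linkage agglomeration. Samples are pre-sorted lexicographically
#' so equal-distance merges resolve deterministically.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return List with `dist` (full symmetric matrix), `order` (leaf order,
#'   sample ids), `hclust`.
#' @export
sample_distance_order <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stopf("need at least 2 samples")
  x <- x[, order(colnames(x)), drop = FALSE]
  d <- stats::dist(t(x), method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  list(dist = as.matrix(d), order = colnames(x)[hc$order], hclust = hc)
}
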