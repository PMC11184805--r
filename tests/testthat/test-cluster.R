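test_that("z-scoring standardizes rows and drops constant ones", {
  x <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(10, 0, 20))
  expect_warning(z <- zscore_scale(x), "constant")
  expect_equal(rownames(z), c("a", "c"))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
  # idempotence
  expect_equal(zscore_scale(z), z, tolerance = 1e-9)
  expect_error(zscore_scale(rbind(c(1, 1, 1))), "constant")
})

test_that("within-dispersion is non-increasing and matched by exhaustive search", {
  set.seed(5)
  x <- rbind(matrix(rnorm(12, 0), 6, 2), matrix(rnorm(12, 5), 6, 2))
  gs <- gap_statistic(x, k_max = 4, B = 10, seed = 1)
  expect_true(all(diff(gs$table$logW) <= 1e-9))
  # exhaustive 2-partition oracle over 12 points
  best_ss <- Inf
  for (code in 0:(2^11 - 1)) {
    grp <- c(0L, as.integer(intToBits(code))[1:11])
    if (length(unique(grp)) < 2L) next
    ss <- sum(vapply(0:1, function(g) {
      pts <- x[grp == g, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    best_ss <- min(best_ss, ss)
  }
  expect_equal(gs$table$logW[2], log(best_ss), tolerance = 1e-9)
})

test_that("gap statistic picks two well-separated blobs", {
  set.seed(11)
  x <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
             matrix(rnorm(60, 6, 0.3), 30, 2))
  gs <- gap_statistic(x, k_max = 5, B = 20, seed = 3)
  expect_equal(gs$chosen_k, 2)
})

test_that("gap and s satisfy their defining identities on a toy set", {
  # recompute every quantity independently from the returned table inputs
  set.seed(13)
  x <- matrix(rnorm(24), 12, 2)
  gs <- gap_statistic(x, k_max = 3, B = 10, seed = 99)
  tab <- gs$table
  expect_equal(tab$gap, tab$logW_ref - tab$logW, tolerance = 1e-12)
  # chosen k is the smallest k with gap(k) >= gap(k+1) - s(k+1)
  rule <- which(tab$gap[-nrow(tab)] >= tab$gap[-1] - tab$s[-1])
  expected <- if (length(rule)) min(rule) else nrow(tab)
  expect_equal(gs$chosen_k, expected)
  # k = 1 dispersion is the total sum of squares around the grand mean
  expect_equal(tab$logW[1], log(sum(sweep(x, 2, colMeans(x))^2)))
})

test_that("k-means handles degenerate and planted cases", {
  x <- matrix(rnorm(20), 10, 2)
  rownames(x) <- paste0("p", 1:10)
  m <- kmeans_cluster(x, k = 10, seed = 1)
  expect_equal(m$tot_withinss, 0)
  expect_equal(sort(unname(m$assignments)), 1:10)
  two_same <- rbind(c(1, 2), c(1, 2))
  m1 <- kmeans_cluster(two_same, 1, seed = 1)
  expect_equal(unname(m1$centroids[1, ]), c(1, 2))
  expect_error(kmeans_cluster(x, 11), "exceed")
  expect_equal(sum(m$sizes), nrow(x))
})

test_that("planted archetypes are recovered up to label permutation", {
  skip_if_not_installed("mclust")
  sim <- simulate_counts(count_sim_spec(
    n_genes = 1000, cluster_sizes = rep(50, 8),
    base_mean_range = c(2000, 10000), log2_effect = 3, dispersion = 0.01,
    seed = 17))
  tx <- shifted_log_transform(sim$counts,
                              estimate_size_factors(sim$counts))
  z <- zscore_scale(tx[sim$truth$gene_id[sim$truth$cluster > 0], ])
  m <- kmeans_cluster(z, 8, seed = 3, n_restarts = 10)
  truth <- sim$truth$cluster[match(names(m$assignments),
                                   sim$truth$gene_id)]
  expect_gte(mclust::adjustedRandIndex(m$assignments, truth), 0.95)
})

test_that("centroid categorization follows the delta rule", {
  model <- make_cluster_model(list(
    c(MH = -1.2, MA = 0.05, F4 = 0),    # under in MH only
    c(MH = -1.0, MA = -1.0, F4 = 1.5),  # under in both
    c(MH = 1.0, MA = 1.0, F4 = -1.5),   # over in both
    c(MH = 0.3, MA = -0.2, F4 = 0),     # nothing beyond delta
    c(MH = 1.2, MA = -1.2, F4 = 0)))    # opposite shifts -> unassigned
  cats <- categorize_clusters(model, sample_groups_9, delta = 0.5)
  expect_equal(cats$category,
               c("UNDER_ONE_PARENT", "UNDER_BOTH_PARENTS",
                 "OVER_BOTH_PARENTS", "UNASSIGNED", "UNASSIGNED"))
  expect_equal(cats$parent[1], "MH")
  mirrored <- make_cluster_model(list(c(MH = 0.05, MA = 1.2, F4 = 0)))
  expect_equal(categorize_clusters(mirrored, sample_groups_9)$category,
               "OVER_ONE_PARENT")
})

test_that("PCA fractions match an independent covariance eigensolve", {
  x <- matrix(c(1, 4, 2, 8, 3, 5, 9, 2, 6, 7, 1, 3), 4, 3)  # genes x samples
  p <- pca_samples(x)
  ev <- eigen(cov(t(x)))$values
  expect_equal(p$variance_fraction[1:2], (ev / sum(ev))[1:2],
               tolerance = 1e-12)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # invariance to gene order and per-gene constant shifts
  p2 <- pca_samples(x[c(3, 1, 4, 2), ] + c(10, -5, 0, 100))
  expect_equal(p2$variance_fraction, p$variance_fraction,
               tolerance = 1e-12)
  # collinear samples put everything on PC1
  line <- rbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(pca_samples(line)$variance_fraction[1], 1)
})

test_that("sample distances are Euclidean, symmetric and ordered stably", {
  x <- cbind(s1 = c(0, 0), s2 = c(3, 4), s3 = c(6, 8))
  out <- sample_distance_order(x)
  expect_equal(out$dist["s1", "s2"], 5)
  expect_equal(unname(diag(out$dist)), c(0, 0, 0))
  expect_equal(out$dist, t(out$dist))
  # complete linkage merges s1,s2 (d=5) then joins s3 at max(10, 5)
  expect_equal(out$hclust$height, c(5, 10))
  dup <- cbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  o <- sample_distance_order(dup)
  pos <- match(c("a", "b"), o$order)
  expect_equal(abs(diff(pos)), 1)   # identical samples are adjacent leaves
})
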