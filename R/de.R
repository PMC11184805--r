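#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making counts comparable across libraries.
#' For each gene expressed in every sample, the count is divided by the
#' gene's geometric mean across samples; a sample's factor is the median of
#' these ratios. Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns.
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stopf(paste("no gene has nonzero counts in every sample;",
                "consider a pseudo-reference (e.g. add a pseudocount)"))
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2L, function(x) exp(stats::median(x - loggeo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Shifted-log transform of normalized counts
#'
#' Places normalized counts on the log2 scale,
#' `t = log2(count / size_factor + 1)`, a monotone variance-damping
#' transform used upstream of Z-scoring and clustering. This is a simpler
#' stand-in for shrinkage-based regularized log transforms: it is exact at
#' zero, monotone, and asymptotically log2.
#'
#' @param counts gene-by-sample count matrix.
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @return Matrix of the same shape on the log2 scale.
#' @export
shifted_log_transform <- function(counts, size_factors) {
  counts <- as.matrix(counts)
  if (length(size_factors) != ncol(counts))
    stopf("one size factor per sample required")
  log2(sweep(counts, 2L, size_factors, "/") + 1)
}

#' Per-gene negative-binomial Wald test between two groups
#'
#' For each gene, group means are estimated from normalized counts and a
#' per-gene NB dispersion `alpha` (variance `mu + alpha * mu^2`) is
#' estimated by method of moments from the within-group variances pooled
#' across the two groups, floored at 1e-8. The effect is
#' `log2fc = log2((muB + eps) / (muA + eps))` with `eps = 0.5`; its standard
#' error comes from the delta method on the NB variance, and the Wald
#' p-value is the two-sided normal tail of `log2fc / se`. P-values are
#' BH-adjusted across all tested genes.
#'
#' @param counts gene-by-sample count matrix.
#' @param size_factors per-sample size factors.
#' @param groups character vector of group labels per sample (column).
#' @param group_a,group_b the two group labels to contrast; the fold change
#'   is B over A.
#' @param eps pseudo-mean added to both group means in the fold change.
#' @return `data.frame` with `gene_id`, `contrast`, `base_mean`, `log2fc`,
#'   `se`, `wald_p`, `padj`.
#' @export
nb_wald_test <- function(counts, size_factors, groups, group_a, group_b,
                         eps = 0.5) {
  counts <- as.matrix(counts)
  a_idx <- which(groups == group_a)
  b_idx <- which(groups == group_b)
  if (length(a_idx) < 2L || length(b_idx) < 2L)
    stopf("need at least 2 replicates per group")
  q <- sweep(counts, 2L, size_factors, "/")
  qa <- q[, a_idx, drop = FALSE]
  qb <- q[, b_idx, drop = FALSE]
  if (all(qa == 0) || all(qb == 0))
    stopf("a group has all-zero counts for every gene")
  na <- length(a_idx); nb <- length(b_idx)
  mu_a <- rowMeans(qa); mu_b <- rowMeans(qb)
  va <- rowSums((qa - mu_a)^2) / (na - 1L)
  vb <- rowSums((qb - mu_b)^2) / (nb - 1L)
  v_pool <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  mu_pool <- (mu_a + mu_b) / 2
  alpha <- pmax((v_pool - mu_pool) / pmax(mu_pool, 1e-12)^2, 1e-8)

  l2fc <- log2((mu_b + eps) / (mu_a + eps))
  var_l2fc <- ((mu_a + alpha * mu_a^2) / na / (mu_a + eps)^2 +
               (mu_b + alpha * mu_b^2) / nb / (mu_b + eps)^2) / log(2)^2
  se <- sqrt(var_l2fc)
  z <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[mu_a == 0 & mu_b == 0] <- 1
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             contrast = paste0(group_b, "-vs-", group_a),
             base_mean = mu_pool, log2fc = l2fc, se = se, wald_p = p,
             padj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DEG accounting across the three pairwise contrasts
#'
#' @param n_f4_vs_mh,n_f4_vs_ma,n_parent_similar_f4_diff counts of the three
#'   disjoint DEG sets.
#' @return Object of class `deg_accounting` with the three counts and their
#'   total.
#' @export
deg_accounting <- function(n_f4_vs_mh, n_f4_vs_ma,
                           n_parent_similar_f4_diff) {
  structure(list(n_f4_vs_mh = n_f4_vs_mh, n_f4_vs_ma = n_f4_vs_ma,
                 n_parent_similar_f4_diff = n_parent_similar_f4_diff,
                 n_total = n_f4_vs_mh + n_f4_vs_ma +
                   n_parent_similar_f4_diff),
            class = "deg_accounting")
}

#' @export
print.deg_accounting <- function(x, ...) {
  cat(sprintf(
    "DEGs: %d (F4 vs MH) + %d (F4 vs MA) + %d (parent-similar) = %d total\n",
    x$n_f4_vs_mh, x$n_f4_vs_ma, x$n_parent_similar_f4_diff, x$n_total))
  invisible(x)
}

#' Call differentially expressed genes and partition them
#'
#' A gene is DE in a contrast when `padj < alpha` and `|log2fc| >= min_l2fc`
#' (fold change of at least `2^min_l2fc`). The parent-similar/hybrid-
#' different set contains genes not DE between the parents but DE against
#' both in the hybrid. The two single-parent sets exclude that set, and a
#' gene DE against both parents that is also DE between the parents is
#' assigned to the F4-vs-MH set, so the three reported sets are disjoint and
#' sum to the union.
#'
#' @param res_f4_mh,res_f4_ma,res_mh_ma results from [nb_wald_test()] for
#'   the F4-vs-MH, F4-vs-MA and MH-vs-MA contrasts (same gene order).
#' @param alpha adjusted-p significance threshold.
#' @param min_l2fc minimum absolute log2 fold change (1 = two-fold).
#' @return List with `accounting` ([deg_accounting()]) and the gene-id
#'   vectors `f4_vs_mh`, `f4_vs_ma`, `parent_similar`, `all`.
#' @export
call_degs <- function(res_f4_mh, res_f4_ma, res_mh_ma,
                      alpha = 0.05, min_l2fc = 1) {
  for (r in list(res_f4_mh, res_f4_ma, res_mh_ma))
    if (!all(c("gene_id", "padj", "log2fc") %in% names(r)))
      stopf("each contrast result needs gene_id, padj, log2fc")
  if (!identical(res_f4_mh$gene_id, res_f4_ma$gene_id) ||
      !identical(res_f4_mh$gene_id, res_mh_ma$gene_id))
    stopf("contrast results must cover the same genes in the same order")
  de <- function(r) !is.na(r$padj) & r$padj < alpha & abs(r$log2fc) >= min_l2fc
  de_mh <- de(res_f4_mh); de_ma <- de(res_f4_ma); de_pp <- de(res_mh_ma)
  ids <- res_f4_mh$gene_id
  parent_similar <- de_mh & de_ma & !de_pp
  set_mh <- de_mh & !parent_similar
  set_ma <- de_ma & !parent_similar & !de_mh
  list(accounting = deg_accounting(sum(set_mh), sum(set_ma),
                                   sum(parent_similar)),
       f4_vs_mh = ids[set_mh], f4_vs_ma = ids[set_ma],
       parent_similar = ids[parent_similar],
       all = ids[set_mh | set_ma | parent_similar])
}

#' Read a gene-by-sample count table
#'
#' @param counts_path TSV with first column `gene_id` and one column per
#'   sample.
#' @param samples_path TSV with columns `sample_id`, `group`.
#' @return List with `counts` (integer matrix) and `samples` (data.frame).
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab[[1L]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(colnames(counts) %in% samples$sample_id))
    stopf("count columns missing from the sample table")
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  check_group(samples$group)
  list(counts = counts, samples = samples)
}
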