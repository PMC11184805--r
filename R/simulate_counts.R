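# The eight planted expression archetypes, as per-group log2 offsets in
# units of log2_effect (MH, MA, F4 relative to the null baseline). They
# realise the four expression-pattern categories of the default study
# design: four clusters
# under-expressed in one parent (three MH, one MA), two over-expressed in
# one parent, one under- and one over-expressed in both parents. The two
# extra MH-under clusters carry a small secondary shift in the other parent
# (within the categorisation half-window) so the eight archetypes stay
# distinct directions after Z-scoring.
COUNT_ARCHETYPES <- list(
  c1 = list(off = c(MH = -1,   MA = 0,    F4 = 0), category = "UNDER_ONE_PARENT", parent = "MH"),
  c2 = list(off = c(MH = 1,    MA = 0,    F4 = 0), category = "OVER_ONE_PARENT",  parent = "MH"),
  c3 = list(off = c(MH = 0,    MA = -1,   F4 = 0), category = "UNDER_ONE_PARENT", parent = "MA"),
  c4 = list(off = c(MH = -1,   MA = 0.25, F4 = 0), category = "UNDER_ONE_PARENT", parent = "MH"),
  c5 = list(off = c(MH = -1,   MA = -0.2, F4 = 0), category = "UNDER_ONE_PARENT", parent = "MH"),
  c6 = list(off = c(MH = -1,   MA = -1,   F4 = 0), category = "UNDER_BOTH_PARENTS", parent = NA),
  c7 = list(off = c(MH = 1,    MA = 1,    F4 = 0), category = "OVER_BOTH_PARENTS", parent = NA),
  c8 = list(off = c(MH = 0,    MA = 1,    F4 = 0), category = "OVER_ONE_PARENT",  parent = "MA"))

#' Specification for the RNA-seq count simulator
#'
#' Counts are negative binomial with variance `mu + dispersion * mu^2`.
#' Genes in one of the eight planted clusters receive group-specific mean
#' shifts following the cluster's archetype (under-/over-expression in one
#' or both parents relative to the hybrid); the remaining genes are null
#' (shared mean across groups).
#'
#' @param n_genes total number of genes.
#' @param cluster_sizes integer vector of length 8: genes per planted
#'   cluster; defaults give category totals 3576/2414/362/250.
#' @param base_mean_range positive range; baseline means are drawn
#'   log-uniformly from it.
#' @param log2_effect magnitude of the planted group shifts (log2 units).
#' @param dispersion NB dispersion `alpha`.
#' @param replicates_per_group replicates per group.
#' @param seed integer seed.
#' @return Object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 20000,
                           cluster_sizes = c(894, 1207, 894, 894, 894,
                                             362, 250, 1207),
                           base_mean_range = c(50, 2000),
                           log2_effect = 2, dispersion = 0.05,
                           replicates_per_group = 3, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", positive = TRUE)
  if (length(cluster_sizes) != 8L || any(cluster_sizes < 0))
    stopf("cluster_sizes must be 8 non-negative counts")
  if (sum(cluster_sizes) > n_genes)
    stopf("sum(cluster_sizes) exceeds n_genes")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stopf("dispersion must be positive")
  if (length(base_mean_range) != 2L || any(base_mean_range <= 0))
    stopf("base_mean_range must be a positive interval")
  structure(list(n_genes = n_genes,
                 cluster_sizes = as.integer(cluster_sizes),
                 base_mean_range = sort(base_mean_range),
                 log2_effect = log2_effect, dispersion = dispersion,
                 replicates_per_group =
                   check_count(replicates_per_group, "replicates_per_group",
                               positive = TRUE),
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Simulate a gene-by-sample NB count matrix with planted clusters
#'
#' @param spec a [count_sim_spec()].
#' @return List with `counts` (integer matrix, genes by samples), `samples`
#'   (data.frame `sample_id`, `group`) and `truth` (data.frame per gene:
#'   `gene_id`, `cluster` (0 = null), `category`, `parent`, and the true
#'   per-group log2 offsets `off_MH`, `off_MA`, `off_F4`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    r <- spec$replicates_per_group
    gene_ids <- sprintf("gene%05d", seq_len(n))
    sample_ids <- paste0(rep(GROUPS, each = r), "_", seq_len(r))
    sample_groups <- rep(GROUPS, each = r)

    cluster <- rep(0L, n)
    pos <- 0L
    for (k in seq_along(spec$cluster_sizes)) {
      cluster[pos + seq_len(spec$cluster_sizes[k])] <- k
      pos <- pos + spec$cluster_sizes[k]
    }
    cluster <- sample(cluster)   # interleave planted and null genes

    lo <- log(spec$base_mean_range[1L]); hi <- log(spec$base_mean_range[2L])
    base_mean <- exp(stats::runif(n, lo, hi))

    off <- matrix(0, n, 3L, dimnames = list(NULL, GROUPS))
    for (k in seq_along(COUNT_ARCHETYPES)) {
      idx <- cluster == k
      if (any(idx))
        off[idx, ] <- matrix(COUNT_ARCHETYPES[[k]]$off[GROUPS] *
                               spec$log2_effect,
                             sum(idx), 3L, byrow = TRUE)
    }

    mu <- base_mean * 2^off[, sample_groups, drop = FALSE]
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / spec$dispersion),
                     n, length(sample_ids),
                     dimnames = list(gene_ids, sample_ids))

    truth <- data.frame(
      gene_id = gene_ids, cluster = cluster,
      category = ifelse(cluster == 0L, "NULL",
                        vapply(pmax(cluster, 1L), function(k)
                          COUNT_ARCHETYPES[[k]]$category, character(1))),
      parent = ifelse(cluster == 0L, NA_character_,
                      vapply(pmax(cluster, 1L), function(k)
                        as.character(COUNT_ARCHETYPES[[k]]$parent),
                        character(1))),
      off_MH = off[, "MH"], off_MA = off[, "MA"], off_F4 = off[, "F4"],
      stringsAsFactors = FALSE)
    truth$category[truth$cluster == 0L] <- "NULL"

    list(counts = counts,
         samples = data.frame(sample_id = sample_ids, group = sample_groups,
                              stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Write simulated counts and sample table
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory.
#' @return Invisibly, the paths written (`counts.tsv`, `samples.tsv`).
#' @export
write_counts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(gene_id = rownames(sim$counts), sim$counts,
                                check.names = FALSE),
                     cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- file.path(dir, "samples.tsv")
  utils::write.table(sim$samples, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cpath, spath))
}
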