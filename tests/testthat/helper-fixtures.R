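# Shared fixture builders: everything is generated in code at test time.

# a minimal variant_set built directly from field values
make_variant_set <- function(fix, gq, ad_ref, ad_alt, gt = NULL,
                             samples = NULL) {
  n <- nrow(fix)
  if (is.null(samples))
    samples <- paste0(rep(c("MH", "MA", "F4"), each = 3), "_", 1:3)
  as_mat <- function(x) {
    m <- matrix(x, nrow = n, ncol = length(samples))
    colnames(m) <- samples
    m
  }
  if (is.null(gt)) gt <- "0/1"
  structure(list(fix = fix, gt = as_mat(gt), gq = as_mat(gq),
                 ad_ref = as_mat(ad_ref), ad_alt = as_mat(ad_alt),
                 samples = samples, n_skipped = 0L),
            class = "variant_set")
}

make_fix <- function(n = 1, QD = 30, FS = 5, MQ = 60, ReadPosRankSum = 0) {
  data.frame(chrom = "chr1A", pos = seq_len(n) * 100L,
             id = sprintf("v%03d", seq_len(n)), ref = "A", alt = "G",
             QD = QD, FS = FS, MQ = MQ, ReadPosRankSum = ReadPosRankSum,
             stringsAsFactors = FALSE)
}

# cluster_model with prescribed per-group centroid means
make_cluster_model <- function(group_means, reps = 3) {
  centroids <- do.call(rbind, lapply(group_means, function(m)
    rep(m[c("MH", "MA", "F4")], each = reps)))
  colnames(centroids) <- paste0(rep(c("MH", "MA", "F4"), each = reps),
                                "_", seq_len(reps))
  structure(list(assignments = stats::setNames(
                   seq_along(group_means),
                   paste0("g", seq_along(group_means))),
                 centroids = centroids,
                 sizes = rep(1L, length(group_means)),
                 tot_withinss = 0),
            class = "cluster_model")
}

sample_groups_9 <- rep(c("MH", "MA", "F4"), each = 3)

# small cluster truth table for the variant simulator
small_cluster_table <- function(n_per = 20) {
  cats <- data.frame(
    cluster = 1:4,
    category = c("UNDER_ONE_PARENT", "OVER_ONE_PARENT",
                 "UNDER_BOTH_PARENTS", "OVER_BOTH_PARENTS"),
    parent = c("MH", "MA", NA, NA), stringsAsFactors = FALSE)
  do.call(rbind, lapply(1:4, function(k)
    data.frame(gene_id = sprintf("gene_c%d_%02d", k, seq_len(n_per)),
               cluster = k, category = cats$category[k],
               parent = cats$parent[k], stringsAsFactors = FALSE)))
}
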