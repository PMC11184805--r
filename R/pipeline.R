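#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' threshold at its documented default. Pass overrides as a named list or a
#' YAML file; unknown keys are rejected.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    out_dir = "hybridomics_out",
    seed = 1L,
    stages = c("simulate", "msap", "de", "cluster", "variants", "enrich"),
    # synthetic data
    msap_sim = list(n_sites = 740,
                    group_meth_levels = c(MH = 0.856, MA = 0.824, F4 = 0.745),
                    n_demeth_sites = 50, n_hyper_sites = 26,
                    replicates_per_group = 4, noise_rate = 0),
    count_sim = list(n_genes = 20000,
                     cluster_sizes = c(894, 1207, 894, 894, 894, 362, 250,
                                       1207),
                     base_mean_range = c(50, 2000), log2_effect = 2,
                     dispersion = 0.05, replicates_per_group = 3),
    variant_sim = list(n_genes_with_snps = 477, snps_per_gene = 2.94,
                       concordant_fraction = 0.73, fail_fraction = 0.1),
    annotation_sim = list(n_null_terms = 30, n_planted_terms = 2,
                          bg_rate = 0.02, enrich_rate = 0.5),
    # analysis thresholds
    alpha = 0.05, min_l2fc = 1,
    delta = 0.5, k_max = 12, gap_B = 50, kmeans_restarts = 25,
    fixed_k = NULL,
    qd_min = 2, fs_max = 60, mq_min = 40, rprs_min = -8,
    min_gq = 15, het_range = c(0.2, 0.8),
    enrich_fdr = 0.05, denominator = "informative", parent_rule = "any")
}

validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, config)
  check_fraction(merged$alpha, "alpha")
  if (merged$min_l2fc < 0) stopf("min_l2fc must be non-negative")
  if (merged$delta <= 0) stopf("delta must be positive")
  if (merged$k_max < 2) stopf("k_max must be >= 2")
  if (merged$gap_B < 10) stopf("gap_B must be >= 10")
  check_fraction(merged$het_range, "het_range")
  if (!all(merged$stages %in% defaults$stages))
    stopf("unknown stage in config")
  merged
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a subset of the keys in [default_config()].
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("msap_sim", "count_sim"))
    if (!is.null(cfg[[key]])) {
      if (!is.null(cfg[[key]]$group_meth_levels))
        cfg[[key]]$group_meth_levels <- unlist(cfg[[key]]$group_meth_levels)
      if (!is.null(cfg[[key]]$cluster_sizes))
        cfg[[key]]$cluster_sizes <- unlist(cfg[[key]]$cluster_sizes)
    }
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' @param config configuration list.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become maps, or YAML drops their names
  as_mappable <- function(x) {
    if (is.list(x)) lapply(x, as_mappable)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(as_mappable(config), path)
  invisible(path)
}

#' Run the full parent-versus-hybrid pipeline
#'
#' Executes the enabled stages in dependency order — synthetic-data
#' generation, MSAP methylation scoring and event calling, differential
#' expression, Z-score/gap-statistic/k-means clustering with category
#' assignment, variant filtering/effect/concordance analysis, and GO
#' enrichment — writing stage outputs under `config$out_dir` and returning
#' a machine-readable run summary.
#'
#' @param config a configuration list (see [default_config()]), or a path
#'   to a YAML file.
#' @return Invisibly, the run summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  else config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, stages = list())
  t_start <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  msap_sim <- counts_sim <- NULL

  if ("simulate" %in% config$stages) {
    stage("simulate", {
      msap_sim <- simulate_msap(do.call(msap_sim_spec,
        c(config$msap_sim, list(seed = config$seed))))
      write_msap_bands(msap_sim$profiles, file.path(out_dir, "bands"))
      counts_sim <- simulate_counts(do.call(count_sim_spec,
        c(config$count_sim, list(seed = config$seed + 1L))))
      write_counts(counts_sim, out_dir)
      summary$stages$simulate <- list(
        n_sites = config$msap_sim$n_sites,
        n_genes = nrow(counts_sim$counts),
        planted_de = sum(counts_sim$truth$cluster > 0))
    })
  }

  profiles <- read_msap_bands(file.path(out_dir, "bands"))
  msap_out <- NULL
  if ("msap" %in% config$stages) {
    stage("msap", {
      msap_out <- run_msap(profiles, file.path(out_dir, "msap"),
                           denominator = config$denominator,
                           parent_rule = config$parent_rule)
      summary$stages$msap <- list(
        n_sites = nrow(msap_out$states),
        levels_pct = stats::setNames(round(msap_out$summary$mean_pct, 2),
                                     msap_out$summary$group),
        demethylation = sum(msap_out$events$event_type == "DEMETHYLATION"),
        hypermethylation =
          sum(msap_out$events$event_type == "HYPERMETHYLATION"))
    })
  }

  cd <- read_counts(file.path(out_dir, "counts.tsv"),
                    file.path(out_dir, "samples.tsv"))
  degs <- NULL; tx <- NULL
  if ("de" %in% config$stages) {
    stage("de", {
      sf <- estimate_size_factors(cd$counts)
      tx <- shifted_log_transform(cd$counts, sf)
      g <- cd$samples$group
      res <- list(
        f4_mh = nb_wald_test(cd$counts, sf, g, "MH", "F4"),
        f4_ma = nb_wald_test(cd$counts, sf, g, "MA", "F4"),
        mh_ma = nb_wald_test(cd$counts, sf, g, "MA", "MH"))
      for (nm in names(res))
        utils::write.table(res[[nm]],
                           file.path(out_dir,
                                     paste0("de_", res[[nm]]$contrast[1L],
                                            ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      degs <- call_degs(res$f4_mh, res$f4_ma, res$mh_ma,
                         alpha = config$alpha, min_l2fc = config$min_l2fc)
      utils::write.table(
        data.frame(gene_id = rownames(tx), tx, check.names = FALSE),
        file.path(out_dir, "transformed.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(unclass(degs$accounting),
                           file.path(out_dir, "deg_accounting.json"),
                           auto_unbox = TRUE, digits = NA)
      summary$stages$de <- unclass(degs$accounting)
    })
  }

  cluster_table <- NULL
  if ("cluster" %in% config$stages) {
    stage("cluster", {
      if (is.null(degs)) stopf("cluster stage requires the de stage")
      z <- zscore_scale(tx[degs$all, , drop = FALSE])
      k <- config$fixed_k
      gap <- NULL
      if (is.null(k)) {
        gap <- gap_statistic(z, k_max = config$k_max, B = config$gap_B,
                             seed = config$seed + 2L)
        k <- gap$chosen_k
        utils::write.table(gap$table, file.path(out_dir, "gapstat.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      model <- kmeans_cluster(z, k, seed = config$seed + 3L,
                              n_restarts = config$kmeans_restarts)
      cats <- categorize_clusters(model, cd$samples$group,
                                  delta = config$delta)
      cluster_table <- data.frame(
        gene_id = names(model$assignments),
        cluster = unname(model$assignments),
        category = cats$category[model$assignments],
        parent = cats$parent[model$assignments],
        stringsAsFactors = FALSE)
      utils::write.table(cluster_table, file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pca <- pca_samples(tx)
      utils::write.table(
        data.frame(sample = rownames(pca$scores),
                   round(pca$scores[, 1:2, drop = FALSE], 4)),
        file.path(out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      sdo <- sample_distance_order(tx)
      utils::write.table(round(sdo$dist, 4),
                         file.path(out_dir, "distance.tsv"), sep = "\t",
                         quote = FALSE)
      summary$stages$cluster <- list(
        chosen_k = k, sizes = model$sizes,
        categories = stats::setNames(cats$category, cats$cluster),
        pc_variance_pct = round(100 * pca$variance_fraction[1:2], 2))
    })
  }

  if ("variants" %in% config$stages) {
    stage("variants", {
      if (is.null(cluster_table)) stopf("variants stage requires clusters")
      if ("simulate" %in% config$stages) {
        vsim <- simulate_variants(do.call(variant_sim_spec,
          c(config$variant_sim, list(seed = config$seed + 4L))),
          cluster_table)
        write_variant_sim(vsim, out_dir)
      }
      vout <- run_variants(file.path(out_dir, "variants.vcf"),
                           file.path(out_dir, "genes.gff3"),
                           file.path(out_dir, "cds.fasta"),
                           cluster_table,
                           min_gq = config$min_gq,
                           het_range = config$het_range,
                           qd_min = config$qd_min, fs_max = config$fs_max,
                           mq_min = config$mq_min,
                           rprs_min = config$rprs_min,
                           dir = file.path(out_dir, "variants"))
      summary$stages$variants <- list(
        n_records = nrow(vout$variant_set$fix),
        n_pass = sum(vout$filters$pass),
        effect_counts = as.list(vout$effect_counts),
        concordance = list(matched = vout$concordance$matched,
                           total = vout$concordance$total,
                           percent = vout$concordance$percent))
    })
  }

  if ("enrich" %in% config$stages) {
    stage("enrich", {
      if (is.null(cluster_table)) stopf("enrich stage requires clusters")
      background <- rownames(cd$counts)
      if ("simulate" %in% config$stages) {
        target_sets <- split(cluster_table$gene_id, cluster_table$cluster)
        ann <- simulate_annotations(background, target_sets,
          n_null_terms = config$annotation_sim$n_null_terms,
          n_planted_terms = config$annotation_sim$n_planted_terms,
          bg_rate = config$annotation_sim$bg_rate,
          enrich_rate = config$annotation_sim$enrich_rate,
          seed = config$seed + 5L)
        write_annotations(ann$annotations, out_dir)
        utils::write.table(ann$truth,
                           file.path(out_dir, "truth_terms.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      annotations <- utils::read.delim(
        file.path(out_dir, "go_annotations.tsv"), stringsAsFactors = FALSE)
      enr <- sea_enrich(degs$all, background, annotations)
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$stages$enrich <- list(
        n_terms_tested = nrow(enr),
        n_enriched = sum(enr$fdr < config$enrich_fdr))
    })
  }

  summary$wall_clock_s <- round(
    as.numeric(difftime(Sys.time(), t_start, units = "secs")), 2)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
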