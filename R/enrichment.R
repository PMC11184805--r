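#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`:
#' the chance that a random query of size `n` from a background of `N`
#' genes, `K` of which carry the term, contains `k` or more carriers.
#' Vectorized over all arguments.
#'
#' @param k observed carriers in the query.
#' @param K carriers in the background.
#' @param n query size.
#' @param N background size.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
hypergeom_overrep_p <- function(k, K, n, N) {
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Singular enrichment analysis by the hypergeometric test
#'
#' For each GO term annotated to at least one background gene, tests
#' over-representation of the term among the query genes: with `N`
#' background genes, `K` of them carrying the term, and a query of size
#' `n` containing `k` carriers, the p-value is the hypergeometric upper
#' tail `P[X >= k]`. P-values are BH-adjusted within each ontology (BP,
#' MF, CC) by default.
#'
#' @param query character vector of query gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background (universe) gene ids.
#' @param annotations `data.frame` with columns `gene_id`, `term_id`,
#'   `ontology`, and optionally `term_name`. Annotations of genes outside
#'   the background are ignored.
#' @param fdr_scope `"ontology"` (BH within each ontology, default) or
#'   `"global"`.
#' @param alternative `"over"` (upper tail, default) or `"two.sided"`
#'   (doubled smaller tail, capped at 1).
#' @return `data.frame` sorted by p-value: `term_id`, `ontology`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @export
sea_enrich <- function(query, background, annotations,
                       fdr_scope = c("ontology", "global"),
                       alternative = c("over", "two.sided")) {
  fdr_scope <- match.arg(fdr_scope)
  alternative <- match.arg(alternative)
  query <- unique(query)
  background <- unique(background)
  missing_q <- setdiff(query, background)
  if (length(missing_q) > 0L)
    stopf("query genes not in background: %s%s",
          paste(utils::head(missing_q, 5L), collapse = ", "),
          if (length(missing_q) > 5L) ", ..." else "")
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, intersect(c("gene_id", "term_id", "ontology",
                                  "term_name"), names(ann))])
  if (nrow(ann) == 0L) stopf("no annotations overlap the background")
  N <- length(background)
  n <- length(query)
  by_term <- split(ann$gene_id, ann$term_id)
  term_ids <- names(by_term)
  K <- lengths(by_term)
  k <- vapply(by_term, function(g) sum(g %in% query), integer(1))
  p_over <- hypergeom_overrep_p(k, K, n, N)
  p <- if (alternative == "over") p_over
       else pmin(1, 2 * pmin(p_over, stats::phyper(k, K, N - K, n)))
  meta <- ann[match(term_ids, ann$term_id), , drop = FALSE]
  out <- data.frame(term_id = term_ids, ontology = meta$ontology,
                    term_name = if ("term_name" %in% names(meta))
                      meta$term_name else NA_character_,
                    k = k, K = unname(K), n = n, N = N, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- if (fdr_scope == "global") stats::p.adjust(out$p, "BH")
             else stats::ave(out$p, out$ontology,
                             FUN = function(x) stats::p.adjust(x, "BH"))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a gene-to-GO annotation table with planted enrichment
#'
#' Null terms annotate every background gene at the baseline rate; each
#' planted term additionally annotates genes of one target set at an
#' elevated rate, making it truly over-represented in that set.
#'
#' @param background character vector of universe gene ids.
#' @param target_sets named list of gene-id vectors (e.g. DE clusters) to
#'   seed enrichment into.
#' @param n_null_terms null terms per ontology.
#' @param n_planted_terms planted terms per target set (cycled over
#'   ontologies).
#' @param bg_rate baseline annotation probability.
#' @param enrich_rate annotation probability inside the target set for
#'   planted terms.
#' @param seed integer seed.
#' @return List: `annotations` (data.frame `gene_id`, `term_id`,
#'   `ontology`, `term_name`) and `truth` (data.frame `term_id`,
#'   `ontology`, `planted`, `target_set`).
#' @export
simulate_annotations <- function(background, target_sets,
                                 n_null_terms = 30, n_planted_terms = 2,
                                 bg_rate = 0.02, enrich_rate = 0.5,
                                 seed = 1L) {
  check_fraction(bg_rate, "bg_rate")
  check_fraction(enrich_rate, "enrich_rate")
  with_seed(seed, {
    ontologies <- c("BP", "MF", "CC")
    rows <- list()
    truth <- list()
    tid <- 0L
    new_term <- function() {
      tid <<- tid + 1L
      sprintf("GO:%07d", tid)
    }
    for (ont in ontologies) {
      for (j in seq_len(n_null_terms)) {
        term <- new_term()
        hit <- background[stats::runif(length(background)) < bg_rate]
        if (length(hit) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = hit, term_id = term, ontology = ont,
          term_name = paste0("null process ", term),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          term_id = term, ontology = ont, planted = FALSE,
          target_set = NA_character_, stringsAsFactors = FALSE)
      }
    }
    set_names <- names(target_sets)
    for (si in seq_along(target_sets)) {
      for (j in seq_len(n_planted_terms)) {
        ont <- ontologies[(si + j - 2L) %% 3L + 1L]
        term <- new_term()
        inset <- target_sets[[si]]
        hit <- unique(c(
          inset[stats::runif(length(inset)) < enrich_rate],
          background[stats::runif(length(background)) < bg_rate]))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = hit, term_id = term, ontology = ont,
          term_name = paste0("planted process ", term),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          term_id = term, ontology = ont, planted = TRUE,
          target_set = set_names[si], stringsAsFactors = FALSE)
      }
    }
    list(annotations = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Write a gene-to-GO annotation table
#'
#' @param annotations data.frame from [simulate_annotations()].
#' @param dir output directory; writes `go_annotations.tsv`.
#' @return Invisibly, the path written.
#' @export
write_annotations <- function(annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "go_annotations.tsv")
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
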