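EFFECT_CLASSES <- c("MODIFIER", "LOW", "MODERATE", "HIGH")  # severity order

#' Read biallelic SNPs from a VCF 4.2 file
#'
#' Parses the site annotations `QD`, `FS`, `MQ`, `ReadPosRankSum` and the
#' per-sample `GT`, `GQ`, `AD` fields. Non-SNP records (indels, multiallelic
#' sites) are skipped with a counter.
#'
#' @param path VCF file (plain or bgzipped).
#' @return Object of class `variant_set`: `fix` (data.frame `chrom`, `pos`,
#'   `id`, `ref`, `alt`, `QD`, `FS`, `MQ`, `ReadPosRankSum`), matrices `gq`,
#'   `ad_ref`, `ad_alt`, `gt` (records by samples), `samples`, and
#'   `n_skipped`.
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(!keep)
  info <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))[keep]
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gq <- suppressWarnings(apply(
    vcfR::extract.gt(v, element = "GQ")[keep, , drop = FALSE], 2L,
    as.numeric))
  ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
  ad_ref <- apply(ad, 2L, function(x)
    suppressWarnings(as.numeric(sub(",.*$", "", x))))
  ad_alt <- apply(ad, 2L, function(x)
    suppressWarnings(as.numeric(sub("^[^,]*,", "", x))))
  for (m in c("gq", "ad_ref", "ad_alt"))
    if (is.null(dim(get(m)))) assign(m, matrix(get(m), nrow = sum(keep)))
  structure(list(
    fix = data.frame(chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     id = fix$ID[keep], ref = fix$REF[keep],
                     alt = fix$ALT[keep],
                     QD = info("QD"), FS = info("FS"), MQ = info("MQ"),
                     ReadPosRankSum = info("ReadPosRankSum"),
                     stringsAsFactors = FALSE),
    gt = gt, gq = gq, ad_ref = ad_ref, ad_alt = ad_alt,
    samples = colnames(gt), n_skipped = n_skipped),
    class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d SNPs x %d samples (%d non-SNP records skipped)\n",
              nrow(x$fix), length(x$samples), x$n_skipped))
  invisible(x)
}

#' Hard-filter variants on site annotations
#'
#' Applies the GATK-style exclusion thresholds: a record is removed when
#' `QD < qd_min`, `FS > fs_max`, `MQ < mq_min` or
#' `ReadPosRankSum < rprs_min`. A missing annotation does not fail its
#' clause.
#'
#' @param vs a `variant_set` from [read_vcf_variants()].
#' @param qd_min,fs_max,mq_min,rprs_min clause thresholds.
#' @return `data.frame` with logical `pass` and a `reasons` string (failed
#'   clauses, `;`-separated, empty when passing).
#' @export
hard_filter <- function(vs, qd_min = 2, fs_max = 60, mq_min = 40,
                        rprs_min = -8) {
  f <- vs$fix
  fail <- cbind(QD = !is.na(f$QD) & f$QD < qd_min,
                FS = !is.na(f$FS) & f$FS > fs_max,
                MQ = !is.na(f$MQ) & f$MQ < mq_min,
                ReadPosRankSum = !is.na(f$ReadPosRankSum) &
                  f$ReadPosRankSum < rprs_min)
  reasons <- apply(fail, 1L, function(r)
    paste(colnames(fail)[r], collapse = ";"))
  data.frame(pass = rowSums(fail) == 0L, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Genotype-quality filter across all samples
#'
#' @param vs a `variant_set`.
#' @param min_gq records pass when every sample's GQ is strictly greater
#'   than this.
#' @return Logical vector per record; a missing GQ fails the record.
#' @export
gq_filter <- function(vs, min_gq = 15) {
  ok <- !is.na(vs$gq) & vs$gq > min_gq
  rowSums(ok) == ncol(vs$gq)
}

#' Zygosity from allelic balance
#'
#' Allelic balance `AB = alt / (ref + alt)` read depth. `AB` within
#' `het_range` (inclusive) is heterozygous, above is homozygous alternate,
#' below homozygous reference; zero depth or missing AD is a no-call.
#'
#' @param vs a `variant_set`.
#' @param het_range inclusive AB interval called heterozygous.
#' @return List of record-by-sample matrices: `ab`, `zygosity` (character:
#'   `HOM_REF`, `HET`, `HOM_ALT`, `NO_CALL`), `carries_alt` (logical; HET or
#'   HOM_ALT).
#' @export
zygosity_from_ab <- function(vs, het_range = c(0.2, 0.8)) {
  depth <- vs$ad_ref + vs$ad_alt
  ab <- ifelse(depth > 0, vs$ad_alt / depth, NA_real_)
  zyg <- ifelse(is.na(ab), "NO_CALL",
         ifelse(ab >= het_range[1L] & ab <= het_range[2L], "HET",
         ifelse(ab > het_range[2L], "HOM_ALT", "HOM_REF")))
  zyg[is.na(vs$gt)] <- "NO_CALL"
  carries <- zyg == "HET" | zyg == "HOM_ALT"
  list(ab = ab, zygosity = zyg, carries_alt = carries)
}

#' Per-group replicate-consistent alternate-allele carriage
#'
#' A SNP is consistent in a group when every replicate of the group carries
#' the alternate allele (heterozygous or homozygous alternate); a no-call
#' breaks consistency.
#'
#' @param carries_alt record-by-sample logical matrix from
#'   [zygosity_from_ab()].
#' @param sample_groups group label per sample column.
#' @return Record-by-group logical matrix (columns `MH`, `MA`, `F4`).
#' @export
group_consistent <- function(carries_alt, sample_groups) {
  check_group(sample_groups)
  sapply(GROUPS, function(g) {
    m <- carries_alt[, sample_groups == g, drop = FALSE]
    rowSums(m) == ncol(m)
  })
}

#' Load gene models from GFF3 and CDS sequences from FASTA
#'
#' Expects `gene`, `mRNA`, `CDS`, `five_prime_UTR` and `three_prime_UTR`
#' features with `ID`/`Parent` attributes (one transcript per gene). CDS
#' sequences are matched to genes by FASTA name.
#'
#' @param gff_path GFF3 file.
#' @param cds_fasta_path FASTA of coding-strand CDS sequences named by gene
#'   id (optional; required for [classify_effect()]).
#' @return Object of class `gene_models`: `features` (data.frame `gene_id`,
#'   `chrom`, `strand`, `region`, `start`, `end`), `cds` (named character
#'   vector of CDS sequences or `NULL`).
#' @export
load_gene_models <- function(gff_path, cds_fasta_path = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  mrna <- type == "mRNA"
  tx2gene <- stats::setNames(
    vapply(gr$Parent[mrna], function(p) p[1L], character(1)),
    gr$ID[mrna])
  keep <- type %in% c("CDS", "five_prime_UTR", "three_prime_UTR")
  feat <- gr[keep]
  parent <- vapply(feat$Parent, function(p)
    if (length(p)) p[1L] else NA_character_, character(1))
  gene_id <- unname(tx2gene[parent])
  gene_id[is.na(gene_id)] <- parent[is.na(gene_id)]
  features <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(feat)),
    strand = as.character(GenomicRanges::strand(feat)),
    region = c(CDS = "CDS", five_prime_UTR = "UTR5",
               three_prime_UTR = "UTR3")[type[keep]],
    start = GenomicRanges::start(feat), end = GenomicRanges::end(feat),
    stringsAsFactors = FALSE)
  if (any(features$start > features$end))
    stopf("malformed gene model: start > end")
  cds_len <- tapply(features$end - features$start + 1L,
                    ifelse(features$region == "CDS", features$gene_id, NA),
                    sum)
  bad <- names(cds_len)[!is.na(cds_len) & cds_len %% 3L != 0L]
  if (length(bad) > 0L)
    warning(sprintf("%d gene(s) with CDS length not divisible by 3 flagged",
                    length(bad)))
  cds <- NULL
  if (!is.null(cds_fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(cds_fasta_path)
    cds <- stats::setNames(as.character(seqs), names(seqs))
  }
  structure(list(features = features, cds = cds,
                 frame_flagged = if (length(bad)) bad else character(0)),
            class = "gene_models")
}

#' Assign variants to genes and gene regions
#'
#' Interval containment on 1-based closed coordinates; a variant may hit
#' several genes.
#'
#' @param vs a `variant_set`.
#' @param models a `gene_models` object.
#' @return `data.frame` with `record` (row index into `vs`), `gene_id`,
#'   `region` (`CDS`, `UTR5`, `UTR3`); records hitting nothing are absent
#'   (query [setdiff()] for `NONE`).
#' @export
assign_to_gene <- function(vs, models) {
  f <- models$features
  q <- GenomicRanges::GRanges(vs$fix$chrom,
                              IRanges::IRanges(vs$fix$pos, vs$fix$pos))
  s <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end))
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  data.frame(record = S4Vectors::queryHits(hits),
             gene_id = f$gene_id[S4Vectors::subjectHits(hits)],
             region = f$region[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the coding effect of SNPs
#'
#' UTR hits are `MODIFIER`. For CDS hits the affected codon is extracted
#' from the gene's coding-strand CDS sequence (reverse-complementing the
#' alleles for minus-strand genes) and the reference and alternate codons
#' are translated with the standard genetic code: a synonymous change is
#' `LOW`, a non-synonymous non-stop change is `MODERATE`, and a change that
#' gains or removes a stop codon is `HIGH`. When a variant hits several
#' genes its highest-severity class is reported.
#'
#' @param vs a `variant_set`.
#' @param hits gene hits from [assign_to_gene()].
#' @param models a `gene_models` object carrying CDS sequences.
#' @return `data.frame` per (record, gene) hit: `record`, `gene_id`,
#'   `region`, `class`, plus an attribute `per_record` (named by record
#'   index: maximum-severity class per variant).
#' @export
classify_effect <- function(vs, hits, models) {
  if (is.null(models$cds)) stopf("gene_models lacks CDS sequences")
  f <- models$features
  cls <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (hits$region[i] != "CDS") { cls[i] <- "MODIFIER"; next }
    gid <- hits$gene_id[i]
    if (gid %in% models$frame_flagged || is.na(models$cds[gid])) {
      cls[i] <- NA_character_
      next
    }
    blocks <- f[f$gene_id == gid & f$region == "CDS", , drop = FALSE]
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    strand <- blocks$strand[1L]
    pos <- vs$fix$pos[hits$record[i]]
    lens <- blocks$end - blocks$start + 1L
    bi <- which(pos >= blocks$start & pos <= blocks$end)
    if (length(bi) != 1L) { cls[i] <- NA_character_; next }
    if (strand == "+") {
      cds_pos <- sum(lens[seq_len(bi - 1L)]) + (pos - blocks$start[bi] + 1L)
      ref_b <- vs$fix$ref[hits$record[i]]
      alt_b <- vs$fix$alt[hits$record[i]]
    } else {
      rev_prior <- if (bi < nrow(blocks))
        sum(lens[(bi + 1L):nrow(blocks)]) else 0L
      cds_pos <- rev_prior + (blocks$end[bi] - pos + 1L)
      ref_b <- revcomp_base(vs$fix$ref[hits$record[i]])
      alt_b <- revcomp_base(vs$fix$alt[hits$record[i]])
    }
    seqc <- models$cds[[gid]]
    codon_i <- (cds_pos - 1L) %/% 3L
    within <- (cds_pos - 1L) %% 3L + 1L
    ref_codon <- substr(seqc, codon_i * 3L + 1L, codon_i * 3L + 3L)
    if (substr(ref_codon, within, within) != ref_b) {
      warning(sprintf("REF allele mismatch vs CDS at %s:%d (gene %s)",
                      vs$fix$chrom[hits$record[i]], pos, gid))
      cls[i] <- NA_character_
      next
    }
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt_b
    aa_ref <- translate_codon(ref_codon)
    aa_alt <- translate_codon(alt_codon)
    cls[i] <- if (aa_ref == aa_alt) "LOW"
              else if (xor(aa_ref == "*", aa_alt == "*")) "HIGH"
              else "MODERATE"
  }
  out <- data.frame(record = hits$record, gene_id = hits$gene_id,
                    region = hits$region, class = cls,
                    stringsAsFactors = FALSE)
  ok <- !is.na(cls)
  per_record <- vapply(split(cls[ok], out$record[ok]), function(v)
    EFFECT_CLASSES[max(match(v, EFFECT_CLASSES))], character(1))
  attr(out, "per_record") <- per_record
  out
}

#' Overall matched-SNP percentage
#'
#' @param matched,total matched and total SNP counts.
#' @return `100 * matched / total` (unrounded; reports round to integer).
#' @export
concordance_percent <- function(matched, total) {
  if (total <= 0) stopf("total must be positive")
  100 * matched / total
}

#' SNP-expression concordance
#'
#' Checks whether each SNP's across-group presence pattern is consistent
#' with its gene's expression cluster category. For a cluster specific to
#' parent P (over- or under-expressed in P vs the hybrid), a SNP matches
#' when it is replicate-consistent in P only, or in the other parent and
#' the hybrid but not P. For a hybrid-specific cluster (both parents
#' shifted together), a SNP matches when the hybrid's consistency status
#' differs from the parents' shared status. SNPs in unclustered genes are
#' excluded.
#'
#' @param snp_genes `data.frame` with one row per SNP: `record` (row in the
#'   consistency matrix), `gene_id`, `category`
#'   (`UNDER_ONE_PARENT`/`OVER_ONE_PARENT`/`UNDER_BOTH_PARENTS`/
#'   `OVER_BOTH_PARENTS`), `parent` (for one-parent categories), and
#'   optionally `cluster`.
#' @param consistency record-by-group logical matrix from
#'   [group_consistent()].
#' @param match_rule optional replacement rule: `function(category, parent,
#'   c_mh, c_ma, c_f4)` returning logical.
#' @return Object of class `concordance_report`: `per_cluster` data.frame
#'   (`cluster`, `matched`, `unmatched`, `total`), `matched`, `total`,
#'   `percent` (rounded to integer), `percent_raw`, `n_excluded`.
#' @export
concordance <- function(snp_genes, consistency, match_rule = NULL) {
  one_parent <- c("UNDER_ONE_PARENT", "OVER_ONE_PARENT")
  both <- c("UNDER_BOTH_PARENTS", "OVER_BOTH_PARENTS")
  usable <- snp_genes$category %in% c(one_parent, both)
  n_excluded <- sum(!usable)
  sg <- snp_genes[usable, , drop = FALSE]
  c_mh <- consistency[sg$record, "MH"]
  c_ma <- consistency[sg$record, "MA"]
  c_f4 <- consistency[sg$record, "F4"]
  if (is.null(match_rule)) {
    is_p_mh <- sg$category %in% one_parent & sg$parent == "MH"
    is_p_ma <- sg$category %in% one_parent & sg$parent == "MA"
    is_f4 <- sg$category %in% both
    matched <- rep(FALSE, nrow(sg))
    matched[is_p_mh] <- (c_mh & !c_ma & !c_f4)[is_p_mh] |
                        (!c_mh & c_ma & c_f4)[is_p_mh]
    matched[is_p_ma] <- (c_ma & !c_mh & !c_f4)[is_p_ma] |
                        (!c_ma & c_mh & c_f4)[is_p_ma]
    matched[is_f4] <- (c_mh == c_ma & c_f4 != c_mh)[is_f4]
  } else {
    matched <- mapply(match_rule, sg$category, sg$parent, c_mh, c_ma, c_f4)
  }
  key <- if ("cluster" %in% names(sg)) sg$cluster else sg$category
  per_cluster <- do.call(rbind, lapply(sort(unique(key)), function(k) {
    idx <- key == k
    data.frame(cluster = k, matched = sum(matched[idx]),
               unmatched = sum(!matched[idx]), total = sum(idx))
  }))
  m <- sum(matched); tot <- nrow(sg)
  structure(list(per_cluster = per_cluster, matched = m, total = tot,
                 percent = round(concordance_percent(m, tot)),
                 percent_raw = concordance_percent(m, tot),
                 n_excluded = n_excluded),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("SNP-expression concordance: %d / %d matched (%d%%)\n",
              x$matched, x$total, x$percent))
  if (x$n_excluded > 0L)
    cat(sprintf("  (%d SNPs in unclustered genes excluded)\n", x$n_excluded))
  print(x$per_cluster, row.names = FALSE)
  invisible(x)
}

#' Run the full variant stage
#'
#' Hard-filters, GQ-filters, calls zygosity, assigns SNPs to genes,
#' classifies effects and computes concordance against cluster categories.
#'
#' @param vcf_path,gff_path,cds_fasta_path input files.
#' @param cluster_table `data.frame` with `gene_id`, `cluster`, `category`,
#'   `parent` for clustered genes.
#' @param min_gq,het_range,qd_min,fs_max,mq_min,rprs_min filter settings.
#' @param dir optional output directory (`effects.tsv`,
#'   `concordance.json`).
#' @return List: `variant_set`, `filters` (per-record pass table),
#'   `effects`, `effect_counts`, `concordance`.
#' @export
run_variants <- function(vcf_path, gff_path, cds_fasta_path, cluster_table,
                         min_gq = 15, het_range = c(0.2, 0.8), qd_min = 2,
                         fs_max = 60, mq_min = 40, rprs_min = -8,
                         dir = NULL) {
  vs <- read_vcf_variants(vcf_path)
  hf <- hard_filter(vs, qd_min, fs_max, mq_min, rprs_min)
  gqp <- gq_filter(vs, min_gq)
  pass <- hf$pass & gqp
  models <- load_gene_models(gff_path, cds_fasta_path)
  keep_vs <- subset_variant_set(vs, which(pass))
  zyg <- zygosity_from_ab(keep_vs, het_range)
  groups <- sub("_[0-9]+$", "", keep_vs$samples)
  cons <- group_consistent(zyg$carries_alt, groups)
  hits <- assign_to_gene(keep_vs, models)
  eff <- classify_effect(keep_vs, hits, models)
  per_record <- attr(eff, "per_record")
  effect_counts <- table(factor(per_record, levels = EFFECT_CLASSES))
  snp_genes <- merge(hits, cluster_table, by = "gene_id")
  snp_genes <- snp_genes[!duplicated(snp_genes[c("record", "gene_id")]), ]
  conc <- concordance(snp_genes, cons)
  out <- list(variant_set = vs,
              filters = data.frame(pass_hard = hf$pass, reasons = hf$reasons,
                                   pass_gq = gqp, pass = pass),
              effects = eff,
              effect_counts = effect_counts,
              concordance = conc)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(eff, file.path(dir, "effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(matched = conc$matched, total = conc$total,
           percent = conc$percent, per_cluster = conc$per_cluster),
      file.path(dir, "concordance.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

subset_variant_set <- function(vs, idx) {
  structure(list(fix = vs$fix[idx, , drop = FALSE],
                 gt = vs$gt[idx, , drop = FALSE],
                 gq = vs$gq[idx, , drop = FALSE],
                 ad_ref = vs$ad_ref[idx, , drop = FALSE],
                 ad_alt = vs$ad_alt[idx, , drop = FALSE],
                 samples = vs$samples, n_skipped = vs$n_skipped),
            class = "variant_set")
}
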