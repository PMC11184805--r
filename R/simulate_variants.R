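# Codon edit table: for each effect class, (reference codon, position
# within codon, alternate base) triples realising the class under the
# standard genetic code. The generator writes the reference codon into the
# CDS and emits the substitution.
CODON_EDITS <- list(
  LOW = list(c("CTT", 3L, "C"),   # Leu -> Leu
             c("GGA", 3L, "G"),   # Gly -> Gly
             c("TCA", 3L, "T")),  # Ser -> Ser
  MODERATE = list(c("GAA", 1L, "C"),   # Glu -> Gln
                  c("GCT", 1L, "T"),   # Ala -> Ser
                  c("ATC", 1L, "C")),  # Ile -> Leu
  HIGH = list(c("TAC", 3L, "A"),   # Tyr -> stop
              c("CGA", 1L, "T"),   # Arg -> stop
              c("TAT", 3L, "A")))  # Tyr -> stop

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

#' Specification for the variant simulator
#'
#' Plants SNPs in differentially expressed genes: a Bernoulli fraction of
#' SNPs follow the across-group presence pattern their gene's expression
#' cluster implies (concordant), the rest violate it; effect classes are
#' realised by editing codons of the synthetic CDS. A configurable fraction
#' of extra records is planted in the fail region of each hard filter.
#'
#' @param n_genes_with_snps number of clustered genes to receive SNPs.
#' @param snps_per_gene mean SNPs per gene (shifted Poisson, minimum 1).
#' @param concordant_fraction probability a SNP is concordant with its
#'   gene's expression pattern.
#' @param effect_class_props named proportions over `LOW`, `MODERATE`,
#'   `HIGH`, `MODIFIER`, summing to 1; defaults follow the 642/303/6/452
#'   split over 1403 SNPs.
#' @param fail_fraction extra filter-failing records, as a fraction of the
#'   passing records.
#' @param replicates_per_group samples per group.
#' @param seed integer seed.
#' @return Object of class `variant_sim_spec`.
#' @export
variant_sim_spec <- function(n_genes_with_snps = 477, snps_per_gene = 2.94,
                             concordant_fraction = 0.73,
                             effect_class_props = c(LOW = 642, MODERATE = 303,
                                                    HIGH = 6, MODIFIER = 452) /
                               1403,
                             fail_fraction = 0.1,
                             replicates_per_group = 3, seed = 1L) {
  check_fraction(concordant_fraction, "concordant_fraction")
  check_fraction(fail_fraction, "fail_fraction")
  if (!setequal(names(effect_class_props),
                c("LOW", "MODERATE", "HIGH", "MODIFIER")))
    stopf("effect_class_props must name LOW, MODERATE, HIGH, MODIFIER")
  if (abs(sum(effect_class_props) - 1) > 1e-9)
    stopf("effect_class_props must sum to 1 (tolerance 1e-9)")
  if (snps_per_gene < 1) stopf("snps_per_gene must be >= 1")
  structure(list(
    n_genes_with_snps = check_count(n_genes_with_snps, "n_genes_with_snps",
                                    positive = TRUE),
    snps_per_gene = snps_per_gene,
    concordant_fraction = concordant_fraction,
    effect_class_props = effect_class_props[c("LOW", "MODERATE", "HIGH",
                                              "MODIFIER")],
    fail_fraction = fail_fraction,
    replicates_per_group = check_count(replicates_per_group,
                                       "replicates_per_group",
                                       positive = TRUE),
    seed = as.integer(seed)), class = "variant_sim_spec")
}

# group presence patterns (which groups are replicate-consistent for the
# alternate allele) compatible / incompatible with each cluster category
concordant_patterns <- function(category, parent) {
  if (category %in% c("UNDER_ONE_PARENT", "OVER_ONE_PARENT")) {
    other <- setdiff(c("MH", "MA"), parent)
    list(parent, c(other, "F4"))
  } else {
    list("F4", c("MH", "MA"))
  }
}

discordant_patterns <- function(category, parent) {
  all_p <- list("MH", "MA", "F4", c("MH", "MA"), c("MH", "F4"),
                c("MA", "F4"), c("MH", "MA", "F4"))
  conc <- concordant_patterns(category, parent)
  Filter(function(p) !any(vapply(conc, identical, logical(1), p)), all_p)
}

#' Simulate a VCF / GFF3 / CDS-FASTA trio with planted variant truth
#'
#' Generates one synthetic gene model per selected gene (60 bp 5'UTR,
#' 300 bp single-block CDS, 60 bp 3'UTR, random strand), plants SNPs with
#' prescribed effect classes by authoring the affected codons, assigns each
#' SNP an across-group genotype pattern that is concordant or discordant
#' with the gene's expression category, and emits VCF 4.2 text with
#' QD/FS/MQ/ReadPosRankSum site annotations and GT:GQ:AD sample fields.
#'
#' @param spec a [variant_sim_spec()].
#' @param cluster_table `data.frame` with `gene_id`, `cluster`, `category`,
#'   `parent` for clustered (differentially expressed) genes, e.g. from
#'   [simulate_counts()] truth or the clustering stage.
#' @return List: `vcf`, `gff3`, `fasta` (character vectors of file lines)
#'   and `truth` (data.frame per record: `id`, `chrom`, `pos`, `gene_id`,
#'   `region`, `class`, `concordant`, `pattern`, `pass_hard`, `pass_gq`,
#'   `fail_reason`).
#' @export
simulate_variants <- function(spec, cluster_table) {
  stopifnot(inherits(spec, "variant_sim_spec"))
  need <- c("gene_id", "cluster", "category", "parent")
  if (!all(need %in% names(cluster_table)))
    stopf("cluster_table needs columns %s", paste(need, collapse = ", "))
  ct <- cluster_table[cluster_table$category %in%
                        c("UNDER_ONE_PARENT", "OVER_ONE_PARENT",
                          "UNDER_BOTH_PARENTS", "OVER_BOTH_PARENTS"), ,
                      drop = FALSE]
  if (nrow(ct) < spec$n_genes_with_snps)
    stopf("cluster_table has %d usable genes; %d requested", nrow(ct),
          spec$n_genes_with_snps)
  with_seed(spec$seed, {
    genes <- ct[sample.int(nrow(ct), spec$n_genes_with_snps), , drop = FALSE]
    ng <- nrow(genes)
    utr_len <- 60L; cds_len <- 300L
    gene_span <- utr_len * 2L + cds_len
    per_chrom <- 100L
    chroms <- paste0("chr", (seq_len(ng) - 1L) %/% per_chrom + 1L, "A")
    offset <- ((seq_len(ng) - 1L) %% per_chrom) * 10000L + 1000L
    strand <- sample(c("+", "-"), ng, replace = TRUE)

    n_codons <- cds_len %/% 3L
    cds_seq <- vapply(seq_len(ng), function(i)
      paste0("ATG",
             paste(sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
                   collapse = ""),
             "TAA"), character(1))

    r <- spec$replicates_per_group
    samples <- paste0(rep(GROUPS, each = r), "_", seq_len(r))
    sample_groups <- rep(GROUPS, each = r)

    n_snps <- 1L + stats::rpois(ng, max(spec$snps_per_gene - 1, 0))
    rec <- list(); ri <- 0L

    genotype_fields <- function(consistent_groups) {
      vapply(sample_groups, function(g) {
        gq <- sample(60:99, 1L)
        if (g %in% consistent_groups) {
          if (stats::runif(1) < 0.6) {          # heterozygous
            ad <- c(sample(8:12, 1L), sample(8:12, 1L))
            gt <- "0/1"
          } else {                               # homozygous alternate
            ad <- c(0L, sample(15:25, 1L))
            gt <- "1/1"
          }
        } else {
          ad <- c(sample(15:25, 1L), 0L)
          gt <- "0/0"
        }
        sprintf("%s:%d:%d,%d", gt, gq, ad[1L], ad[2L])
      }, character(1))
    }

    pass_info <- function() {
      sprintf("QD=%.2f;FS=%.2f;MQ=%.2f;ReadPosRankSum=%.2f",
              stats::runif(1, 10, 35), stats::runif(1, 0, 20),
              stats::runif(1, 50, 60), stats::runif(1, -3, 3))
    }

    for (i in seq_len(ng)) {
      used_codons <- integer(0)
      used_utr <- list(UTR5 = integer(0), UTR3 = integer(0))
      cls_i <- sample(names(spec$effect_class_props), n_snps[i],
                      replace = TRUE, prob = spec$effect_class_props)
      for (s in seq_len(n_snps[i])) {
        cls <- cls_i[s]
        if (cls == "MODIFIER") {
          region <- sample(c("UTR5", "UTR3"), 1L)
          upos <- sample(setdiff(seq_len(utr_len), used_utr[[region]]), 1L)
          used_utr[[region]] <- c(used_utr[[region]], upos)
          # genomic placement of the UTRs depends on strand
          five_first <- strand[i] == "+"
          lo <- if ((region == "UTR5") == five_first) offset[i]
                else offset[i] + utr_len + cds_len
          pos <- lo + upos - 1L
          ref <- sample(c("A", "C", "G", "T"), 1L)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        } else {
          region <- "CDS"
          free <- setdiff(2:(n_codons - 1L), used_codons)
          ci <- if (length(free) == 1L) free else sample(free, 1L)
          used_codons <- c(used_codons, ci)
          edit <- CODON_EDITS[[cls]][[sample.int(3L, 1L)]]
          substr(cds_seq[i], (ci - 1L) * 3L + 1L, ci * 3L) <- edit[1L]
          cds_pos <- (ci - 1L) * 3L + as.integer(edit[2L])
          ref_cds <- substr(edit[1L], as.integer(edit[2L]),
                            as.integer(edit[2L]))
          alt_cds <- edit[3L]
          if (strand[i] == "+") {
            pos <- offset[i] + utr_len + cds_pos - 1L
            ref <- ref_cds; alt <- alt_cds
          } else {
            pos <- offset[i] + utr_len + cds_len - cds_pos
            ref <- revcomp_base(ref_cds); alt <- revcomp_base(alt_cds)
          }
        }
        concordant <- stats::runif(1) < spec$concordant_fraction
        pats <- if (concordant)
          concordant_patterns(genes$category[i], genes$parent[i])
        else discordant_patterns(genes$category[i], genes$parent[i])
        pattern <- pats[[sample.int(length(pats), 1L)]]
        ri <- ri + 1L
        rec[[ri]] <- list(chrom = chroms[i], pos = pos,
                          id = sprintf("snp%05d", ri), ref = ref, alt = alt,
                          info = pass_info(),
                          gt = genotype_fields(pattern),
                          gene_id = genes$gene_id[i], region = region,
                          class = cls, concordant = concordant,
                          pattern = paste(pattern, collapse = "+"),
                          pass_hard = TRUE, pass_gq = TRUE,
                          fail_reason = "")
      }
    }

    # planted filter-failing records, placed in the UTRs of random genes
    n_fail <- round(spec$fail_fraction * ri)
    fail_types <- c("QD", "FS", "MQ", "ReadPosRankSum", "GQ")
    for (j in seq_len(n_fail)) {
      i <- sample.int(ng, 1L)
      pos <- offset[i] + utr_len + cds_len + utr_len + 100L + j  # intergenic-ish
      type <- fail_types[(j - 1L) %% length(fail_types) + 1L]
      info <- c(QD = stats::runif(1, 10, 35), FS = stats::runif(1, 0, 20),
                MQ = stats::runif(1, 50, 60),
                ReadPosRankSum = stats::runif(1, -3, 3))
      if (type == "QD") info["QD"] <- stats::runif(1, 0, 1.9)
      if (type == "FS") info["FS"] <- stats::runif(1, 61, 120)
      if (type == "MQ") info["MQ"] <- stats::runif(1, 10, 39)
      if (type == "ReadPosRankSum")
        info["ReadPosRankSum"] <- stats::runif(1, -12, -8.1)
      gt <- genotype_fields(sample(list("MH", "F4", c("MH", "MA", "F4")),
                                   1L)[[1L]])
      if (type == "GQ") {
        k <- sample.int(length(gt), 1L)
        gt[k] <- sub(":[0-9]+:", sprintf(":%d:", sample(0:15, 1L)), gt[k])
      }
      ri <- ri + 1L
      rec[[ri]] <- list(chrom = chroms[i], pos = pos,
                        id = sprintf("snp%05d", ri),
                        ref = "A", alt = "G",
                        info = sprintf(
                          "QD=%.2f;FS=%.2f;MQ=%.2f;ReadPosRankSum=%.2f",
                          info["QD"], info["FS"], info["MQ"],
                          info["ReadPosRankSum"]),
                        gt = gt, gene_id = NA_character_, region = "NONE",
                        class = NA_character_, concordant = NA,
                        pattern = "", pass_hard = type %in% "GQ",
                        pass_gq = type != "GQ",
                        fail_reason = type)
    }

    truth <- do.call(rbind, lapply(rec, function(x)
      data.frame(id = x$id, chrom = x$chrom, pos = x$pos,
                 gene_id = x$gene_id, region = x$region, class = x$class,
                 concordant = x$concordant, pattern = x$pattern,
                 pass_hard = x$pass_hard, pass_gq = x$pass_gq,
                 fail_reason = x$fail_reason, stringsAsFactors = FALSE)))
    ord <- order(truth$chrom, truth$pos)
    truth <- truth[ord, , drop = FALSE]
    rec <- rec[ord]

    vcf <- c("##fileformat=VCFv4.2",
             "##source=hybridomics-simulator",
             sprintf("##contig=<ID=%s>", unique(chroms)),
             "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
             "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
             "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
             "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             vapply(rec, function(x)
               paste(c(x$chrom, x$pos, x$id, x$ref, x$alt, "100", "PASS",
                       x$info, "GT:GQ:AD", x$gt), collapse = "\t"),
               character(1)))

    gff3 <- c("##gff-version 3")
    for (i in seq_len(ng)) {
      g0 <- offset[i]; g1 <- offset[i] + gene_span - 1L
      cds0 <- g0 + utr_len; cds1 <- cds0 + cds_len - 1L
      five_first <- strand[i] == "+"
      u5 <- if (five_first) c(g0, g0 + utr_len - 1L) else c(cds1 + 1L, g1)
      u3 <- if (five_first) c(cds1 + 1L, g1) else c(g0, g0 + utr_len - 1L)
      gid <- genes$gene_id[i]; tid <- paste0(gid, ".1")
      row <- function(type, s0, s1, attrs)
        sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t%s\t%s", chroms[i], type, s0,
                s1, strand[i], if (type == "CDS") "0" else ".", attrs)
      gff3 <- c(gff3,
                row("gene", g0, g1, sprintf("ID=%s", gid)),
                row("mRNA", g0, g1, sprintf("ID=%s;Parent=%s", tid, gid)),
                row("five_prime_UTR", u5[1L], u5[2L],
                    sprintf("ID=%s.utr5;Parent=%s", gid, tid)),
                row("CDS", cds0, cds1,
                    sprintf("ID=%s.cds;Parent=%s", gid, tid)),
                row("three_prime_UTR", u3[1L], u3[2L],
                    sprintf("ID=%s.utr3;Parent=%s", gid, tid)))
    }

    fasta <- as.vector(rbind(paste0(">", genes$gene_id), cds_seq))

    list(vcf = vcf, gff3 = gff3, fasta = fasta, truth = truth,
         genes = data.frame(gene_id = genes$gene_id, chrom = chroms,
                            strand = strand, cluster = genes$cluster,
                            category = genes$category,
                            parent = genes$parent,
                            stringsAsFactors = FALSE))
  })
}

#' Write variant-simulator outputs to disk
#'
#' @param sim result of [simulate_variants()].
#' @param dir output directory; writes `variants.vcf`, `genes.gff3`,
#'   `cds.fasta` and `truth/variants.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_variant_sim <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             gff3 = file.path(dir, "genes.gff3"),
             fasta = file.path(dir, "cds.fasta"),
             truth = file.path(dir, "truth", "variants.tsv"))
  writeLines(sim$vcf, paths["vcf"])
  writeLines(sim$gff3, paths["gff3"])
  writeLines(sim$fasta, paths["fasta"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
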