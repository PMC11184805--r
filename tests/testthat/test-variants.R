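test_that("hard filter applies each exclusion clause", {
  vs <- make_variant_set(make_fix(4, QD = c(1.5, 30, 30, 30),
                                  FS = c(5, 70, 5, 5),
                                  MQ = c(60, 60, 60, 30),
                                  ReadPosRankSum = c(0, 0, -9, 0)),
                         gq = 99, ad_ref = 10, ad_alt = 10)
  hf <- hard_filter(vs)
  expect_equal(hf$pass, c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(hf$reasons, c("QD", "FS", "ReadPosRankSum", "MQ"))
  ok <- make_variant_set(make_fix(1), gq = 99, ad_ref = 10, ad_alt = 10)
  expect_true(hard_filter(ok)$pass)
  # a missing annotation does not fail its clause
  na_fix <- make_fix(1); na_fix$ReadPosRankSum <- NA
  expect_true(hard_filter(make_variant_set(na_fix, 99, 10, 10))$pass)
})

test_that("GQ filter is strict and per-sample", {
  gq_at <- function(v) {
    gq <- matrix(99, 1, 9); gq[1, 5] <- v
    vs <- make_variant_set(make_fix(1), gq = 99, ad_ref = 10, ad_alt = 10)
    vs$gq <- gq
    gq_filter(vs)
  }
  expect_true(gq_at(99))
  expect_false(gq_at(15))   # "higher than 15" is strict
  expect_true(gq_at(16))
  expect_false(gq_at(NA))
})

test_that("allelic balance calls zygosity with inclusive HET bounds", {
  vs <- make_variant_set(make_fix(1), gq = 99,
                         ad_ref = c(5, 0, 8, 10, 2, 0, 10, 4, 1),
                         ad_alt = c(5, 10, 2, 0, 8, 0, 40, 16, 99))
  z <- zygosity_from_ab(vs)
  expect_equal(unname(z$zygosity[1, 1:6]),
               c("HET", "HOM_ALT", "HET", "HOM_REF", "HET", "NO_CALL"))
  expect_equal(unname(z$ab[1, 3]), 0.2)   # boundary inclusive
  expect_equal(unname(z$carries_alt[1, 1:6]),
               c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  # AB just outside the interval
  vs2 <- make_variant_set(make_fix(1), gq = 99, ad_ref = 81, ad_alt = 19)
  expect_equal(unname(zygosity_from_ab(vs2)$zygosity[1, 1]), "HOM_REF")
})

test_that("group consistency needs all replicates to carry the allele", {
  carries <- matrix(FALSE, 3, 9,
                    dimnames = list(NULL, paste0(sample_groups_9, "_",
                                                 rep(1:3, 3))))
  carries[1, 1:3] <- TRUE                 # all MH replicates
  carries[2, c(1, 2)] <- TRUE             # 2 of 3
  cons <- group_consistent(carries, sample_groups_9)
  expect_true(cons[1, "MH"])
  expect_false(cons[2, "MH"])
  expect_false(cons[3, "MH"])             # all HOM_REF
  expect_false(any(cons[, c("MA", "F4")]))
})

test_that("hard and GQ filters compose in either order", {
  ct <- small_cluster_table(20)
  sim <- simulate_variants(variant_sim_spec(n_genes_with_snps = 30,
                                            fail_fraction = 0.4, seed = 6),
                           ct)
  d <- withr::local_tempdir()
  write_variant_sim(sim, d)
  vs <- read_vcf_variants(file.path(d, "variants.vcf"))
  a <- hard_filter(vs)$pass & gq_filter(vs)
  b <- gq_filter(vs) & hard_filter(vs)$pass
  expect_identical(a, b)
})

test_that("variants map to gene regions by 1-based closed containment", {
  d <- withr::local_tempdir()
  gff <- c("##gff-version 3",
           "chr1A\tsim\tgene\t1000\t1419\t.\t+\t.\tID=gA",
           "chr1A\tsim\tmRNA\t1000\t1419\t.\t+\t.\tID=gA.1;Parent=gA",
           "chr1A\tsim\tfive_prime_UTR\t1000\t1059\t.\t+\t.\tID=gA.u5;Parent=gA.1",
           "chr1A\tsim\tCDS\t1060\t1359\t.\t+\t0\tID=gA.c;Parent=gA.1",
           "chr1A\tsim\tthree_prime_UTR\t1360\t1419\t.\t+\t.\tID=gA.u3;Parent=gA.1")
  writeLines(gff, file.path(d, "g.gff3"))
  models <- load_gene_models(file.path(d, "g.gff3"))
  fix <- make_fix(4)
  fix$pos <- c(1060L, 1000L, 1419L, 5000L)
  vs <- make_variant_set(fix, gq = 99, ad_ref = 10, ad_alt = 10)
  hits <- assign_to_gene(vs, models)
  expect_equal(hits$region[hits$record == 1], "CDS")
  expect_equal(hits$region[hits$record == 2], "UTR5")
  expect_equal(hits$region[hits$record == 3], "UTR3")
  expect_false(4 %in% hits$record)        # intergenic -> no hit
})

test_that("codon-level effect classes follow the genetic code", {
  d <- withr::local_tempdir()
  # plus-strand gene with CDS 1060-1068: ATG GAA TAC -> edit codons 2,3
  gff <- c("##gff-version 3",
           "chr1A\tsim\tgene\t1000\t1100\t.\t+\t.\tID=gA",
           "chr1A\tsim\tmRNA\t1000\t1100\t.\t+\t.\tID=gA.1;Parent=gA",
           "chr1A\tsim\tfive_prime_UTR\t1000\t1059\t.\t+\t.\tID=u5;Parent=gA.1",
           "chr1A\tsim\tCDS\t1060\t1068\t.\t+\t0\tID=c;Parent=gA.1",
           "chr1A\tsim\tthree_prime_UTR\t1069\t1100\t.\t+\t.\tID=u3;Parent=gA.1")
  writeLines(gff, file.path(d, "g.gff3"))
  writeLines(c(">gA", "ATGGAATAC"), file.path(d, "c.fa"))
  models <- load_gene_models(file.path(d, "g.gff3"), file.path(d, "c.fa"))
  fix <- make_fix(3)
  # GAA->GAG (Glu->Glu, synonymous), TAC->TAA (Tyr->stop), UTR
  fix$pos <- c(1065L, 1068L, 1070L)
  fix$ref <- c("A", "C", "A"); fix$alt <- c("G", "A", "T")
  vs <- make_variant_set(fix, gq = 99, ad_ref = 10, ad_alt = 10)
  hits <- assign_to_gene(vs, models)
  eff <- classify_effect(vs, hits, models)
  expect_equal(eff$class[eff$record == 1], "LOW")
  expect_equal(eff$class[eff$record == 2], "HIGH")
  expect_equal(eff$class[eff$record == 3], "MODIFIER")
})

test_that("minus-strand codons are reverse-complemented", {
  d <- withr::local_tempdir()
  # minus-strand gene; coding-strand CDS ATG GAA TAC maps to genome
  # positions 1068..1060 (reverse complement on the genome)
  gff <- c("##gff-version 3",
           "chr1A\tsim\tgene\t1000\t1100\t.\t-\t.\tID=gB",
           "chr1A\tsim\tmRNA\t1000\t1100\t.\t-\t.\tID=gB.1;Parent=gB",
           "chr1A\tsim\tthree_prime_UTR\t1000\t1059\t.\t-\t.\tID=u3;Parent=gB.1",
           "chr1A\tsim\tCDS\t1060\t1068\t.\t-\t0\tID=c;Parent=gB.1",
           "chr1A\tsim\tfive_prime_UTR\t1069\t1100\t.\t-\t.\tID=u5;Parent=gB.1")
  writeLines(gff, file.path(d, "g.gff3"))
  writeLines(c(">gB", "ATGGAATAC"), file.path(d, "c.fa"))
  models <- load_gene_models(file.path(d, "g.gff3"), file.path(d, "c.fa"))
  # cds position 6 (third base of GAA) sits at genome pos 1063 as T
  fix <- make_fix(1)
  fix$pos <- 1063L; fix$ref <- "T"; fix$alt <- "C"  # GAA -> GAG coding
  vs <- make_variant_set(fix, gq = 99, ad_ref = 10, ad_alt = 10)
  eff <- classify_effect(vs, assign_to_gene(vs, models), models)
  expect_equal(eff$class, "LOW")
})

test_that("effect classes agree with whole-CDS translation", {
  ct <- small_cluster_table(25)
  sim <- simulate_variants(variant_sim_spec(n_genes_with_snps = 60,
                                            snps_per_gene = 2,
                                            fail_fraction = 0, seed = 12),
                           ct)
  d <- withr::local_tempdir()
  write_variant_sim(sim, d)
  models <- load_gene_models(file.path(d, "genes.gff3"),
                             file.path(d, "cds.fasta"))
  vs <- read_vcf_variants(file.path(d, "variants.vcf"))
  hits <- assign_to_gene(vs, models)
  eff <- classify_effect(vs, hits, models)
  cds_hits <- eff[eff$region == "CDS", ]
  feats <- models$features
  for (i in seq_len(nrow(cds_hits))) {
    gid <- cds_hits$gene_id[i]
    blocks <- feats[feats$gene_id == gid & feats$region == "CDS", ]
    strand <- blocks$strand[1]
    pos <- vs$fix$pos[cds_hits$record[i]]
    cds_pos <- if (strand == "+") pos - blocks$start + 1L
               else blocks$end - pos + 1L
    ref_seq <- models$cds[[gid]]
    alt_base <- if (strand == "+") vs$fix$alt[cds_hits$record[i]]
                else chartr("ACGT", "TGCA", vs$fix$alt[cds_hits$record[i]])
    alt_seq <- ref_seq
    substr(alt_seq, cds_pos, cds_pos) <- alt_base
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(ref_seq)))
    aa_alt <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(alt_seq))))
    expected <- if (aa_ref == aa_alt) "LOW"
                else if (lengths(regmatches(aa_alt, gregexpr("\\*", aa_alt))) !=
                         lengths(regmatches(aa_ref, gregexpr("\\*", aa_ref))))
                  "HIGH" else "MODERATE"
    expect_equal(cds_hits$class[i], expected,
                 label = sprintf("record %d", cds_hits$record[i]))
  }
})

test_that("concordance follows the cluster-category matching rule", {
  sg <- data.frame(record = 1:4, gene_id = "g",
                   category = "OVER_ONE_PARENT", parent = "MH",
                   cluster = 1, stringsAsFactors = FALSE)
  cons <- cbind(MH = c(TRUE, FALSE, TRUE, FALSE),
                MA = c(FALSE, TRUE, TRUE, FALSE),
                F4 = c(FALSE, TRUE, FALSE, TRUE))
  rep <- concordance(sg, cons)
  # MH only -> matched; MA+F4 -> matched; MH+MA -> unmatched; F4 -> unmatched
  expect_equal(rep$matched, 2)
  expect_equal(rep$total, 4)
  expect_equal(rep$per_cluster$matched + rep$per_cluster$unmatched,
               rep$per_cluster$total)
  # hybrid-specific cluster: F4 status must differ from the parents'
  sg2 <- sg; sg2$category <- "UNDER_BOTH_PARENTS"; sg2$parent <- NA
  rep2 <- concordance(sg2, cons)
  expect_equal(rep2$matched, 2)  # F4-only and MH+MA patterns match
  # unclustered genes are excluded
  sg3 <- rbind(sg, data.frame(record = 1, gene_id = "h", category = "NULL",
                              parent = NA, cluster = 0))
  expect_equal(concordance(sg3, cons)$n_excluded, 1)
})

test_that("non-SNP records are skipped on read", {
  ct <- small_cluster_table(10)
  sim <- simulate_variants(variant_sim_spec(n_genes_with_snps = 10,
                                            fail_fraction = 0, seed = 2),
                           ct)
  body_start <- grep("^#CHROM", sim$vcf)
  indel <- strsplit(sim$vcf[body_start + 1], "\t")[[1]]
  indel[2] <- "999"; indel[3] <- "indel1"; indel[4] <- "AT"
  vcf <- append(sim$vcf, paste(indel, collapse = "\t"), body_start)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  vs <- read_vcf_variants(path)
  expect_equal(vs$n_skipped, 1L)
  expect_equal(nrow(vs$fix), length(sim$vcf) - body_start)
})
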