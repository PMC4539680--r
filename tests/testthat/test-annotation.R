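## Longest-transcript selection, coordinate projection on both strands,
## consequence classification and catalogue-level bookkeeping.

test_that("the longest transcript is selected, with a deterministic tie-break", {
  cds_a <- randomCDS(351, seed = 1)   # 350-residue protein
  cds_b <- randomCDS(421, seed = 2)   # 421 codons -> 420 residues
  chrom <- paste0(strrep("A", 10), cds_a, strrep("C", 20), cds_b,
                  strrep("G", 10))
  models <- toyModels(chrom, list(
    list(gene = "G1", tx = "G1.T2", strand = "+",
         exons = cbind(11L, 10L + nchar(cds_a))),
    list(gene = "G1", tx = "G1.T1", strand = "+",
         exons = cbind(10L + nchar(cds_a) + 21L,
                       10L + nchar(cds_a) + 20L + nchar(cds_b)))))
  expect_identical(unname(selectLongestTranscript(models, "G1")), "G1.T1")

  ## single transcript returns itself
  single <- toyModels(chrom, list(list(gene = "G1", tx = "G1.T9",
                                       strand = "+",
                                       exons = cbind(11L, 10L + nchar(cds_a)))))
  expect_identical(unname(selectLongestTranscript(single, "G1")), "G1.T9")

  ## equal protein lengths: lexicographically smaller id wins
  tie <- toyModels(chrom, list(
    list(gene = "G1", tx = "G1.T2", strand = "+",
         exons = cbind(11L, 10L + nchar(cds_a))),
    list(gene = "G1", tx = "G1.T1", strand = "+",
         exons = cbind(11L, 10L + nchar(cds_a)))))
  expect_identical(unname(selectLongestTranscript(tie, "G1")), "G1.T1")

  expect_error(selectLongestTranscript(models, "NOPE"), "NOPE")
})

test_that("plus-strand projection yields the stated CDS coordinates", {
  toy <- toySingleExon("ATGGCTCGATGGTAA", pad = 100L)  # M A R W *
  pr <- projectVariant(vrow(103, "G", "T"), toy$models)
  expect_identical(pr$status, "coding")
  expect_identical(pr$cds_pos, 3L)
  expect_identical(pr$residue_pos, 1L)
  expect_identical(pr$codon_offset, 3L)
})

test_that("minus-strand projection reverse-complements alleles and context", {
  ## plus strand 101..106 is ACGCAT; the minus-strand CDS reads ATGCGT
  set.seed(9)
  pre <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  post <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                collapse = "")
  chrom <- paste0(pre, "ACGCAT", post)
  models <- toyModels(chrom, list(list(gene = "G1", tx = "G1.T1",
                                       strand = "-",
                                       exons = cbind(101L, 106L))))
  pr <- projectVariant(vrow(102, "C", "T"), models)
  expect_identical(pr$status, "coding")
  expect_identical(pr$cds_pos, 5L)
  expect_identical(pr$coding_ref, "G")
  expect_identical(pr$coding_alt, "A")
  expect_identical(pr$ref_codon, "CGT")
  expect_identical(pr$alt_codon, "CAT")
})

test_that("intronic positions within 2 nt of a CDS boundary are splice sites", {
  cds <- randomCDS(40, seed = 5)          # 120 nt, split 60 + 60
  set.seed(6)
  pad <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
  intron <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
  chrom <- paste0(pad, substr(cds, 1, 60), intron, substr(cds, 61, 120),
                  pad)
  models <- toyModels(chrom, list(list(
    gene = "G1", tx = "G1.T1", strand = "+",
    exons = cbind(c(51L, 151L), c(110L, 210L)))))
  expect_identical(projectVariant(vrow(111, "A", "C"), models)$status,
                   "splice_site")
  expect_identical(projectVariant(vrow(112, "A", "C"), models)$status,
                   "splice_site")
  expect_identical(projectVariant(vrow(113, "A", "C"), models)$status,
                   "noncoding")
  expect_identical(projectVariant(vrow(150, "A", "C"), models)$status,
                   "splice_site")
})

test_that("a reference mismatch is reported with both bases", {
  toy <- toySingleExon("ATGGCTCGATGGTAA", pad = 100L)
  ## position 101 is A; claim it is C
  expect_error(projectVariant(vrow(101, "C", "G"), toy$models),
               "reference mismatch")
})

test_that("codon changes classify by the genetic code", {
  expect_identical(classifyConsequence("CGT", "TGT")$consequence, "missense")
  expect_identical(classifyConsequence("CGT", "TGT")$alt_aa, "C")
  expect_identical(classifyConsequence("CGT", "CGC")$consequence,
                   "synonymous")
  expect_identical(classifyConsequence("TGG", "TGA")$consequence, "nonsense")
  expect_identical(classifyConsequence("TGA", "TCA")$consequence,
                   "stop_loss")
  expect_error(classifyConsequence("CGT", "CGT"), "exactly one")
  expect_error(classifyConsequence("CGT", "TGC"), "exactly one")
})

test_that("classification agrees with brute-force translation over all 576 changes", {
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE)
  n_checked <- 0L
  for (cod in codons) {
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        got <- classifyConsequence(cod, alt)
        ## independent oracle: Biostrings translation + direct comparison
        raa <- as.character(Biostrings::translate(
          Biostrings::DNAString(cod), no.init.codon = TRUE))
        aaa <- as.character(Biostrings::translate(
          Biostrings::DNAString(alt), no.init.codon = TRUE))
        want <- if (raa == aaa) "synonymous" else if (aaa == "*")
          "nonsense" else if (raa == "*") "stop_loss" else "missense"
        expect_identical(got$consequence, want,
                         info = paste(cod, alt))
        expect_identical(got$ref_aa, raa)
        expect_identical(got$alt_aa, aaa)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_identical(n_checked, 576L)
})

test_that("hand-crafted variants on a toy gene annotate to the expected records", {
  toy <- toySingleExon("ATGGCTCGATGGTAA", pad = 100L)  # M A R W *
  vars <- rbind(
    vrow(106, "T", "C", sample_id = "S1"),   # GCT>GCC  synonymous A>A
    vrow(105, "C", "T", sample_id = "S2"),   # GCT>GTT  missense  A>V
    vrow(112, "G", "A", sample_id = "S3"))   # TGG>TGA  nonsense  W>*
  out <- annotateCatalog(vars, toy$models)
  expect_identical(nrow(out$aas), 3L)
  expect_identical(out$aas$consequence, c("synonymous", "missense",
                                          "nonsense"))
  expect_identical(out$aas$residue_pos, c(2L, 2L, 4L))
  expect_identical(out$aas$ref_aa, c("A", "A", "W"))
  expect_identical(out$aas$alt_aa, c("A", "V", "*"))
  ov <- out$summary[out$summary$cancer_type == "overall", ]
  expect_identical(ov$missense + ov$synonymous + ov$nonsense, 3L)
})

test_that("an empty variant table yields an empty catalogue and zero summary", {
  toy <- toySingleExon("ATGGCTCGATGGTAA")
  out <- annotateCatalog(vrow(1, "A", "C")[0, ], toy$models)
  expect_identical(nrow(out$aas), 0L)
  expect_true(all(out$summary[, -1] == 0))
})

test_that("catalogue counts are conserved and match the generator's own labels", {
  cfg <- smallConfig(seed = 8)
  genes <- generateGenes(cfg)
  co <- generateCohort(cfg, genes)
  out <- annotateCatalog(co$variants, genes)
  ov <- out$summary[out$summary$cancer_type == "overall", ]
  ## conservation: every input row lands in exactly one class
  expect_identical(sum(ov[, setdiff(names(ov), "cancer_type")]),
                   nrow(co$variants))
  expect_identical(attr(out$summary, "n_multi_gene"), 0L)
  ## generator sidecar as oracle, per class
  truth_tab <- table(co$truth$consequence)
  for (cl in names(truth_tab))
    expect_identical(ov[[cl]], as.integer(truth_tab[[cl]]), info = cl)
})

test_that("minus-strand annotation mirrors the reverse-complemented plus gene", {
  ## the same CDS planted as a plus-strand gene and as its mirrored
  ## minus-strand twin must give identical protein-level records
  cds <- randomCDS(80, seed = 21)
  set.seed(22)
  pad1 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
  pad2 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
  chrom_p <- paste0(pad1, cds, pad2)
  L <- nchar(chrom_p)
  chrom_m <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chrom_p)))
  mod_p <- toyModels(chrom_p, list(list(gene = "G1", tx = "G1.T1",
                                        strand = "+",
                                        exons = cbind(31L, 30L + nchar(cds)))))
  mod_m <- toyModels(chrom_m, list(list(gene = "G1", tx = "G1.T1",
                                        strand = "-",
                                        exons = cbind(L - (30L + nchar(cds)) + 1L,
                                                      L - 31L + 1L))))
  set.seed(23)
  chars <- strsplit(chrom_p, "")[[1]]
  pos <- sample(seq(31L, 30L + nchar(cds)), 1000L, replace = TRUE)
  ref <- chars[pos]
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1L), character(1))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ann_p <- annotateCatalog(
    data.frame(sample_id = sprintf("s%04d", seq_along(pos)),
               cancer_type = "cx", chrom = "chr1", pos = pos, ref = ref,
               alt = alt, stringsAsFactors = FALSE), mod_p)
  ann_m <- annotateCatalog(
    data.frame(sample_id = sprintf("s%04d", seq_along(pos)),
               cancer_type = "cx", chrom = "chr1", pos = L - pos + 1L,
               ref = unname(comp[ref]), alt = unname(comp[alt]),
               stringsAsFactors = FALSE), mod_m)
  expect_identical(ann_p$aas$consequence, ann_m$aas$consequence)
  expect_identical(ann_p$aas$residue_pos, ann_m$aas$residue_pos)
  expect_identical(ann_p$aas$ref_aa, ann_m$aas$ref_aa)
  expect_identical(ann_p$aas$alt_aa, ann_m$aas$alt_aa)
  expect_identical(ann_p$aas$ref_codon, ann_m$aas$ref_codon)
})

test_that("the nonsynonymous/synonymous ratio follows its definition", {
  expect_identical(nsSynRatio(c(missense = 824336, synonymous = 308896),
                              digits = 1), 2.7)
  expect_identical(nsSynRatio(c(missense = 10, synonymous = 10)), 1)
  expect_identical(nsSynRatio(c(missense = 0, synonymous = 10)), 0)
  expect_error(nsSynRatio(c(missense = 5, synonymous = 0)), "undefined")
  ## stop-gains can be pulled into the numerator explicitly
  expect_equal(nsSynRatio(c(missense = 6, nonsense = 2, synonymous = 4),
                          nonsynClasses = c("missense", "nonsense")), 2)
})
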