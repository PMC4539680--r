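## Synthetic-cohort generator: determinism, structural invariants of the
## gene models, planted-truth bookkeeping, spectrum sampling and the
## Beta harmfulness mixture.

test_that("identical seeds give identical generated objects and files", {
  cfg <- smallConfig(seed = 7)
  g1 <- generateGenes(cfg)
  g2 <- generateGenes(cfg)
  expect_identical(as.character(refSequence(g1)), as.character(refSequence(g2)))
  expect_identical(as.data.frame(cdsExons(g1)), as.data.frame(cdsExons(g2)))

  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulateCohort(cfg, d1)
  s2 <- simulateCohort(cfg, d2)
  for (nm in names(s1$paths)) {
    expect_identical(unname(tools::md5sum(s1$paths[[nm]])),
                     unname(tools::md5sum(s2$paths[[nm]])),
                     info = nm)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated gene models satisfy the CDS structure contract", {
  cfg <- smallConfig(seed = 2)
  genes <- generateGenes(cfg)
  tx <- as.data.frame(transcriptTable(genes))
  expect_true(all(tx$cds_length %% 3 == 0))
  expect_true(all(c("+", "-") %in% tx$strand))
  ## at least one gene with isoforms of different protein lengths
  multi <- vapply(split(tx$protein_length, tx$gene_id),
                  function(x) length(unique(x)) > 1, logical(1))
  expect_true(any(multi))

  ## independent translation check: every CDS starts M, ends *, and has
  ## no internal stop (extracted and translated with Biostrings)
  ex <- cdsExons(genes)
  chrom <- refSequence(genes)[["chr1"]]
  for (tid in tx$transcript_id) {
    sel <- ex[S4Vectors::mcols(ex)$transcript_id == tid]
    sel <- sel[order(GenomicRanges::start(sel))]
    cds <- do.call(Biostrings::xscat, lapply(seq_along(sel), function(i)
      Biostrings::subseq(chrom, GenomicRanges::start(sel)[i],
                         GenomicRanges::end(sel)[i])))
    if (as.character(GenomicRanges::strand(sel))[1] == "-")
      cds <- Biostrings::reverseComplement(cds)
    aa <- as.character(Biostrings::translate(cds))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 2, nchar(aa) - 1L), fixed = TRUE))
  }
})

test_that("transcripts_per_gene = (2,2) forces exactly two isoforms", {
  cfg <- smallConfig(seed = 3, transcripts_per_gene = c(2L, 2L),
                     n_genes = 15L)
  genes <- generateGenes(cfg)
  tx <- as.data.frame(transcriptTable(genes))
  expect_true(all(table(tx$gene_id) == 2L))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(smallConfig(n_genes = 1L), "n_genes")
  expect_error(smallConfig(drivers_per_cancer = 40L, n_genes = 40L),
               "drivers_per_cancer")
  expect_error(smallConfig(pathway_size = 100L), "pathway_size")
  expect_error(smallConfig(network_density = 2), "network_density")
  expect_error(smallConfig(harm_thresholds = c(0.9, 0.1)),
               "harm_thresholds")
})

test_that("an empty cohort is returned for zero samples", {
  cfg <- smallConfig(seed = 1, samples_per_cancer = 0L)
  genes <- generateGenes(cfg)
  co <- generateCohort(cfg, genes)
  expect_identical(nrow(co$variants), 0L)
  expect_length(co$truth$consequence, 0L)
})

test_that("cohort generation requires a gene set", {
  cfg <- smallConfig()
  expect_error(generateCohort(cfg), "gene set")
})

test_that("without a driver boost, driver and background missense rates agree", {
  ## driver_boost = 1 plants nothing: per-base missense rates in driver
  ## vs non-driver genes must agree within 3 Monte-Carlo SDs across seeds
  diffs <- vapply(1:10, function(s) {
    cfg <- smallConfig(seed = s, driver_boost = 1)
    genes <- generateGenes(cfg)
    co <- generateCohort(cfg, genes)
    ann <- annotateCatalog(co$variants, genes)
    mis <- ann$aas[ann$aas$consequence == "missense", ]
    tx <- as.data.frame(transcriptTable(genes))
    keep <- selectLongestTranscript(genes)
    tx <- tx[tx$transcript_id %in% keep, ]
    pool <- somaticAAS:::.plantDrivers(cfg, genes)$pool
    cds_len <- stats::setNames(tx$cds_length, tx$gene_id)
    drv_bases <- sum(cds_len[pool])
    bg_bases <- sum(cds_len) - drv_bases
    sum(mis$gene_id %in% pool) / drv_bases -
      sum(!mis$gene_id %in% pool) / bg_bases
  }, numeric(1))
  tstat <- mean(diffs) / (stats::sd(diffs) / sqrt(length(diffs)))
  expect_lt(abs(tstat), 3)
})

test_that("generated SNV channels follow the planted spectrum weights", {
  ## default genome scale, one cancer: > 10,000 SNVs
  cfg <- syntheticConfig(seed = 11, n_cancers = 1L,
                         samples_per_cancer = 80L)
  genes <- generateGenes(cfg)
  co <- generateCohort(cfg, genes)
  expect_gt(nrow(co$variants), 10000)
  chars <- strsplit(as.character(refSequence(genes)[["chr1"]]), "")[[1]]
  chan <- pyrimidineCanonical(co$variants$ref, co$variants$alt,
                              chars[co$variants$pos - 1L],
                              chars[co$variants$pos + 1L])$channel
  obs <- tabulate(chan, 96L)
  w <- cfg$spectrum_weights[, 1]
  pval <- suppressWarnings(stats::chisq.test(obs, p = w)$p.value)
  expect_gt(pval, 0.001)
})

test_that("harmfulness probabilities separate drivers from background", {
  cfg <- smallConfig(seed = 4, harm_high = c(50, 1), harm_low = c(1, 50))
  genes <- generateGenes(cfg)
  co <- generateCohort(cfg, genes)
  ann <- annotateCatalog(co$variants, genes)
  preds <- generatePredictions(ann$aas, co$truth, cfg)
  expect_true(all(preds$probability >= 0 & preds$probability <= 1))
  gene_of <- sub("\\.T\\d+$", "", preds$protein_id)
  isdrv <- gene_of %in% co$truth$pool
  expect_gt(mean(preds$probability[isdrv]),
            mean(preds$probability[!isdrv]))
  expect_true(all(preds$class %in% c("harmful", "neutral", "unknown")))

  ## fraction labelled unknown matches the Beta-mixture mass between the
  ## thresholds within 3 binomial SDs
  w_d <- mean(isdrv)
  mass <- function(ab) stats::pbeta(0.95, ab[1], ab[2]) -
    stats::pbeta(0.05, ab[1], ab[2])
  p_unk <- w_d * mass(cfg$harm_high) + (1 - w_d) * mass(cfg$harm_low)
  obs <- mean(preds$class == "unknown")
  se <- sqrt(p_unk * (1 - p_unk) / nrow(preds))
  expect_lt(abs(obs - p_unk), 3 * se + 1e-12)
})

test_that("planted gene sets and interaction network have the promised structure", {
  dens <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    cfg <- smallConfig(seed = s)
    genes <- generateGenes(cfg)
    co <- generateCohort(cfg, genes)
    sets <- generateGenesetsAndNetwork(genes, co$truth, cfg)
    planted <- sets$pathways[grep("^PW_PLANTED_", names(sets$pathways))]
    ## every planted driver appears in at least one planted pathway
    for (cc in names(co$truth$drivers))
      expect_true(all(co$truth$drivers[[cc]] %in% unlist(planted)))
    g <- sets$network
    expect_false(any(igraph::which_loop(g)))
    expect_false(any(igraph::which_multiple(g)))
    ## within- vs cross-pathway edge density
    memb <- sets$pathway_membership
    el <- igraph::as_edgelist(g)
    same <- !is.na(memb[el[, 1]]) & !is.na(memb[el[, 2]]) &
      memb[el[, 1]] == memb[el[, 2]]
    sizes <- table(memb)
    n_within_pairs <- sum(sizes * (sizes - 1) / 2)
    n <- length(memb)
    n_cross_pairs <- n * (n - 1) / 2 - n_within_pairs
    dens[s, ] <- c(sum(same) / n_within_pairs,
                   sum(!same) / n_cross_pairs)
  }
  expect_gt(mean(dens[, 1]), mean(dens[, 2]))
})

test_that("every stage regenerates identically from the master seed", {
  cfg <- smallConfig(seed = 5)
  genes <- generateGenes(cfg)
  co1 <- generateCohort(cfg, genes)
  ann <- annotateCatalog(co1$variants, genes)
  p1 <- generatePredictions(ann$aas, co1$truth, cfg)
  ## regenerate the predictions without re-running the earlier stages
  p2 <- generatePredictions(ann$aas, co1$truth, cfg)
  expect_identical(p1, p2)
  co2 <- generateCohort(cfg, genes)
  expect_identical(co1$variants, co2$variants)
})
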