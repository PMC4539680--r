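## Distinct-sample counting, the nearest-rank percentile threshold,
## the recurrence rule, length normalisation and cancer-gene overlap.

## harmful table in which protein i has a harmful AAS in each of the
## given samples (one row per sample, distinct substitutions)
countsTable <- function(counts, cancer = "cx") {
  prot <- rep(sprintf("P%03d.T1", seq_along(counts)), counts)
  idx <- unlist(lapply(counts, seq_len))
  data.frame(sample_id = sprintf("S%03d", idx), cancer_type = cancer,
             gene_id = sub("\\..*$", "", prot), protein_id = prot,
             residue_pos = idx, ref_aa = "R", alt_aa = "H",
             consequence = "missense", stringsAsFactors = FALSE)
}

test_that("sample counts are distinct-sample tallies", {
  h <- rbind(hrow("P1.T1", "S1", pos = 1L),
             hrow("P1.T1", "S1", pos = 2L),
             hrow("P1.T1", "S2", pos = 3L))
  expect_identical(sampleCounts(h), c(P1.T1 = 2L))
  expect_length(sampleCounts(h[0, ]), 0L)
  ## brute-force group-by oracle on a synthetic cohort
  cfg <- smallConfig(seed = 17)
  genes <- generateGenes(cfg)
  co <- generateCohort(cfg, genes)
  ann <- annotateCatalog(co$variants, genes)
  preds <- generatePredictions(ann$aas, co$truth, cfg)
  harm <- joinHarmful(ann$aas, preds)
  got <- sampleCounts(harm, cancer = "cancer01")
  sub <- harm[harm$cancer_type == "cancer01", ]
  want <- tapply(sub$sample_id, sub$protein_id,
                 function(x) length(unique(x)))
  expect_identical(got[order(names(got))],
                   stats::setNames(as.integer(want), names(want))[
                     order(names(want))])
})

test_that("nearest-rank percentile agrees with stats::quantile type 1", {
  expect_identical(nearestRankPercentile(2:100, 95), 96L)
  set.seed(41)
  for (i in 1:300) {
    x <- stats::rpois(sample(5:300, 1), sample(2:40, 1)) + 2L
    p <- stats::runif(1, 1, 99)
    expect_identical(as.numeric(nearestRankPercentile(x, p)),
                     unname(stats::quantile(x, p / 100, type = 1)))
  }
  expect_error(nearestRankPercentile(integer(), 95), "empty")
})

test_that("percentile selection matches the worked threshold example", {
  ## surviving counts 2..100: the 95th-percentile threshold is the 95th
  ## smallest value (96); strictly greater selects 97..100
  h <- countsTable(2:100)
  sel <- selectProteins(h, "cx", 100)
  expect_identical(sel@threshold, 96)
  expect_identical(sum(selectionTable(sel)$selected), 4L)
  expect_true(all(selectionTable(sel)$n_samples[
    selectionTable(sel)$selected] > 96))

  ## all counts below min_samples: empty selection, not an error
  h1 <- countsTable(rep(1L, 10))
  sel1 <- selectProteins(h1, "cx", 100)
  expect_identical(nrow(selectionTable(sel1)), 0L)
  expect_identical(sum(selectionTable(sel1)$selected), 0L)
})

test_that("selection agrees with a brute-force oracle on random count vectors", {
  set.seed(43)
  for (i in 1:200) {
    counts <- stats::rpois(sample(10:200, 1), sample(3:30, 1))
    counts <- counts[counts >= 2]
    if (!length(counts)) next
    h <- countsTable(counts)
    sel <- selectProteins(h, "cx", 500)
    ## oracle: quantile type 1 + strict comparison
    thr <- unname(stats::quantile(counts, 0.95, type = 1))
    expect_identical(sel@threshold, as.numeric(thr))
    expect_identical(sum(selectionTable(sel)$selected),
                     sum(counts > thr))
  }
})

test_that("the recurrence rule admits frequent identical substitutions", {
  ## 49 proteins with counts 10..58 push the threshold far above 5;
  ## protein PREC has one identical substitution in 5 of 200 samples
  ## (2.5 %) and the cohort has 150 > 100 samples with harmful AASs
  base <- countsTable(seq(10L, 58L))
  filler <- do.call(rbind, lapply(59:150, function(s)
    hrow("P001.T1", sprintf("S%03d", s), pos = 999L)))
  rec <- do.call(rbind, lapply(1:5, function(s)
    hrow("PREC.T1", sprintf("S%03d", s), pos = 42L, ref_aa = "R",
         alt_aa = "W")))
  h <- rbind(base, filler, rec)
  sel <- selectProteins(h, "cx", 200)
  expect_gt(sel@nSamplesHarmful, 100L)
  tb <- selectionTable(sel)
  expect_true(tb$selected[tb$protein_id == "PREC.T1"])
  expect_identical(tb$reason[tb$protein_id == "PREC.T1"], "recurrence")
  expect_lt(5, sel@threshold)

  ## same table but only 90 samples with harmful AASs: gate closed
  h2 <- h[!h$sample_id %in% sprintf("S%03d", 91:150), ]
  sel2 <- selectProteins(h2, "cx", 200)
  tb2 <- selectionTable(sel2)
  expect_false(tb2$selected[tb2$protein_id == "PREC.T1"])
})

test_that("per-residue normalisation divides counts by protein length", {
  expect_equal(normalizeByLength(c(P1 = 10), c(P1 = 1000)), 0.01)
  expect_equal(normalizeByLength(c(P1 = 0), c(P1 = 50)), 0)
  f <- normalizeByLength(c(A = 20, B = 20), c(A = 500, B = 5000))
  expect_equal(f[1] / f[2], 10)
  expect_error(normalizeByLength(c(A = 1), c(A = 0)), "positive")
  expect_error(normalizeByLength(c(A = 1), c(B = 10)), "missing")
})

test_that("known-list overlap partitions the selection", {
  ov <- cgcOverlap(c("A", "B", "C"), c("B", "C", "D"))
  expect_identical(ov$n_overlap, 2L)
  expect_identical(sort(ov$known), c("B", "C"))
  expect_identical(ov$novel, "A")
  expect_identical(cgcOverlap(c("A", "B"), c("A", "B"))$novel, character(0))
  expect_identical(cgcOverlap(c("A"), c("B"))$n_overlap, 0L)
  expect_identical(ov$n_overlap + length(ov$novel), 3L)
})

test_that("adding harmful AASs never shrinks the selection at a fixed threshold", {
  set.seed(47)
  for (i in 1:20) {
    counts <- stats::rpois(60, 8) + 2L
    h <- countsTable(counts)
    sel <- selectProteins(h, "cx", 200)
    thr <- sel@threshold
    base_sel <- selectedProteins(sel)
    ## add a harmful AAS in a new sample for a random protein
    extra <- hrow(sprintf("P%03d.T1", sample(60, 1)), "S999", pos = 77L)
    h2 <- rbind(h, extra)
    counts2 <- sampleCounts(h2)
    ## with the original threshold, the selected set can only grow
    sel2_fixed <- names(counts2)[counts2 > thr]
    expect_true(all(base_sel %in% sel2_fixed))
    ## and per-protein counts are monotone
    expect_true(all(counts2[names(sampleCounts(h))] >= sampleCounts(h)))
  }
})

test_that("on the synthetic cohort the selection is approximately the top 5 %", {
  cfg <- syntheticConfig(seed = 19, n_cancers = 1L)
  genes <- generateGenes(cfg)
  co <- generateCohort(cfg, genes)
  ann <- annotateCatalog(co$variants, genes)
  preds <- generatePredictions(ann$aas, co$truth, cfg)
  harm <- joinHarmful(ann$aas, preds)
  sel <- selectProteins(harm, "cancer01", cfg$samples_per_cancer)
  tb <- selectionTable(sel)
  n_perc <- sum(tb$selected & tb$reason == "percentile")
  expect_gte(nrow(tb), 100L)
  expect_lte(n_perc / nrow(tb), 0.06)
})
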