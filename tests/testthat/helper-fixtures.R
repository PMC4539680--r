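## Shared fixture builders.  Everything is generated in code; no stored
## binary data.

## A small, fast generator configuration for unit tests (the full default
## configuration is exercised by the recovery tests).
smallConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, n_cancers = 2L, samples_per_cancer = 12L,
               n_genes = 40L, cds_length_range = c(100L, 200L),
               drivers_per_cancer = 6L, driver_blocks = 3L,
               blocks_per_cancer = 2L, background_rate = 30,
               pathway_size = 5L, cgc_decoys = 5L)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticConfig, args)
}

## Random CDS of n codons: ATG + sense codons + stop.
randomCDS <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

## Build a GeneModelSet from explicit transcripts on one chromosome.
## transcripts: list of list(gene, tx, strand, exons = 2-col matrix of
## genomic start/end).  chrom_seq: the full chromosome string.
toyModels <- function(chrom_seq, transcripts) {
  rows <- do.call(rbind, lapply(transcripts, function(t)
    data.frame(start = t$exons[, 1], end = t$exons[, 2],
               strand = t$strand, gene_id = t$gene,
               transcript_id = t$tx, stringsAsFactors = FALSE)))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  GeneModelSet(gr, Biostrings::DNAStringSet(c(chr1 = chrom_seq)))
}

## Plus-strand single-exon toy gene: pad bases, then the CDS, then pad.
## Returns list(models, cds_start) with the CDS starting at genomic
## position pad + 1.
toySingleExon <- function(cds, pad = 100L, strand = "+", seed = 42) {
  set.seed(seed)
  pre <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
               collapse = "")
  post <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                collapse = "")
  chrom <- paste0(pre, cds, post)
  models <- toyModels(chrom, list(list(
    gene = "G1", tx = "G1.T1", strand = strand,
    exons = cbind(pad + 1L, pad + nchar(cds)))))
  list(models = models, cds_start = pad + 1L, chrom = chrom)
}

## Minimal variant row.
vrow <- function(pos, ref, alt, sample_id = "S1", cancer = "cx",
                 chrom = "chr1") {
  data.frame(sample_id = sample_id, cancer_type = cancer, chrom = chrom,
             pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

## Minimal harmful-AAS table row (as produced by joinHarmful()).
hrow <- function(protein, sample, cancer = "cx", pos = 1L,
                 ref_aa = "R", alt_aa = "H", gene = NULL) {
  data.frame(sample_id = sample, cancer_type = cancer,
             gene_id = if (is.null(gene)) sub("\\..*$", "", protein)
             else gene,
             protein_id = protein, residue_pos = pos, ref_aa = ref_aa,
             alt_aa = alt_aa, consequence = "missense",
             stringsAsFactors = FALSE)
}
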