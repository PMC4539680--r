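#' GeneModelSet: CDS exon structure plus reference sequence
#'
#' Container for a set of protein-coding gene models on a reference
#' sequence.  CDS exons are stored as a [GenomicRanges::GRanges] with
#' metadata columns `gene_id`, `transcript_id` and `exon_rank` (rank in
#' genomic order).  The transcript table caches per-transcript summaries
#' (strand, CDS length, protein length) used by longest-transcript
#' selection.
#'
#' Coordinates are 1-based and inclusive throughout, matching GFF3.
#' For every transcript the total CDS length is a multiple of three and
#' the protein length is `CDS length / 3 - 1` (the terminal stop codon is
#' not part of the protein).
#'
#' @slot exons `GRanges` of CDS exons with `gene_id`, `transcript_id`,
#'   `exon_rank` metadata columns.
#' @slot reference `DNAStringSet` with one entry per chromosome.
#' @slot transcripts `DataFrame` with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `cds_length`, `protein_length`, `n_exons`.
#'
#' @seealso [readGeneModels()], [writeGeneModels()], [generateGenes()],
#'   [selectLongestTranscript()]
#' @export
setClass("GeneModelSet",
         slots = c(exons = "GRanges",
                   reference = "DNAStringSet",
                   transcripts = "DataFrame"))

setValidity("GeneModelSet", function(object) {
  msgs <- character()
  ex <- object@exons
  need <- c("gene_id", "transcript_id", "exon_rank")
  if (!all(need %in% colnames(S4Vectors::mcols(ex))))
    msgs <- c(msgs, "exons must carry gene_id, transcript_id, exon_rank")
  tx <- object@transcripts
  if (nrow(tx)) {
    if (any(tx$cds_length %% 3L != 0L))
      msgs <- c(msgs, "every transcript CDS length must be divisible by 3")
    if (any(tx$protein_length != tx$cds_length / 3L - 1L))
      msgs <- c(msgs, "protein_length must equal cds_length/3 - 1")
    if (!all(tx$strand %in% c("+", "-")))
      msgs <- c(msgs, "strand must be '+' or '-'")
    if (!all(as.character(unique(GenomicRanges::seqnames(ex))) %in%
             names(object@reference)))
      msgs <- c(msgs, "all exon chromosomes must be present in the reference")
  }
  if (length(msgs)) msgs else TRUE
})

#' SpectrumMatrix: 96-channel trinucleotide substitution spectrum
#'
#' Counts of SNVs over the six pyrimidine-centred substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G) by the 16 combinations of immediate 5'
#' and 3' flanking bases.  The class total always equals the number of
#' SNVs included in the spectrum.
#'
#' @slot cancerType single cancer type label (or `"all"`).
#' @slot counts 6 x 16 integer matrix; rows are substitution classes,
#'   columns `5'_3'` contexts.
#' @slot total number of SNVs included.
#' @slot nExcluded SNVs dropped (splice-site or missing context).
#' @seealso [buildSpectrum()], [pyrimidineCanonical()]
#' @export
setClass("SpectrumMatrix",
         slots = c(cancerType = "character",
                   counts = "matrix",
                   total = "integer",
                   nExcluded = "integer"))

setValidity("SpectrumMatrix", function(object) {
  msgs <- character()
  if (!identical(dim(object@counts), c(6L, 16L)))
    msgs <- c(msgs, "counts must be a 6 x 16 matrix")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (sum(object@counts) != object@total)
    msgs <- c(msgs, "channel counts must sum to the total")
  if (length(msgs)) msgs else TRUE
})

#' SelectionResult: prioritised proteins for one cancer type
#'
#' Result of the sample-count / percentile / recurrence prioritisation of
#' proteins containing harmful AASs in one cancer type.  The table keeps
#' every protein that survived the minimum-sample filter, with the selected
#' subset flagged and the admission reason recorded (`percentile` or
#' `recurrence`).
#'
#' @slot cancerType cancer type label.
#' @slot table `DataFrame` with columns `protein_id`, `n_samples`,
#'   `n_harmful_aas`, `selected`, `reason`.
#' @slot threshold the nearest-rank 95th-percentile sample-count threshold
#'   actually used (NA when no protein survived).
#' @slot nSamplesCancer number of samples in the cancer type.
#' @slot nSamplesHarmful number of samples with at least one harmful AAS.
#' @slot params the [selectionParams()] list used.
#' @seealso [selectProteins()]
#' @export
setClass("SelectionResult",
         slots = c(cancerType = "character",
                   table = "DataFrame",
                   threshold = "numeric",
                   nSamplesCancer = "integer",
                   nSamplesHarmful = "integer",
                   params = "list"))

setValidity("SelectionResult", function(object) {
  msgs <- character()
  tb <- object@table
  need <- c("protein_id", "n_samples", "selected", "reason")
  if (!all(need %in% colnames(tb)))
    msgs <- c(msgs, "table must carry protein_id, n_samples, selected, reason")
  if (nrow(tb) && any(tb$selected & !tb$reason %in% c("percentile", "recurrence")))
    msgs <- c(msgs, "every selected protein must have a recorded reason")
  if (length(msgs)) msgs else TRUE
})

## ---- generics ----

#' @rdname GeneModelSet-class
#' @param x a `GeneModelSet`.
#' @export
setGeneric("cdsExons", function(x) standardGeneric("cdsExons"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))

#' @rdname SpectrumMatrix-class
#' @param x a `SpectrumMatrix`.
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))

#' @rdname SelectionResult-class
#' @param x a `SelectionResult`.
#' @export
setGeneric("selectedProteins", function(x) standardGeneric("selectedProteins"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

## ---- methods ----

#' @rdname GeneModelSet-class
setMethod("cdsExons", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-class
setMethod("refSequence", "GeneModelSet", function(x) x@reference)

#' @rdname GeneModelSet-class
setMethod("transcriptTable", "GeneModelSet", function(x) x@transcripts)

setMethod("show", "GeneModelSet", function(object) {
  tx <- object@transcripts
  cat("GeneModelSet with", length(unique(tx$gene_id)), "genes,",
      nrow(tx), "transcripts,", length(object@exons), "CDS exons\n")
  cat("  reference:", paste(names(object@reference), collapse = ", "),
      "(", sum(Biostrings::width(object@reference)), "bp )\n")
  if (nrow(tx))
    cat("  protein length range:", min(tx$protein_length), "-",
        max(tx$protein_length), "residues\n")
})

#' @rdname SpectrumMatrix-class
setMethod("spectrumCounts", "SpectrumMatrix", function(x) x@counts)

setMethod("show", "SpectrumMatrix", function(object) {
  cat("SpectrumMatrix for", object@cancerType, "-", object@total,
      "SNVs (", object@nExcluded, "excluded )\n")
  cls <- rowSums(object@counts)
  cat("  class totals:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
})

#' @rdname SelectionResult-class
setMethod("selectedProteins", "SelectionResult", function(x) {
  as.character(x@table$protein_id[x@table$selected])
})

#' @rdname SelectionResult-class
setMethod("selectionTable", "SelectionResult", function(x) x@table)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult for", object@cancerType, ":",
      sum(object@table$selected), "selected of", nrow(object@table),
      "surviving proteins\n")
  cat("  threshold =", object@threshold, "samples;",
      object@nSamplesHarmful, "of", object@nSamplesCancer,
      "samples carry harmful AASs\n")
})
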