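## Readers and writers for the standard input formats.

#' Read a somatic variant table
#'
#' Tab-separated with header columns `sample_id`, `cancer_type`, `chrom`,
#' `pos` (1-based), `ref`, `alt`.
#'
#' @param path file path.
#' @return data.frame of variants.
#' @export
readVariants <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("sample_id", "cancer_type", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(v))
  if (length(missing_cols))
    stop("variant file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  v$pos <- as.integer(v$pos)
  v
}

#' Read SNVs from a minimal VCF
#'
#' Uses \pkg{VariantAnnotation} to parse CHROM/POS/REF/ALT; only
#' single-base substitutions are kept.  Sample and cancer labels are
#' supplied by the caller (one VCF per sample).
#'
#' @param path VCF path.
#' @param sample_id,cancer_type labels attached to every record.
#' @return data.frame in [readVariants()] layout.
#' @export
readVariantsVCF <- function(path, sample_id, cancer_type) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- vapply(as.list(rr$ALT), function(a)
    if (length(a)) as.character(a[[1]]) else NA_character_, character(1))
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
  data.frame(sample_id = sample_id, cancer_type = cancer_type,
             chrom = as.character(GenomicRanges::seqnames(rr))[keep],
             pos = GenomicRanges::start(rr)[keep],
             ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE)
}

#' Read gene models from GFF3 + FASTA
#'
#' Expects CDS features whose `Parent` points at mRNA features, which in
#' turn point at gene features (the layout written by
#' [writeGeneModels()]).
#'
#' @param gff3 GFF3 path.
#' @param fasta reference FASTA path.
#' @return a [GeneModelSet-class].
#' @export
readGeneModels <- function(gff3, fasta) {
  for (p in c(gff3, fasta))
    if (!file.exists(p)) stop("gene model file not found: ", p)
  gr <- rtracklayer::import(gff3, format = "gff3")
  mrna <- gr[gr$type == "mRNA"]
  tx2gene <- stats::setNames(
    vapply(mrna$Parent, `[`, character(1), 1L), mrna$ID)
  cds <- gr[gr$type == "CDS"]
  tid <- vapply(cds$Parent, `[`, character(1), 1L)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(cds),
                                IRanges::IRanges(GenomicRanges::start(cds),
                                                 GenomicRanges::end(cds)),
                                strand = GenomicRanges::strand(cds))
  S4Vectors::mcols(out)$gene_id <- unname(tx2gene[tid])
  S4Vectors::mcols(out)$transcript_id <- tid
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*", "", names(ref))
  GeneModelSet(out, ref)
}

#' Write gene models as GFF3 + FASTA
#'
#' @param models a [GeneModelSet-class].
#' @param gff3,fasta output paths.
#' @return invisibly, the GFF3 path.
#' @export
writeGeneModels <- function(models, gff3, fasta) {
  ex <- cdsExons(models)
  tx <- as.data.frame(transcriptTable(models))
  mc <- S4Vectors::mcols(ex)
  gene_rows <- do.call(rbind, lapply(split(seq_len(nrow(tx)), tx$gene_id),
    function(i) data.frame(gene_id = tx$gene_id[i[1]],
                           chrom = tx$chrom[i[1]],
                           strand = tx$strand[i[1]])))
  spans_g <- vapply(split(seq_along(ex), mc$gene_id), function(i)
    c(min(GenomicRanges::start(ex)[i]), max(GenomicRanges::end(ex)[i])),
    numeric(2))
  spans_t <- vapply(split(seq_along(ex), mc$transcript_id), function(i)
    c(min(GenomicRanges::start(ex)[i]), max(GenomicRanges::end(ex)[i])),
    numeric(2))
  g_gene <- GenomicRanges::GRanges(
    gene_rows$chrom,
    IRanges::IRanges(spans_g[1, gene_rows$gene_id],
                     spans_g[2, gene_rows$gene_id]),
    strand = gene_rows$strand, type = "gene", ID = gene_rows$gene_id)
  g_mrna <- GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(spans_t[1, tx$transcript_id],
                     spans_t[2, tx$transcript_id]),
    strand = tx$strand, type = "mRNA", ID = tx$transcript_id,
    Parent = as.character(tx$gene_id))
  g_cds <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex),
    IRanges::IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)),
    strand = GenomicRanges::strand(ex), type = "CDS",
    phase = 0L,  # exons are codon-aligned by construction
    Parent = as.character(mc$transcript_id))
  all <- c(g_gene, g_mrna, g_cds)
  rtracklayer::export(all, gff3, format = "gff3")
  Biostrings::writeXStringSet(refSequence(models), fasta)
  invisible(gff3)
}

#' Read a one-id-per-line gene list
#'
#' @param path file path.
#' @return character vector.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
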