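## Mapping genomic SNVs onto the coding sequence of the longest transcript
## per gene and classifying their consequences.

#' Construct a GeneModelSet
#'
#' @param exons `GRanges` of CDS exons with metadata columns `gene_id` and
#'   `transcript_id` (an `exon_rank` column in genomic order is added when
#'   absent).  Exons of one transcript must be non-overlapping and lie on
#'   one strand of one chromosome.
#' @param reference named `DNAStringSet`, one entry per chromosome.
#' @return a [GeneModelSet-class] object.
#' @export
GeneModelSet <- function(exons, reference) {
  mc <- S4Vectors::mcols(exons)
  if (!all(c("gene_id", "transcript_id") %in% colnames(mc)))
    stop("exons must carry 'gene_id' and 'transcript_id' metadata columns")
  o <- order(mc$transcript_id, GenomicRanges::start(exons))
  exons <- exons[o]
  mc <- S4Vectors::mcols(exons)
  rk <- stats::ave(seq_along(exons), mc$transcript_id,
                   FUN = seq_along)
  S4Vectors::mcols(exons)$exon_rank <- as.integer(rk)
  w <- GenomicRanges::width(exons)
  tx_ids <- mc$transcript_id
  cds_len <- as.integer(tapply(w, tx_ids, sum)[unique(tx_ids)])
  first <- !duplicated(tx_ids)
  tx <- S4Vectors::DataFrame(
    gene_id = mc$gene_id[first],
    transcript_id = tx_ids[first],
    chrom = as.character(GenomicRanges::seqnames(exons))[first],
    strand = as.character(GenomicRanges::strand(exons))[first],
    cds_length = cds_len,
    protein_length = cds_len %/% 3L - 1L,
    n_exons = as.integer(table(tx_ids)[unique(tx_ids)]))
  if (any(tx$strand == "*"))
    stop("every transcript needs an explicit strand")
  if (any(tx$cds_length %% 3L != 0L))
    stop("CDS length not divisible by 3 for transcript(s): ",
         paste(tx$transcript_id[tx$cds_length %% 3L != 0L], collapse = ", "))
  methods::new("GeneModelSet", exons = exons, reference = reference,
               transcripts = tx)
}

#' Select the longest transcript per gene
#'
#' The analysis protein for each gene is the one encoded by its longest
#' transcript (largest protein length).  Ties are broken by the
#' lexicographically smallest transcript id so the choice is deterministic.
#'
#' @param models a [GeneModelSet-class].
#' @param gene optional single gene id; when given, returns that gene's
#'   transcript id only.
#' @return named character vector of transcript ids, one per gene (names
#'   are gene ids); or a single transcript id when `gene` is given.
#' @export
selectLongestTranscript <- function(models, gene = NULL) {
  tx <- as.data.frame(transcriptTable(models))
  if (!is.null(gene)) {
    tx <- tx[tx$gene_id == gene, , drop = FALSE]
    if (!nrow(tx)) stop("no transcript models for gene ", gene)
  }
  if (!nrow(tx)) stop("empty gene model set")
  tx <- tx[order(tx$gene_id, -tx$protein_length, tx$transcript_id), ]
  keep <- tx[!duplicated(tx$gene_id), ]
  out <- stats::setNames(keep$transcript_id, keep$gene_id)
  if (!is.null(gene)) unname(out) else out
}

## ---- internal engine ----

## Per-transcript lookup tables for a set of transcript ids: exon ranges,
## cumulative CDS offsets in coding order, and the CDS sequence string.
.transcriptIndex <- function(models, transcript_ids) {
  ex <- cdsExons(models)
  ex <- ex[S4Vectors::mcols(ex)$transcript_id %in% transcript_ids]
  mc <- S4Vectors::mcols(ex)
  chr <- as.character(GenomicRanges::seqnames(ex))
  st <- GenomicRanges::start(ex)
  en <- GenomicRanges::end(ex)
  strand <- as.character(GenomicRanges::strand(ex))
  w <- en - st + 1L
  ## coding-order cumulative length preceding each exon
  cum_before <- integer(length(ex))
  for (tid in unique(mc$transcript_id)) {
    i <- which(mc$transcript_id == tid)
    i <- i[order(st[i])]
    if (strand[i[1]] == "+") {
      cum_before[i] <- cumsum(c(0L, w[i]))[seq_along(i)]
    } else {
      ri <- rev(i)
      cum_before[ri] <- cumsum(c(0L, w[ri]))[seq_along(ri)]
    }
  }
  ## CDS sequence per transcript (coding strand)
  refchars <- lapply(refSequence(models), function(s)
    strsplit(as.character(s), "", fixed = TRUE)[[1]])
  seqs <- vapply(split(seq_along(ex), mc$transcript_id)[unique(mc$transcript_id)],
    function(i) {
      i <- i[order(st[i])]
      plus <- paste(unlist(lapply(i, function(j)
        refchars[[chr[j]]][st[j]:en[j]])), collapse = "")
      if (strand[i[1]] == "+") plus else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus)))
    }, character(1))
  list(exons = ex, chrom = chr, start = st, end = en, strand = strand,
       cum_before = cum_before,
       tx_of_exon = mc$transcript_id, gene_of_exon = mc$gene_id,
       cds_seq = seqs, refchars = refchars)
}

## Vectorised projection + classification of variants already matched to
## exons.  `hit_exon` indexes into idx$exons, parallel to variants rows.
.projectHits <- function(variants, idx, hit_exon) {
  st <- idx$start[hit_exon]; en <- idx$end[hit_exon]
  strand <- idx$strand[hit_exon]
  pos <- variants$pos
  cds_pos <- ifelse(strand == "+",
                    idx$cum_before[hit_exon] + (pos - st + 1L),
                    idx$cum_before[hit_exon] + (en - pos + 1L))
  coding_ref <- ifelse(strand == "+", variants$ref, .compBase(variants$ref))
  coding_alt <- ifelse(strand == "+", variants$alt, .compBase(variants$alt))
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  offset <- (cds_pos - 1L) %% 3L + 1L
  tx <- idx$tx_of_exon[hit_exon]
  cds_seq <- idx$cds_seq[tx]
  ref_codon <- substring(cds_seq, 3L * codon_idx - 2L, 3L * codon_idx)
  seq_ref <- substring(ref_codon, offset, offset)
  alt_codon <- ref_codon
  substring(alt_codon, offset, offset) <- coding_alt
  data.frame(gene_id = idx$gene_of_exon[hit_exon], protein_id = tx,
             strand = strand, cds_pos = as.integer(cds_pos),
             residue_pos = as.integer(codon_idx),
             codon_offset = as.integer(offset),
             ref_codon = ref_codon, alt_codon = alt_codon,
             coding_ref = coding_ref, coding_alt = coding_alt,
             seq_ref = seq_ref, stringsAsFactors = FALSE)
}

## plus-strand trinucleotide context of each variant position
.plusContext <- function(variants, refchars) {
  n <- nrow(variants)
  five <- three <- rep(NA_character_, n)
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    if (!ch %in% names(refchars)) next
    chars <- refchars[[ch]]
    p <- variants$pos[i]
    ok5 <- p > 1L
    ok3 <- p < length(chars)
    five[i[ok5]] <- chars[p[ok5] - 1L]
    three[i[ok3]] <- chars[p[ok3] + 1L]
  }
  data.frame(context5 = five, context3 = three, stringsAsFactors = FALSE)
}

#' Project one variant onto a gene model
#'
#' Maps a genomic SNV to CDS coordinates of one transcript: CDS position,
#' codon index, offset within the codon, and the reference/alternate codon
#' on the coding strand.  For minus-strand transcripts the alleles are
#' complemented.  Positions up to 2 nt inside an intron flanking a CDS
#' exon return status `splice_site`; other non-CDS positions return
#' `noncoding`.
#'
#' @param variant a one-row data.frame (or list) with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param models a [GeneModelSet-class].
#' @param transcript transcript id to project onto; defaults to the longest
#'   transcript of the gene overlapping the variant.
#' @return a list with `status` (`"coding"`, `"splice_site"` or
#'   `"noncoding"`) and, for coding hits, `gene_id`, `protein_id`,
#'   `cds_pos`, `residue_pos` (codon index), `codon_offset`, `ref_codon`,
#'   `alt_codon`, `coding_ref`, `coding_alt`.
#' @export
projectVariant <- function(variant, models, transcript = NULL) {
  variant <- as.data.frame(variant, stringsAsFactors = FALSE)
  stopifnot(nrow(variant) == 1L)
  if (is.null(transcript)) {
    keep <- selectLongestTranscript(models)
  } else keep <- transcript
  idx <- .transcriptIndex(models, keep)
  vgr <- GenomicRanges::GRanges(variant$chrom,
                                IRanges::IRanges(variant$pos, variant$pos))
  ov <- GenomicRanges::findOverlaps(vgr, idx$exons, ignore.strand = TRUE)
  if (length(ov)) {
    pr <- .projectHits(variant, idx, S4Vectors::subjectHits(ov)[1])
    if (pr$seq_ref != pr$coding_ref)
      stop("reference mismatch at ", variant$chrom, ":", variant$pos,
           ": variant ref '", variant$ref, "' vs reference base '",
           if (pr$strand == "+") pr$seq_ref else .compBase(pr$seq_ref), "'")
    return(c(list(status = "coding"), as.list(pr[, c(
      "gene_id", "protein_id", "cds_pos", "residue_pos", "codon_offset",
      "ref_codon", "alt_codon", "coding_ref", "coding_alt")])))
  }
  flank <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::resize(idx$exons,
                          GenomicRanges::width(idx$exons) + 4L, fix = "center")))
  ovf <- GenomicRanges::findOverlaps(vgr, flank, ignore.strand = TRUE)
  if (length(ovf)) return(list(status = "splice_site"))
  list(status = "noncoding")
}

#' Annotate a variant catalogue against the longest transcripts
#'
#' Classifies every SNV against the longest transcript of the gene(s) it
#' overlaps.  Variants overlapping no CDS are counted as `noncoding`
#' (or `splice_site` when within 2 nt of a CDS exon boundary inside the
#' intron); malformed rows (bad bases, `ref == alt`, reference mismatch)
#' are counted and dropped, not fatal.
#'
#' When genes do not overlap, the per-class counts in the summary add up
#' exactly to the number of input rows.  A variant inside two overlapping
#' genes is annotated once per gene (no information loss); the surplus is
#' reported as `n_multi_gene`.
#'
#' @param variants data.frame with columns `sample_id`, `cancer_type`,
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param models a [GeneModelSet-class].
#' @return a list with
#'   \describe{
#'     \item{aas}{data.frame of coding records: sample/cancer columns,
#'       `gene_id`, `protein_id`, `residue_pos`, `ref_aa`, `alt_aa`,
#'       `consequence` (`synonymous`, `missense`, `nonsense`,
#'       `stop_loss`), codons, plus-strand `context5`/`context3`, and the
#'       genomic coordinates.}
#'     \item{summary}{data.frame of per-cancer counts per class plus
#'       `splice_site`, `noncoding` and `malformed`, with an `overall`
#'       row; attributes `n_input` and `n_multi_gene`.}
#'   }
#' @export
annotateCatalog <- function(variants, models) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  cols <- c("sample_id", "cancer_type", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(cols, names(variants))
  if (length(missing_cols))
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  n_input <- nrow(variants)
  classes <- c("missense", "synonymous", "nonsense", "stop_loss",
               "splice_site", "noncoding", "malformed")
  empty_aas <- data.frame(
    sample_id = character(), cancer_type = character(),
    gene_id = character(), protein_id = character(),
    residue_pos = integer(), ref_aa = character(), alt_aa = character(),
    consequence = character(), ref_codon = character(),
    alt_codon = character(), context5 = character(),
    context3 = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), stringsAsFactors = FALSE)
  if (!n_input) {
    summ <- .annotationSummary(character(), character(), classes, 0L, 0L)
    return(list(aas = empty_aas, summary = summ))
  }
  ok <- variants$ref %in% .BASES & variants$alt %in% .BASES &
    variants$ref != variants$alt & !is.na(variants$pos) & variants$pos >= 1
  malformed <- !ok
  v <- variants[ok, , drop = FALSE]
  v$pos <- as.integer(v$pos)

  keep <- selectLongestTranscript(models)
  idx <- .transcriptIndex(models, keep)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  ov <- GenomicRanges::findOverlaps(vgr, idx$exons, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)

  pr <- if (length(ov)) .projectHits(v[qh, , drop = FALSE], idx, sh) else NULL
  status <- rep("noncoding", nrow(v))
  if (length(ov)) {
    mism <- pr$seq_ref != pr$coding_ref
    ## a reference-mismatching row is malformed, even if also hitting
    ## another gene
    bad_rows <- unique(qh[mism])
    keep_hit <- !mism & !(qh %in% bad_rows)
    status[unique(qh[keep_hit])] <- "coding"
    status[bad_rows] <- "malformed"
    pr <- pr[keep_hit, , drop = FALSE]
    qh <- qh[keep_hit]
  }
  ## splice: within 2 nt of an exon boundary, intron side
  nc <- which(status == "noncoding")
  if (length(nc)) {
    flank <- suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
      idx$exons, GenomicRanges::width(idx$exons) + 4L, fix = "center")))
    ovf <- GenomicRanges::findOverlaps(vgr[nc], flank, ignore.strand = TRUE)
    status[nc[unique(S4Vectors::queryHits(ovf))]] <- "splice_site"
  }

  if (length(qh)) {
    cls <- classifyConsequence(pr$ref_codon, pr$alt_codon)
    ctx <- .plusContext(v[qh, , drop = FALSE], idx$refchars)
    aas <- data.frame(
      sample_id = v$sample_id[qh], cancer_type = v$cancer_type[qh],
      gene_id = pr$gene_id, protein_id = pr$protein_id,
      residue_pos = pr$residue_pos, ref_aa = cls$ref_aa,
      alt_aa = cls$alt_aa, consequence = cls$consequence,
      ref_codon = pr$ref_codon, alt_codon = pr$alt_codon,
      context5 = ctx$context5, context3 = ctx$context3,
      chrom = v$chrom[qh], pos = v$pos[qh], ref = v$ref[qh],
      alt = v$alt[qh], stringsAsFactors = FALSE)
  } else aas <- empty_aas

  n_multi <- if (length(qh)) sum(duplicated(qh)) else 0L
  unit_cancer <- c(if (length(qh)) aas$cancer_type,
                   v$cancer_type[status == "splice_site"],
                   v$cancer_type[status == "noncoding"],
                   v$cancer_type[status == "malformed"],
                   variants$cancer_type[malformed])
  unit_class <- c(if (length(qh)) aas$consequence,
                  rep("splice_site", sum(status == "splice_site")),
                  rep("noncoding", sum(status == "noncoding")),
                  rep("malformed", sum(status == "malformed") + sum(malformed)))
  summ <- .annotationSummary(unit_cancer, unit_class, classes, n_input,
                             as.integer(n_multi))
  list(aas = aas, summary = summ)
}

.annotationSummary <- function(cancer, class, classes, n_input, n_multi) {
  cancers <- sort(unique(cancer))
  if (length(cancer)) {
    t2 <- table(factor(cancer, cancers), factor(class, classes))
    tab <- matrix(as.integer(t2), nrow = length(cancers),
                  dimnames = list(cancers, classes))
    tab <- rbind(tab, overall = colSums(tab))
    storage.mode(tab) <- "integer"
  } else {
    tab <- matrix(0L, nrow = 1L, ncol = length(classes),
                  dimnames = list("overall", classes))
  }
  out <- data.frame(cancer_type = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_input") <- n_input
  attr(out, "n_multi_gene") <- n_multi
  out
}

#' Ratio of nonsynonymous to synonymous variants
#'
#' By default the nonsynonymous numerator counts missense changes only;
#' stop-gains can be included via `nonsynClasses`.
#'
#' @param summary an annotation summary from [annotateCatalog()], or a
#'   named numeric vector of class counts (e.g.
#'   `c(missense = 824336, synonymous = 308896)`).
#' @param cancer cancer type row to use; default `"overall"`.
#' @param nonsynClasses classes counted as nonsynonymous.
#' @param digits optional rounding of the returned ratio.
#' @return the ratio as a single number.
#' @examples
#' nsSynRatio(c(missense = 824336, synonymous = 308896), digits = 1)  # 2.7
#' @export
nsSynRatio <- function(summary, cancer = "overall",
                       nonsynClasses = "missense", digits = NULL) {
  if (is.numeric(summary)) {
    counts <- summary
  } else {
    row <- summary[summary$cancer_type == cancer, , drop = FALSE]
    if (!nrow(row)) stop("no summary row for cancer '", cancer, "'")
    counts <- unlist(row[1, setdiff(names(row), "cancer_type")])
  }
  syn <- counts[["synonymous"]]
  if (is.na(syn) || syn <= 0)
    stop("undefined ratio: synonymous count is zero")
  ns <- sum(counts[nonsynClasses], na.rm = TRUE)
  r <- ns / syn
  if (!is.null(digits)) round(r, digits) else r
}
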