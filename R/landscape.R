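## Trinucleotide substitution spectra ("lego plot" matrices) and amino acid
## substitution matrices, per cancer type.

.SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.CONTEXTS <- as.vector(outer(.BASES, .BASES,
                             function(a, b) paste0(a, "_", b)))

#' Canonicalize a substitution to its pyrimidine-centred channel
#'
#' Substitutions are represented by the pyrimidine of the mutated base
#' pair: when the reference base is a purine, the substitution and its
#' flanking bases are reverse-complemented.  The resulting channel is one
#' of 6 substitution classes x 16 (5', 3') contexts = 96.
#'
#' @param ref,alt reference and alternate base (vectors).
#' @param five_prime,three_prime plus-strand flanking bases (vectors).
#' @return data.frame with canonical `class`, `context5`, `context3`, the
#'   channel `label` (`"A[C>T]G"` style) and the `channel` index in 1..96
#'   (class-major, contexts ordered A,C,G,T by 5' then 3').
#' @examples
#' pyrimidineCanonical("C", "T", "A", "G")  # C>T in A_G
#' pyrimidineCanonical("G", "A", "T", "C")  # reverse-complements to C>T in G_A
#' @export
pyrimidineCanonical <- function(ref, alt, five_prime, three_prime) {
  n <- max(length(ref), length(alt), length(five_prime), length(three_prime))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  five_prime <- rep_len(five_prime, n); three_prime <- rep_len(three_prime, n)
  if (!all(c(ref, alt, five_prime, three_prime) %in% .BASES))
    stop("invalid base(s); expected A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  cref <- ifelse(flip, .compBase(ref), ref)
  calt <- ifelse(flip, .compBase(alt), alt)
  c5 <- ifelse(flip, .compBase(three_prime), five_prime)
  c3 <- ifelse(flip, .compBase(five_prime), three_prime)
  cls <- paste0(cref, ">", calt)
  idx_cls <- match(cls, .SUB_CLASSES)
  idx_ctx <- match(paste0(c5, "_", c3), .CONTEXTS)
  data.frame(class = cls, context5 = c5, context3 = c3,
             label = paste0(c5, "[", cls, "]", c3),
             channel = (idx_cls - 1L) * 16L + idx_ctx,
             stringsAsFactors = FALSE)
}

#' Build a trinucleotide substitution spectrum
#'
#' Counts SNVs into the 96 pyrimidine-centred channels.  Records flagged
#' as splice-site (when a `consequence` column is present) and records
#' with missing flanking context are excluded and counted in
#' `nExcluded`.  Pass a pre-filtered table (e.g. missense only, or the
#' harmful subset from [joinHarmful()]) to build the corresponding
#' spectrum.
#'
#' @param records data.frame with `ref`, `alt`, `context5`, `context3`
#'   (plus-strand) and optionally `cancer_type` and `consequence`.
#' @param cancer restrict to one cancer type; `NULL` uses all records and
#'   labels the spectrum `"all"`.
#' @return a [SpectrumMatrix-class].
#' @export
buildSpectrum <- function(records, cancer = NULL) {
  label <- if (is.null(cancer)) "all" else cancer
  if (!is.null(cancer) && nrow(records))
    records <- records[records$cancer_type == cancer, , drop = FALSE]
  n0 <- nrow(records)
  if (n0 && "consequence" %in% names(records))
    records <- records[records$consequence != "splice_site", , drop = FALSE]
  ok <- if (nrow(records))
    !is.na(records$context5) & !is.na(records$context3) else logical(0)
  records <- records[ok, , drop = FALSE]
  counts <- matrix(0L, 6L, 16L, dimnames = list(.SUB_CLASSES, .CONTEXTS))
  if (nrow(records)) {
    chan <- pyrimidineCanonical(records$ref, records$alt,
                                records$context5, records$context3)$channel
    tab <- tabulate(chan, nbins = 96L)
    counts <- matrix(as.integer(tab), 6L, 16L, byrow = TRUE,
                     dimnames = list(.SUB_CLASSES, .CONTEXTS))
  }
  methods::new("SpectrumMatrix", cancerType = label, counts = counts,
               total = nrow(records),
               nExcluded = as.integer(n0 - nrow(records)))
}

#' Write a spectrum as a 96-row channel table
#'
#' @param spectrum a [SpectrumMatrix-class].
#' @param path output file (tab-separated: channel label, count,
#'   frequency).
#' @return the table, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  counts <- as.vector(t(spectrumCounts(spectrum)))
  labels <- as.vector(vapply(.SUB_CLASSES, function(cl)
    paste0(substring(.CONTEXTS, 1, 1), "[", cl, "]",
           substring(.CONTEXTS, 3, 3)), character(16)))
  tab <- data.frame(channel = labels, count = counts,
                    frequency = if (spectrum@total)
                      counts / spectrum@total else 0)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Plot a 96-channel spectrum as a bar chart
#'
#' Flat 96-bar rendering of the spectrum, grouped by substitution class.
#'
#' @param spectrum a [SpectrumMatrix-class].
#' @param file optional PNG path; when `NULL`, draws on the current device.
#' @return invisibly, the channel counts.
#' @export
plotSpectrum <- function(spectrum, file = NULL) {
  counts <- as.vector(t(spectrumCounts(spectrum)))
  cols <- rep(c("#03BCEE", "#010101", "#E32926",
                "#CAC9C9", "#A1CE63", "#EBC5C4"), each = 16L)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(counts, col = cols, border = NA, space = 0.2,
                    main = paste0(spectrum@cancerType, " (n = ",
                                  spectrum@total, ")"),
                    ylab = "SNV count")
  graphics::legend("topright", legend = .SUB_CLASSES, bty = "n",
                   fill = unique(cols), ncol = 3)
  invisible(counts)
}

#' Build an amino acid substitution matrix
#'
#' Counts missense and nonsense AAS records by (reference residue,
#' alternate residue), with the stop symbol `"*"` as a possible alternate.
#' The reachability mask ([aaReachableMask()]) marks pairs attainable by a
#' single base change; counts outside the mask cannot occur for true SNV
#' data.
#'
#' @param aas AAS table from [annotateCatalog()] (or its harmful subset).
#' @param cancer restrict to one cancer type (`NULL` = all).
#' @param uniqueSubstitutions count each distinct (protein, position,
#'   ref, alt) substitution once instead of every occurrence.
#' @return a list with `counts` (20 x 21 integer matrix), `mask`, and
#'   `cancer_type`.
#' @export
buildAASMatrix <- function(aas, cancer = NULL, uniqueSubstitutions = FALSE) {
  if (!is.null(cancer))
    aas <- aas[aas$cancer_type == cancer, , drop = FALSE]
  aas <- aas[aas$consequence %in% c("missense", "nonsense"), , drop = FALSE]
  if (uniqueSubstitutions && nrow(aas)) {
    key <- paste(aas$protein_id, aas$residue_pos, aas$ref_aa, aas$alt_aa)
    aas <- aas[!duplicated(key), , drop = FALSE]
  }
  counts <- matrix(0L, length(.AA_LEVELS), length(.AA_LEVELS) + 1L,
                   dimnames = list(.AA_LEVELS, c(.AA_LEVELS, .STOP)))
  if (nrow(aas)) {
    t2 <- table(factor(aas$ref_aa, .AA_LEVELS),
                factor(aas$alt_aa, c(.AA_LEVELS, .STOP)))
    counts[] <- as.integer(t2)
  }
  list(counts = counts, mask = aaReachableMask(),
       cancer_type = if (is.null(cancer)) "all" else cancer)
}
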