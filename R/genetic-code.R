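## Codon-level utilities shared by the annotation, landscape and synthetic
## modules.  The standard genetic code table comes from Biostrings; all
## consequence logic is defined here.

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
.AA_LEVELS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
.STOP <- "*"

#' Complement a vector of single bases
#' @param x character vector of bases in `A`, `C`, `G`, `T`.
#' @return character vector of complements.
#' @keywords internal
.compBase <- function(x) {
  out <- unname(.COMPLEMENT[x])
  if (anyNA(out)) stop("invalid base(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

## reverse complement of equal-length short strings (codons, triplets),
## vectorised without round-tripping through XStringSet
.revCompStr <- function(x, n = 3L) {
  parts <- lapply(seq_len(n), function(i) .compBase(substring(x, i, i)))
  do.call(paste0, rev(parts))
}

#' Translate codons to single-letter amino acids
#'
#' Uses the standard genetic code; stop codons translate to `"*"`.
#'
#' @param codons character vector of 3-base codons (uppercase DNA).
#' @return character vector of single-letter amino acids.
#' @examples
#' translateCodon(c("ATG", "TGA", "CGT"))
#' @export
translateCodon <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}

#' Classify the consequence of a single-base codon change
#'
#' Compares the reference and alternate codon of one SNV and returns the
#' consequence class together with the translated residues.  Codons must
#' differ at exactly one position.
#'
#' Classes: `synonymous` (same residue), `missense` (different residue,
#' neither is a stop), `nonsense` (stop gained), `stop_loss` (reference
#' codon is a stop, alternate is not).
#'
#' @param ref_codon,alt_codon character vectors of 3-base codons.
#' @return a `data.frame` with columns `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa` and `consequence`.
#' @examples
#' classifyConsequence("CGT", "TGT")  # missense R>C
#' classifyConsequence("TGG", "TGA")  # nonsense W>*
#' @export
classifyConsequence <- function(ref_codon, alt_codon) {
  n <- max(length(ref_codon), length(alt_codon))
  ref_codon <- rep_len(ref_codon, n)
  alt_codon <- rep_len(alt_codon, n)
  ndiff <- (substring(ref_codon, 1, 1) != substring(alt_codon, 1, 1)) +
    (substring(ref_codon, 2, 2) != substring(alt_codon, 2, 2)) +
    (substring(ref_codon, 3, 3) != substring(alt_codon, 3, 3))
  if (any(ndiff != 1L))
    stop("codons must differ at exactly one position; offending pair(s): ",
         paste(ref_codon[ndiff != 1L], alt_codon[ndiff != 1L],
               sep = ">", collapse = ", "))
  ref_aa <- translateCodon(ref_codon)
  alt_aa <- translateCodon(alt_codon)
  consequence <- .consequenceFromAA(ref_aa, alt_aa)
  data.frame(ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa,
             consequence = consequence, stringsAsFactors = FALSE)
}

## residue-pair -> class, vectorised; assumes a single-base codon change
.consequenceFromAA <- function(ref_aa, alt_aa) {
  ifelse(ref_aa == alt_aa, "synonymous",
         ifelse(alt_aa == .STOP, "nonsense",
                ifelse(ref_aa == .STOP, "stop_loss", "missense")))
}

#' Amino acid pairs reachable by a single base change
#'
#' Enumerates all 64 x 9 single-base codon substitutions and marks which
#' ordered (reference residue, alternate residue) pairs can arise from one
#' SNV.  Rows are the 20 reference residues, columns the 20 residues plus
#' `"*"` (stop gained).  Pairs with a stop reference codon are outside the
#' AAS analysis and not represented.
#'
#' @return a 20 x 21 logical matrix.
#' @examples
#' m <- aaReachableMask()
#' m["R", "H"]  # TRUE:  e.g. CGC -> CAC
#' m["M", "W"]  # FALSE: ATG and TGG differ at two positions
#' @export
aaReachableMask <- function() {
  codons <- names(Biostrings::GENETIC_CODE)
  mask <- matrix(FALSE, nrow = length(.AA_LEVELS),
                 ncol = length(.AA_LEVELS) + 1L,
                 dimnames = list(.AA_LEVELS, c(.AA_LEVELS, .STOP)))
  for (cod in codons) {
    ref_aa <- translateCodon(cod)
    if (ref_aa == .STOP) next
    for (pos in 1:3) {
      for (b in setdiff(.BASES, substring(cod, pos, pos))) {
        alt <- cod
        substring(alt, pos, pos) <- b
        alt_aa <- translateCodon(alt)
        if (alt_aa != ref_aa) mask[ref_aa, alt_aa] <- TRUE
      }
    }
  }
  mask
}
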