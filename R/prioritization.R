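## Selecting, per cancer type, the proteins most affected by harmful AASs:
## minimum-sample filter, nearest-rank 95th-percentile threshold on
## per-protein sample counts, and a recurrence rule for frequent identical
## substitutions.

#' Prioritisation parameters
#'
#' @param min_samples minimum number of distinct samples with a harmful
#'   AAS for a protein to be considered (default 2).
#' @param percentile percentile of the surviving sample counts used as
#'   selection threshold (default 95; nearest-rank method, selection is
#'   strictly above the threshold, i.e. approximately the top 5 %).
#' @param recurrence_fraction fraction of all samples of the cancer type
#'   that one identical substitution must exceed for the recurrence rule
#'   (default 0.02).
#' @param recurrence_gate the recurrence rule applies only when more than
#'   this many samples contain harmful AASs (default 100).
#' @return validated list of class `selection_params`.
#' @export
selectionParams <- function(min_samples = 2L, percentile = 95,
                            recurrence_fraction = 0.02,
                            recurrence_gate = 100L) {
  if (!(percentile > 0 && percentile < 100))
    stop("percentile must be in (0, 100)")
  if (!(recurrence_fraction > 0 && recurrence_fraction < 1))
    stop("recurrence_fraction must be in (0, 1)")
  if (min_samples < 1) stop("min_samples must be >= 1")
  structure(list(min_samples = as.integer(min_samples),
                 percentile = percentile,
                 recurrence_fraction = recurrence_fraction,
                 recurrence_gate = as.integer(recurrence_gate)),
            class = "selection_params")
}

#' Nearest-rank percentile
#'
#' The value at position `ceiling(p/100 * n)` of the sorted sample; no
#' interpolation.
#'
#' @param x numeric vector.
#' @param p percentile in (0, 100).
#' @return the nearest-rank percentile value.
#' @examples
#' nearestRankPercentile(2:100, 95)  # 96
#' @export
nearestRankPercentile <- function(x, p) {
  if (!length(x)) stop("empty vector")
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Per-protein counts of samples containing harmful AASs
#'
#' A sample contributes at most once per protein regardless of how many
#' harmful AASs it carries in it.
#'
#' @param harmful harmful AAS table ([joinHarmful()] output).
#' @param cancer restrict to one cancer type (`NULL` = all rows).
#' @return named integer vector of distinct-sample counts per protein.
#' @export
sampleCounts <- function(harmful, cancer = NULL) {
  if (!is.null(cancer))
    harmful <- harmful[harmful$cancer_type == cancer, , drop = FALSE]
  if (!nrow(harmful)) return(stats::setNames(integer(0), character(0)))
  u <- unique(harmful[, c("protein_id", "sample_id")])
  tab <- table(u$protein_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Select the proteins most affected by harmful AASs in one cancer
#'
#' Proteins with harmful AASs in fewer than `min_samples` samples are
#' eliminated; among the survivors, the nearest-rank 95th percentile of
#' the per-protein sample counts sets the threshold, and proteins with
#' strictly more affected samples are selected (approximately the top
#' 5 %).  When more than `recurrence_gate` samples contain harmful AASs,
#' proteins carrying one identical substitution in more than
#' `recurrence_fraction` of all samples of the cancer type are admitted
#' as well (reason `recurrence`).
#'
#' @param harmful harmful AAS table ([joinHarmful()] output).
#' @param cancer cancer type to select for.
#' @param nSamplesCancer total number of samples of this cancer type in
#'   the cohort (the recurrence denominator).
#' @param params a [selectionParams()] list.
#' @param proteinLengths optional named vector of protein lengths; when
#'   given, a per-residue normalised harmful-AAS frequency column is
#'   added.
#' @return a [SelectionResult-class].
#' @export
selectProteins <- function(harmful, cancer, nSamplesCancer,
                           params = selectionParams(),
                           proteinLengths = NULL) {
  h <- harmful[harmful$cancer_type == cancer, , drop = FALSE]
  counts <- sampleCounts(h)
  n_harm_samples <- length(unique(h$sample_id))
  occ <- table(h$protein_id)
  surv <- counts[counts >= params$min_samples]
  if (!length(surv)) {
    tb <- S4Vectors::DataFrame(protein_id = character(),
                               n_samples = integer(),
                               n_harmful_aas = integer(),
                               selected = logical(), reason = character())
    return(methods::new("SelectionResult", cancerType = cancer, table = tb,
                        threshold = NA_real_,
                        nSamplesCancer = as.integer(nSamplesCancer),
                        nSamplesHarmful = as.integer(n_harm_samples),
                        params = unclass(params)))
  }
  thr <- nearestRankPercentile(surv, params$percentile)
  reason <- ifelse(surv > thr, "percentile", NA_character_)
  ## recurrence rule: one identical harmful substitution in more than
  ## recurrence_fraction of all samples, gated on cohort size
  if (n_harm_samples > params$recurrence_gate && nrow(h)) {
    u <- unique(h[, c("protein_id", "sample_id", "residue_pos",
                      "ref_aa", "alt_aa")])
    sub_key <- paste(u$protein_id, u$residue_pos, u$ref_aa, u$alt_aa)
    per_sub <- table(sub_key)
    rec_subs <- names(per_sub)[per_sub > params$recurrence_fraction *
                                 nSamplesCancer]
    rec_prot <- unique(u$protein_id[match(rec_subs, sub_key)])
    add <- names(surv) %in% rec_prot & is.na(reason)
    reason[add] <- "recurrence"
  }
  o <- order(-surv, names(surv))
  tb <- S4Vectors::DataFrame(
    protein_id = names(surv)[o],
    n_samples = as.integer(unname(surv[o])),
    n_harmful_aas = as.integer(unname(occ[names(surv)[o]])),
    selected = unname(!is.na(reason[o])),
    reason = unname(reason[o]))
  if (!is.null(proteinLengths))
    tb$norm_frequency <- normalizeByLength(
      stats::setNames(tb$n_harmful_aas, tb$protein_id), proteinLengths)
  methods::new("SelectionResult", cancerType = cancer, table = tb,
               threshold = as.numeric(thr),
               nSamplesCancer = as.integer(nSamplesCancer),
               nSamplesHarmful = as.integer(n_harm_samples),
               params = unclass(params))
}

#' Normalise per-protein harmful AAS counts by protein length
#'
#' @param counts named vector of harmful AAS occurrences per protein.
#' @param lengths named vector of protein lengths (residues).
#' @return per-residue frequencies, aligned with `counts`.
#' @examples
#' normalizeByLength(c(P1 = 10), c(P1 = 1000))  # 0.01
#' @export
normalizeByLength <- function(counts, lengths) {
  len <- lengths[names(counts)]
  if (anyNA(len))
    stop("missing protein length(s): ",
         paste(names(counts)[is.na(len)], collapse = ", "))
  if (any(len <= 0)) stop("protein lengths must be positive")
  unname(counts) / unname(len)
}

#' Overlap of a selection with a known cancer-gene list
#'
#' @param selected character vector of selected protein/gene ids.
#' @param geneList character vector of known cancer genes (CGC-like).
#' @return list with `n_overlap`, `known` (selected ids in the list) and
#'   `novel` (the rest).
#' @export
cgcOverlap <- function(selected, geneList) {
  known <- intersect(selected, geneList)
  list(n_overlap = length(known), known = known,
       novel = setdiff(selected, geneList))
}
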