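## Attaching externally predicted harmfulness to AAS records and computing
## evaluation statistics.  The predictor itself is consumed as a file of
## per-substitution probabilities and three-class calls; it is never
## re-implemented here.

.HARM_CLASSES <- c("harmful", "neutral", "unknown")

#' Load a harmfulness prediction table
#'
#' Reads a tab-separated prediction file with header columns `protein_id`,
#' `position`, `ref_aa`, `alt_aa`, `probability` and (optionally) `class`.
#' When the `class` column is absent it is derived from the probability
#' with [classifyByProbability()]; when present, the file's own call takes
#' precedence.  Duplicate substitution keys and out-of-range probabilities
#' are errors that cite the offending line.
#'
#' @param path path to the file.
#' @param low,high probability thresholds used only when the file has no
#'   `class` column.
#' @return data.frame of harmfulness calls.
#' @export
loadPredictions <- function(path, low = 0.05, high = 0.95) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  pred <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "ref_aa", "alt_aa", "probability")
  missing_cols <- setdiff(need, names(pred))
  if (length(missing_cols))
    stop("prediction file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(is.na(pred$probability) | pred$probability < 0 |
                 pred$probability > 1)
  if (length(bad))
    stop("probability out of [0,1] on line ", bad[1] + 1L,
         " of ", path, " (value ", pred$probability[bad[1]], ")")
  key <- paste(pred$protein_id, pred$position, pred$ref_aa, pred$alt_aa)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate substitution key on line ", dup[1] + 1L, " of ", path,
         ": ", key[dup[1]])
  if (!"class" %in% names(pred)) {
    pred$class <- classifyByProbability(pred$probability, low, high)
  } else if (!all(pred$class %in% .HARM_CLASSES)) {
    bad <- which(!pred$class %in% .HARM_CLASSES)[1]
    stop("invalid class on line ", bad + 1L, " of ", path, ": ",
         pred$class[bad])
  }
  pred
}

#' Map a harmfulness probability to a three-class call
#'
#' Probabilities at or above `high` are `harmful`, at or below `low` are
#' `neutral`, anything between is `unknown`.  This threshold rule is a
#' declared approximation of the external predictor's confidence-based
#' classification and is only used when a prediction file carries no class
#' column of its own.
#'
#' @param probability numeric vector in \[0,1\].
#' @param low,high thresholds with `0 <= low < high <= 1`.
#' @return character vector of `harmful` / `neutral` / `unknown`.
#' @examples
#' classifyByProbability(c(0.97, 0.02, 0.5))
#' @export
classifyByProbability <- function(probability, low = 0.05, high = 0.95) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("thresholds must satisfy 0 <= low < high <= 1")
  ifelse(probability >= high, "harmful",
         ifelse(probability <= low, "neutral", "unknown"))
}

#' Join AAS records with harmfulness calls and keep the harmful subset
#'
#' Missense records are matched to predictions on the key
#' (protein, position, reference residue, alternate residue).  Records
#' without a prediction are treated as unknown; unknown and neutral calls
#' are excluded from the returned table (downstream statistics use
#' confidently harmful AASs only).  Sample and cancer columns are carried
#' through.
#'
#' @param aas AAS table from [annotateCatalog()].
#' @param predictions prediction table from [loadPredictions()] (or an
#'   equivalent data.frame).
#' @return the harmful missense records with `probability` and `class`
#'   columns appended; attributes `n_missing` (missense AASs without a
#'   prediction), `n_unknown`, `n_neutral` record what was excluded.
#' @export
joinHarmful <- function(aas, predictions) {
  mis <- aas[aas$consequence == "missense", , drop = FALSE]
  if (!nrow(mis)) {
    out <- cbind(mis, probability = numeric(0), class = character(0))
    attr(out, "n_missing") <- 0L
    attr(out, "n_unknown") <- 0L
    attr(out, "n_neutral") <- 0L
    return(out)
  }
  key_a <- paste(mis$protein_id, mis$residue_pos, mis$ref_aa, mis$alt_aa)
  key_p <- paste(predictions$protein_id, predictions$position,
                 predictions$ref_aa, predictions$alt_aa)
  m <- match(key_a, key_p)
  n_missing <- sum(is.na(m))
  if (n_missing)
    warning(n_missing, " missense AAS(s) without a prediction; ",
            "treated as unknown and excluded")
  cls <- ifelse(is.na(m), "unknown", predictions$class[m])
  out <- mis[cls == "harmful", , drop = FALSE]
  out$probability <- predictions$probability[m][cls == "harmful"]
  out$class <- rep("harmful", nrow(out))
  rownames(out) <- NULL
  attr(out, "n_missing") <- as.integer(n_missing)
  attr(out, "n_unknown") <- as.integer(sum(cls == "unknown") - n_missing)
  attr(out, "n_neutral") <- as.integer(sum(cls == "neutral"))
  out
}

#' Confusion statistics of harmfulness calls on a labelled set
#'
#' For substitutions with known benign/pathogenic labels, computes the
#' false positive rate (predicted harmful among labelled benign) and true
#' positive rate (predicted harmful among labelled pathogenic), each as a
#' percentage of all labelled calls in the class, including unclassified
#' ones.
#'
#' @param class character vector of predicted classes
#'   (`harmful`/`neutral`/`unknown`).
#' @param label parallel character vector of `benign` / `pathogenic`.
#' @return a list with `n_total`, `n_predicted_harmful`,
#'   `n_predicted_neutral`, `n_unclassified`, `fpr_pct` and `tpr_pct`
#'   (percentages; `NA` when the label class is empty).
#' @examples
#' ## 454 labelled-benign AASs of which 87 called harmful -> FPR 19.2 %
#' cls <- rep(c("harmful", "neutral"), c(87, 367))
#' confusionStats(cls, rep("benign", 454))$fpr_pct
#' @export
confusionStats <- function(class, label) {
  if (length(class) != length(label))
    stop("every call needs a label")
  if (!all(class %in% .HARM_CLASSES))
    stop("invalid class value(s)")
  if (!all(label %in% c("benign", "pathogenic")))
    stop("labels must be 'benign' or 'pathogenic'")
  rate <- function(lab) {
    n <- sum(label == lab)
    if (!n) return(NA_real_)
    100 * sum(class == "harmful" & label == lab) / n
  }
  list(n_total = length(class),
       n_predicted_harmful = sum(class == "harmful"),
       n_predicted_neutral = sum(class == "neutral"),
       n_unclassified = sum(class == "unknown"),
       fpr_pct = rate("benign"),
       tpr_pct = rate("pathogenic"))
}

#' Percentage of calls in one class
#'
#' @param class character vector of predicted classes.
#' @param which the class to count (`harmful`, `neutral` or `unknown`).
#' @return percentage of calls in `which`.
#' @examples
#' ## 733 of 1058 validated AASs called harmful -> 69.3 %
#' fractionClass(rep(c("harmful", "neutral", "unknown"),
#'                   c(733, 4, 321)), "harmful")
#' @export
fractionClass <- function(class, which = "harmful") {
  if (!length(class)) stop("no calls supplied")
  which <- match.arg(which, .HARM_CLASSES)
  100 * sum(class == which) / length(class)
}
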