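## Mapping AASs onto protein domain intervals and computing the
## length-normalised domain mutation density.

#' Read a domain annotation table
#'
#' Tab-separated with header `protein_id`, `accession`, `name`, `start`,
#' `end`; protein coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @return data.frame of domain instances.
#' @export
readDomains <- function(path) {
  if (!file.exists(path)) stop("domain file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "accession", "start", "end")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("domain file lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(d$start < 1 | d$end < d$start))
    stop("domain intervals must satisfy 1 <= start <= end")
  d
}

#' Assign AAS records to domain instances
#'
#' An AAS is assigned to every domain instance whose `[start, end]`
#' interval (inclusive) contains its residue position on the same
#' protein.  Overlapping instances yield multiple assignments.
#'
#' @param aas AAS table (needs `protein_id`, `residue_pos`; other columns
#'   are carried through).
#' @param domains domain instance table ([readDomains()] format).
#' @return data.frame of assignments: the AAS columns plus `accession`,
#'   `domain_start`, `domain_end` and `instance_id`.
#' @export
mapAASToDomains <- function(aas, domains) {
  domains$instance_id <- paste(domains$protein_id, domains$accession,
                               domains$start, domains$end, sep = ":")
  hit <- merge(aas, domains[, c("protein_id", "accession", "start", "end",
                                "instance_id")],
               by = "protein_id")
  hit <- hit[hit$residue_pos >= hit$start & hit$residue_pos <= hit$end, ,
             drop = FALSE]
  names(hit)[names(hit) == "start"] <- "domain_start"
  names(hit)[names(hit) == "end"] <- "domain_end"
  rownames(hit) <- NULL
  hit
}

#' Length-normalised domain mutation density
#'
#' For each domain accession, the number of AASs falling inside its
#' instances is divided by the cumulative length of the instances that
#' contain at least one AAS (instances without any AAS contribute nothing
#' to the denominator).  Domains with one or no AAS are dropped.
#'
#' @param aas AAS table (pass the harmful subset for harmful-AAS
#'   densities).
#' @param domains domain instance table.
#' @param cancer restrict to one cancer type (`NULL` = all records).
#' @param uniqueSubstitutions count each distinct substitution once
#'   instead of every occurrence (occurrences are the default).
#' @return data.frame `accession`, `n_aas`, `cumulative_length`,
#'   `normalized_frequency`, sorted by decreasing frequency.
#' @export
domainNormalizedFrequency <- function(aas, domains, cancer = NULL,
                                      uniqueSubstitutions = FALSE) {
  if (!is.null(cancer))
    aas <- aas[aas$cancer_type == cancer, , drop = FALSE]
  if (uniqueSubstitutions && nrow(aas)) {
    key <- paste(aas$protein_id, aas$residue_pos, aas$ref_aa, aas$alt_aa)
    aas <- aas[!duplicated(key), , drop = FALSE]
  }
  empty <- data.frame(accession = character(), n_aas = integer(),
                      cumulative_length = integer(),
                      normalized_frequency = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(aas)) return(empty)
  hits <- mapAASToDomains(aas, domains)
  if (!nrow(hits)) return(empty)
  per_inst <- stats::aggregate(list(n = rep(1L, nrow(hits))),
                               by = list(accession = hits$accession,
                                         instance_id = hits$instance_id,
                                         len = hits$domain_end -
                                           hits$domain_start + 1L),
                               FUN = sum)
  out <- do.call(rbind, lapply(split(per_inst, per_inst$accession),
    function(d) data.frame(accession = d$accession[1],
                           n_aas = as.integer(sum(d$n)),
                           cumulative_length = as.integer(sum(d$len)),
                           stringsAsFactors = FALSE)))
  out <- out[out$n_aas > 1L, , drop = FALSE]
  out$normalized_frequency <- out$n_aas / out$cumulative_length
  out <- out[order(-out$normalized_frequency, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k domains by normalised AAS frequency
#'
#' @param frequencies output of [domainNormalizedFrequency()].
#' @param k number of domains to keep (all when fewer are present).
#' @return the top-k rows; ties at the cut are resolved by the
#'   lexicographically smaller accession.
#' @export
topDomains <- function(frequencies, k = 20L) {
  if (k < 1) stop("k must be >= 1")
  o <- order(-frequencies$normalized_frequency, frequencies$accession)
  out <- frequencies[o, , drop = FALSE][seq_len(min(k, nrow(frequencies))), ,
                                        drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of cancer types in which each domain is mutated
#'
#' @param aas AAS table with `cancer_type`.
#' @param domains domain instance table.
#' @return data.frame `accession`, `n_cancer_types` (domains never hit are
#'   absent).
#' @export
domainCancerPrevalence <- function(aas, domains) {
  hits <- mapAASToDomains(aas, domains)
  if (!nrow(hits))
    return(data.frame(accession = character(), n_cancer_types = integer(),
                      stringsAsFactors = FALSE))
  u <- unique(hits[, c("accession", "cancer_type")])
  out <- stats::aggregate(list(n_cancer_types = rep(1L, nrow(u))),
                          by = list(accession = u$accession), FUN = sum)
  out[order(-out$n_cancer_types, out$accession), , drop = FALSE]
}
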