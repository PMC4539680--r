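## Hypergeometric GO/pathway over-representation with Benjamini-Hochberg
## FDR, the two-tier query policy, and pathway co-membership networks.

#' Read / write gene-set collections in GMT format
#'
#' `readGMT()` wraps [fgsea::gmtPathways()]; `writeGMT()` writes one named
#' set per line (name, description, tab-separated gene ids).
#'
#' @param path file path.
#' @return `readGMT()`: named list of character vectors.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (any(!lengths(sets))) stop("GMT contains an empty set")
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more query genes inside a set of size
#' `K`, for a query of size `n` drawn from a universe of size `N`
#' (one-sided over-representation test).
#'
#' @param k overlap count.
#' @param K gene-set size.
#' @param n query size.
#' @param N universe size.
#' @return `P[X >= k]`.
#' @examples
#' hypergeomP(3, 5, 4, 10)  # 55/210
#' @export
hypergeomP <- function(k, K, n, N) {
  if (any(K > N | n > N | k > pmin(K, n) | k < 0 | K < 0 | n < 0))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment; input order is preserved.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in (0, 1].
#' @export
bhFDR <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Query policy for GO / pathway enrichment
#'
#' Cancers with fewer than `selected_cutoff` selected proteins are queried
#' with all genes containing at least one harmful AAS (GO significance at
#' `go_fdr_small`); the others with the selected genes themselves (GO
#' significance at `go_fdr_large`).  Pathway significance is always
#' `pathway_fdr`.
#'
#' @param selected_cutoff selection-size cutoff (default 20).
#' @param go_fdr_small,go_fdr_large,pathway_fdr FDR tiers.
#' @return a list of class `query_policy`.
#' @export
queryPolicy <- function(selected_cutoff = 20L, go_fdr_small = 0.01,
                        go_fdr_large = 0.001, pathway_fdr = 0.05) {
  structure(list(selected_cutoff = as.integer(selected_cutoff),
                 go_fdr_small = go_fdr_small,
                 go_fdr_large = go_fdr_large,
                 pathway_fdr = pathway_fdr),
            class = "query_policy")
}

#' Build the enrichment query for one cancer
#'
#' @param selectedGenes genes corresponding to the selected proteins.
#' @param harmfulGenes genes containing at least one harmful AAS in the
#'   cancer.
#' @param policy a [queryPolicy()].
#' @return list with `query`, `go_fdr`, `pathway_fdr` and `used`
#'   (`"selected_genes"` or `"harmful_genes"`).
#' @export
buildQuery <- function(selectedGenes, harmfulGenes,
                       policy = queryPolicy()) {
  if (length(selectedGenes) < policy$selected_cutoff) {
    list(query = unique(harmfulGenes), go_fdr = policy$go_fdr_small,
         pathway_fdr = policy$pathway_fdr, used = "harmful_genes")
  } else {
    list(query = unique(selectedGenes), go_fdr = policy$go_fdr_large,
         pathway_fdr = policy$pathway_fdr, used = "selected_genes")
  }
}

#' Hypergeometric over-representation of gene sets
#'
#' Tests each set of the collection for over-representation of the query
#' (classic one-sided hypergeometric), adjusts with Benjamini-Hochberg
#' within the tested family, and flags significance at `fdr`.  Only terms
#' overlapping the query (`k >= 1`) are reported.
#'
#' @param query character vector of gene ids; ids outside the universe
#'   are dropped with a warning.
#' @param collection named list of gene sets (e.g. from [readGMT()]).
#' @param fdr significance tier.
#' @param universe gene universe; defaults to the union of all sets in
#'   the collection.
#' @return data.frame `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, ordered by `p`.
#' @export
enrichTerms <- function(query, collection, fdr = 0.05, universe = NULL) {
  if (!length(collection)) stop("empty gene-set collection")
  if (is.null(universe)) universe <- unique(unlist(collection))
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  drop <- setdiff(query, universe)
  if (length(drop))
    warning(length(drop), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  n <- length(query); N <- length(universe)
  k <- vapply(collection, function(s) length(intersect(s, query)),
              integer(1))
  K <- vapply(collection, function(s) length(intersect(s, universe)),
              integer(1))
  keep <- k >= 1L
  out <- data.frame(term = names(collection)[keep], k = k[keep],
                    K = K[keep], n = rep(n, sum(keep)),
                    N = rep(N, sum(keep)),
                    p = hypergeomP(k[keep], K[keep], n, N),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    out$q <- bhFDR(out$p)
    out$significant <- out$q < fdr
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$q <- numeric(0); out$significant <- logical(0)
  }
  out
}

#' Pathway co-membership network
#'
#' Nodes are significant pathways; two pathways are connected when they
#' share selected proteins, with the edge weight equal to the number of
#' shared selected proteins.
#'
#' @param terms character vector of significant pathway names.
#' @param collection named list of gene sets.
#' @param selectedGenes genes/proteins of interest (typically the
#'   selection of one cancer).
#' @return an [igraph::graph] with edge attribute `weight`.
#' @export
pathwayComembershipNetwork <- function(terms, collection, selectedGenes) {
  if (!all(terms %in% names(collection)))
    stop("unknown term(s): ",
         paste(setdiff(terms, names(collection)), collapse = ", "))
  members <- lapply(collection[terms], intersect, y = selectedGenes)
  g <- igraph::make_empty_graph(n = length(terms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = terms)
  if (length(terms) >= 2) {
    pairs <- utils::combn(seq_along(terms), 2)
    w <- apply(pairs, 2, function(ij)
      length(intersect(members[[ij[1]]], members[[ij[2]]])))
    keep <- w > 0
    if (any(keep))
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]),
                             weight = w[keep])
  }
  g
}
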