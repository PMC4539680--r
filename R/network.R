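## Functional-interaction-network reduction, the average-degree statistic,
## module detection, and cross-cancer overlap networks.

#' Read an interaction network from a SIF or 2-column edge list
#'
#' Accepts simple interaction format (`node1 type node2`) or a 2-column
#' tab-separated edge list.  Self-loops and duplicate edges are dropped at
#' load; the numbers removed are recorded in the graph attributes
#' `n_self_loops` and `n_duplicates`.
#'
#' @param path file path.
#' @return an undirected simple [igraph::graph].
#' @export
readSIF <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(!nf %in% c(2L, 3L)))
    stop("malformed network line ", which(!nf %in% c(2L, 3L))[1])
  from <- vapply(parts, `[`, character(1), 1L)
  to <- vapply(parts, function(x) x[length(x)], character(1))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  n_dup <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "n_self_loops", n_loops)
  igraph::set_graph_attr(g, "n_duplicates", n_dup)
}

#' @rdname readSIF
#' @param g an [igraph::graph].
#' @param interaction interaction type written in the middle column.
#' @export
writeSIF <- function(g, path, interaction = "interacts") {
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1], interaction, el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Reduce a network to proteins of interest and their first neighbours
#'
#' Keeps the selected proteins, the proteins with harmful AASs, and every
#' first neighbour of either set; all other nodes are removed and only
#' induced edges remain.
#'
#' @param g the full interaction network.
#' @param selected character vector of selected protein ids.
#' @param harmful character vector of proteins containing harmful AASs.
#' @return the induced subgraph.  Ids absent from the network are dropped
#'   with a warning; an empty result is returned (with a warning), not an
#'   error.
#' @export
reduceNetwork <- function(g, selected, harmful = character()) {
  seeds <- unique(c(selected, harmful))
  missing_ids <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing_ids))
    warning(length(missing_ids), " id(s) not present in the network")
  seeds <- setdiff(seeds, missing_ids)
  if (!length(seeds)) {
    warning("reduced network is empty")
    return(igraph::induced_subgraph(g, integer(0)))
  }
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, seeds),
                             igraph::as_ids)))
  keep <- union(seeds, nb)
  igraph::induced_subgraph(g, keep)
}

#' Average degree of a node set within the full network
#'
#' Computes `D_n = (2 * E_n + E_other) / n`, where `E_n` is the number of
#' edges connecting two nodes of the set (each contributes to the degree
#' of both endpoints, hence the factor 2) and `E_other` the number of
#' edges connecting the set to the rest of the network.  For the whole
#' network `E_other = 0` and the statistic reduces to `2 |E| / |V|`.
#' Both edge counts are evaluated on the graph passed in, so pass the
#' full (unreduced) network to reproduce whole-network comparisons.
#'
#' @param subset character vector of node ids (ids absent from the graph
#'   are dropped with a warning); `NULL` evaluates the whole network.
#' @param g an undirected [igraph::graph].
#' @return list with `n`, `e_within`, `e_other` and `average_degree`.
#' @export
averageDegree <- function(subset = NULL, g) {
  if (is.null(subset)) subset <- igraph::V(g)$name
  missing_ids <- setdiff(subset, igraph::V(g)$name)
  if (length(missing_ids))
    warning(length(missing_ids), " id(s) not present in the network")
  subset <- intersect(unique(subset), igraph::V(g)$name)
  if (!length(subset)) stop("empty node subset")
  el <- igraph::as_edgelist(g)
  in1 <- el[, 1] %in% subset
  in2 <- el[, 2] %in% subset
  e_within <- sum(in1 & in2)
  e_other <- sum(xor(in1, in2))
  list(n = length(subset), e_within = e_within, e_other = e_other,
       average_degree = degreeFromCounts(length(subset), e_within, e_other))
}

#' Average degree from edge counts
#'
#' The bare equation `(2 * e_within + e_other) / n`, for use when the
#' edge counts are known without materialising the graph (e.g. published
#' network sizes).
#'
#' @param n number of nodes in the set.
#' @param e_within edges with both endpoints in the set.
#' @param e_other edges with exactly one endpoint in the set (0 for a
#'   whole network).
#' @return the average degree.
#' @examples
#' degreeFromCounts(10706, 171449)  # 32.0: a full published network
#' @export
degreeFromCounts <- function(n, e_within, e_other = 0) {
  if (n <= 0) stop("n must be positive")
  (2 * e_within + e_other) / n
}

#' Cluster a network into modules
#'
#' Greedy modularity maximisation ([igraph::cluster_fast_greedy()]) with a
#' fixed seed, as a documented, pluggable stand-in for unspecified
#' clustering tools.  Every node receives exactly one module id.
#'
#' @param g an undirected simple graph.
#' @param seed integer seed for determinism.
#' @return named integer vector of module memberships.
#' @export
clusterModules <- function(g, seed = 1L) {
  if (!igraph::vcount(g)) stop("empty graph")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  cm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  stats::setNames(as.integer(igraph::membership(cm)), igraph::V(g)$name)
}

#' Cross-cancer overlap networks
#'
#' Cancers are split into those with more than `splitCutoff` selected
#' proteins and the rest; within each group a network is built with one
#' node per cancer (attributes: number of significant pathways, number of
#' selected proteins) and an edge wherever two cancers share at least one
#' significant pathway (attributes: `n_common_pathways`,
#' `n_common_proteins`).
#'
#' @param pathwaysByCancer named list: significant pathway names per
#'   cancer.
#' @param proteinsByCancer named list: selected proteins per cancer.
#' @param splitCutoff selection-size split (default 20).
#' @return list of two [igraph::graph]s, `high` (> cutoff) and `low`.
#' @export
cancerOverlap <- function(pathwaysByCancer, proteinsByCancer,
                          splitCutoff = 20L) {
  cancers <- names(pathwaysByCancer)
  if (length(cancers) < 2) stop("need at least two cancers")
  if (!setequal(cancers, names(proteinsByCancer)))
    stop("pathway and protein lists must cover the same cancers")
  high <- cancers[lengths(proteinsByCancer)[cancers] > splitCutoff]
  build <- function(cc) {
    g <- igraph::make_empty_graph(n = length(cc), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = cc)
    g <- igraph::set_vertex_attr(g, "n_pathways",
                                 value = lengths(pathwaysByCancer)[cc])
    g <- igraph::set_vertex_attr(g, "n_proteins",
                                 value = lengths(proteinsByCancer)[cc])
    if (length(cc) >= 2) {
      pairs <- utils::combn(seq_along(cc), 2)
      np <- apply(pairs, 2, function(ij) length(intersect(
        pathwaysByCancer[[cc[ij[1]]]], pathwaysByCancer[[cc[ij[2]]]])))
      npr <- apply(pairs, 2, function(ij) length(intersect(
        proteinsByCancer[[cc[ij[1]]]], proteinsByCancer[[cc[ij[2]]]])))
      keep <- np >= 1
      if (any(keep)) {
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
        g <- igraph::set_edge_attr(g, "n_common_pathways", value = np[keep])
        g <- igraph::set_edge_attr(g, "n_common_proteins", value = npr[keep])
      }
    }
    g
  }
  list(high = build(high), low = build(setdiff(cancers, high)))
}
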