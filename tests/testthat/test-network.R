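## Network reduction, the average-degree equation, module detection and
## cross-cancer overlap networks.

mkGraph <- function(edges, isolated = character()) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

test_that("reduction keeps seeds and their first neighbours only", {
  star <- mkGraph(c("hub", "a", "hub", "b", "hub", "c"))
  red <- reduceNetwork(star, "hub")
  expect_setequal(igraph::V(red)$name, c("hub", "a", "b", "c"))

  lone <- mkGraph(c("x", "y"), isolated = "solo")
  red2 <- reduceNetwork(lone, "solo")
  expect_identical(igraph::V(red2)$name, "solo")
  expect_equal(igraph::ecount(red2), 0)

  path <- mkGraph(c("a", "b", "b", "c", "c", "d"))
  red3 <- reduceNetwork(path, "a")
  expect_setequal(igraph::V(red3)$name, c("a", "b"))
  expect_equal(igraph::ecount(red3), 1)

  expect_warning(expect_warning(reduceNetwork(path, "nope"),
                                "not present"), "empty")
  expect_warning(expect_equal(igraph::vcount(
    reduceNetwork(path, character())), 0), "empty")
})

test_that("reduction is idempotent", {
  set.seed(61)
  g <- igraph::sample_gnp(60, 0.08)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", 1:60))
  sel <- sprintf("n%02d", sample(60, 5))
  r1 <- reduceNetwork(g, sel)
  r2 <- reduceNetwork(r1, intersect(sel, igraph::V(r1)$name))
  expect_setequal(igraph::V(r1)$name, igraph::V(r2)$name)
  expect_identical(igraph::ecount(r1), igraph::ecount(r2))
})

test_that("the average-degree equation counts within and crossing edges", {
  tri <- mkGraph(c("a", "b", "b", "c", "a", "c"))
  d <- averageDegree(c("a", "b"), tri)
  expect_identical(d$e_within, 1L)
  expect_identical(d$e_other, 2L)
  expect_identical(d$average_degree, 2)

  solo <- mkGraph(c("a", "b"), isolated = "z")
  expect_identical(averageDegree("z", solo)$average_degree, 0)
  expect_error(averageDegree(character(), tri), "empty")

  ## printed full-network size: 10,706 nodes, 171,449 edges -> 32.0
  expect_identical(round(degreeFromCounts(10706, 171449), 1), 32)
})

test_that("whole-network degree identities hold on random graphs", {
  set.seed(62)
  g <- igraph::sample_gnp(80, 0.1)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", 1:80))
  d <- averageDegree(NULL, g)
  expect_identical(d$e_other, 0L)
  expect_equal(d$average_degree, 2 * igraph::ecount(g) / igraph::vcount(g))
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  ## crossing edges counted from the complement agree
  sub <- sprintf("n%02d", sample(80, 20))
  comp <- setdiff(igraph::V(g)$name, sub)
  expect_identical(averageDegree(sub, g)$e_other,
                   averageDegree(comp, g)$e_other)
})

test_that("module detection separates two cliques joined by one edge", {
  edges <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    edges <- c(edges, paste0("a", i), paste0("a", j),
               paste0("b", i), paste0("b", j))
  }
  g <- mkGraph(c(edges, "a1", "b1"))
  memb <- clusterModules(g, seed = 1)
  expect_identical(length(unique(memb)), 2L)
  expect_identical(length(unique(memb[paste0("a", 1:5)])), 1L)
  expect_identical(length(unique(memb[paste0("b", 1:5)])), 1L)
  expect_false(memb[["a1"]] == memb[["b1"]])

  single <- mkGraph(character(0), isolated = "only")
  expect_identical(unname(clusterModules(single)), 1L)
  ## deterministic under a fixed seed
  expect_identical(clusterModules(g, seed = 9), clusterModules(g, seed = 9))
})

test_that("modules recover the planted pathway communities", {
  ari <- vapply(1:10, function(s) {
    cfg <- smallConfig(seed = s, n_genes = 60L, pathway_size = 10L,
                       network_density = 0.01,
                       within_pathway_density = 0.7)
    genes <- generateGenes(cfg)
    co <- generateCohort(cfg, genes)
    sets <- generateGenesetsAndNetwork(genes, co$truth, cfg)
    memb <- clusterModules(sets$network, seed = 1)
    truth <- sets$pathway_membership[names(memb)]
    keep <- !is.na(truth)
    igraph::compare(memb[keep], truth[keep], method = "adjusted.rand")
  }, numeric(1))
  expect_gt(mean(ari), 0.5)
})

test_that("cancer overlap networks split at the selection cutoff and weight edges", {
  pw <- list(c1 = sprintf("P%d", 1:7), c2 = sprintf("P%d", 1:7),
             c3 = c("X1", "X2"), c4 = c("Y1"))
  prot <- list(c1 = sprintf("g%02d", 1:30), c2 = sprintf("g%02d", 11:45),
               c3 = sprintf("h%02d", 1:5), c4 = sprintf("k%02d", 1:3))
  ov <- cancerOverlap(pw, prot, splitCutoff = 20)
  expect_setequal(igraph::V(ov$high)$name, c("c1", "c2"))
  expect_setequal(igraph::V(ov$low)$name, c("c3", "c4"))
  ## identical 7-pathway sets: one edge of weight 7
  expect_equal(igraph::ecount(ov$high), 1)
  expect_identical(igraph::E(ov$high)$n_common_pathways, 7L)
  expect_identical(igraph::E(ov$high)$n_common_proteins, 20L)
  ## disjoint pathway sets: no edge
  expect_equal(igraph::ecount(ov$low), 0)
  expect_identical(igraph::V(ov$high)$n_pathways,
                   c(7L, 7L))
  expect_error(cancerOverlap(pw[1], prot[1]), "two cancers")
})

test_that("overlap edge weights equal brute-force set intersections", {
  cfg <- smallConfig(seed = 23, n_cancers = 4L)
  genes <- generateGenes(cfg)
  co <- generateCohort(cfg, genes)
  pw <- co$truth$driver_pathways
  prot <- co$truth$drivers
  ov <- cancerOverlap(pw, prot, splitCutoff = 2)
  g <- ov$high
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      eid <- igraph::get_edge_ids(g, c(a, b))
      expect_identical(igraph::E(g)$n_common_pathways[eid],
                       length(intersect(pw[[a]], pw[[b]])))
      expect_identical(igraph::E(g)$n_common_proteins[eid],
                       length(intersect(prot[[a]], prot[[b]])))
    }
  }
  ## every non-edge pair shares no pathway
  cc <- igraph::V(g)$name
  for (a in cc) for (b in cc) if (a < b) {
    if (igraph::get_edge_ids(g, c(a, b)) == 0)
      expect_identical(length(intersect(pw[[a]], pw[[b]])), 0L)
  }
})

test_that("SIF files round-trip with loops and duplicates removed", {
  f <- tempfile(fileext = ".sif")
  writeLines(c("a\tpp\tb", "b\tpp\ta", "a\tpp\ta", "b\tpp\tc"), f)
  g <- readSIF(f)
  expect_equal(igraph::ecount(g), 2)
  expect_false(any(igraph::which_loop(g)))
  expect_identical(igraph::graph_attr(g, "n_self_loops"), 1L)
  f2 <- tempfile(fileext = ".sif")
  writeSIF(g, f2)
  g2 <- readSIF(f2)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})
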