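toyEdges <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(part_a = r[[1]], module_a = r[[2]],
               part_b = r[[3]], module_b = r[[4]],
               weight = if (length(r) > 4) r[[5]] else 1)))
}

test_that("triangle enumeration finds exactly the cross-part cliques", {
  e <- toyEdges(list(list("M", "M1", "P", "P1"),
                     list("P", "P1", "H", "H1"),
                     list("M", "M1", "H", "H1"),
                     list("M", "M2", "P", "P2")))
  g <- graphFromEdges(e, c("M", "P", "H"))
  tris <- enumerateTriangles(g)
  expect_identical(nrow(triangleMembers(tris)), 1L)
  expect_identical(unname(triangleMembers(tris)[1, ]), c("M1", "P1", "H1"))
})

test_that("triangle enumeration matches brute force on random tripartite graphs", {
  set.seed(23)
  for (i in 1:60) {
    e <- randomTripartiteEdges(sample(2:8, 1))
    if (!nrow(e)) next
    g <- graphFromEdges(e, c("A", "B", "C"))
    got <- triangleMembers(enumerateTriangles(g))
    want <- bruteTriangles(e, c("A", "B", "C"))
    expect_identical(unname(got), unname(want))
  }
})

test_that("triangle-graph adjacency marks exactly shared information edges", {
  e <- toyEdges(list(list("M", "M1", "P", "P1", 0.4),
                     list("M", "M1", "H", "H1", 0.3),
                     list("P", "P1", "H", "H1", 0.2),
                     list("M", "M1", "H", "H2", 0.1),
                     list("P", "P1", "H", "H2", 0.1)))
  g <- graphFromEdges(e, c("M", "P", "H"))
  tris <- enumerateTriangles(g)
  expect_identical(nrow(triangleMembers(tris)), 2L)
  tg <- buildTriangleGraph(tris, g)
  expect_equal(igraph::ecount(tg), 1)
  # shared edge is M1-P1, so shared-w weight = 0.4
  expect_equal(igraph::E(tg)$weight, 0.4)
  tgb <- buildTriangleGraph(tris, g, weightMode = "binary")
  expect_equal(igraph::E(tgb)$weight, 1)
})

test_that("vertex-disjoint triangles are unconnected in the triangle graph", {
  e <- toyEdges(list(list("M", "M1", "P", "P1"), list("P", "P1", "H", "H1"),
                     list("M", "M1", "H", "H1"),
                     list("M", "M2", "P", "P2"), list("P", "P2", "H", "H2"),
                     list("M", "M2", "H", "H2")))
  g <- graphFromEdges(e, c("M", "P", "H"))
  tg <- buildTriangleGraph(enumerateTriangles(g), g)
  expect_equal(igraph::ecount(tg), 0)
})

test_that("triangle-graph adjacency matches exhaustive pairwise comparison", {
  set.seed(29)
  for (i in 1:20) {
    e <- randomTripartiteEdges(sample(3:6, 1), pEdge = 0.5)
    g <- graphFromEdges(e, c("A", "B", "C"))
    tris <- enumerateTriangles(g)
    m <- triangleMembers(tris)
    if (nrow(m) < 2) next
    tg <- buildTriangleGraph(tris, g)
    adj <- igraph::as_adjacency_matrix(tg, sparse = FALSE) > 0
    for (x in seq_len(nrow(m) - 1)) for (y in seq((x + 1), nrow(m))) {
      shares <- sum(m[x, ] == m[y, ]) >= 2
      expect_identical(unname(adj[x, y]), shares)
    }
  }
})

test_that("communities never span disconnected triangle-graph components", {
  set.seed(37)
  for (i in 1:10) {
    e <- randomTripartiteEdges(5, pEdge = 0.4)
    g <- graphFromEdges(e, c("A", "B", "C"))
    tris <- enumerateTriangles(g)
    if (nrow(triangleMembers(tris)) < 2) next
    tg <- buildTriangleGraph(tris, g)
    comp <- igraph::components(tg)$membership
    memb <- communityMembership(detectCommunities(tg))
    # a community id must map to exactly one component
    expect_true(all(tapply(comp, memb, function(x) length(unique(x))) == 1))
  }
})

test_that("an isolated triangle forms a singleton community", {
  e <- toyEdges(list(list("M", "M1", "P", "P1"), list("P", "P1", "H", "H1"),
                     list("M", "M1", "H", "H1")))
  g <- graphFromEdges(e, c("M", "P", "H"))
  comms <- detectCommunities(buildTriangleGraph(enumerateTriangles(g), g))
  expect_identical(communityMembership(comms), 1L)
  expect_identical(length(communityModules(comms)), 1L)
})

test_that("planted two-block triangle graphs are recovered exactly", {
  # two 6-triangle blocks: dense weight-1.0 within, a single 0.01 bridge
  blockTris <- function(tag) {
    members <- cbind(A = paste0(tag, "A", c(1, 1, 1, 1, 1, 1)),
                     B = paste0(tag, "B", c(1, 1, 2, 2, 3, 3)),
                     C = paste0(tag, "C", c(1, 2, 1, 2, 1, 2)))
    members
  }
  members <- rbind(blockTris("x"), blockTris("y"))
  tris <- new("TriangleSet", parts = c("A", "B", "C"), members = members,
              overlap = replicate(nrow(members), character(), simplify = FALSE))
  recoveries <- vapply(1:50, function(s) {
    set.seed(s)
    tg <- igraph::make_empty_graph(12, directed = FALSE)
    igraph::V(tg)$name <- sprintf("T%d", 1:12)
    within <- rbind(t(combn(1:6, 2)), t(combn(7:12, 2)))
    tg <- igraph::add_edges(tg, t(within), weight = 1.0)
    tg <- igraph::add_edges(tg, c(sample(1:6, 1), sample(7:12, 1)),
                            weight = 0.01)
    tg$triangles <- tris
    memb <- communityMembership(detectCommunities(tg, seed = s))
    length(unique(memb)) == 2 &&
      length(unique(memb[1:6])) == 1 && length(unique(memb[7:12])) == 1
  }, logical(1))
  expect_true(all(recoveries))
})

test_that("consensus cluster is the within-dataset union intersected across datasets", {
  parts <- list(
    M = GenePartition("M", c(g1 = "m1", g2 = "m1", g3 = "m1", g4 = "m1",
                             g5 = "m1")),
    P = GenePartition("P", c(g1 = "p1", g2 = "p1", g3 = "p2", g6 = "p2")),
    H = GenePartition("H", c(g1 = "h1", g2 = "h1", g3 = "h1", g4 = "h1")))
  cc <- consensusCluster(list(M = "m1", P = c("p1", "p2"), H = "h1"), parts)
  expect_identical(cc, c("g1", "g2", "g3"))

  # identity case: one identical module everywhere
  ident <- lapply(c("X", "Y", "Z"), function(d)
    GenePartition(d, c(a = "m", b = "m", c = "m")))
  expect_identical(consensusCluster(list(X = "m", Y = "m", Z = "m"), ident),
                   c("a", "b", "c"))

  # one dataset's union disjoint from another's: empty consensus is legal
  disj <- list(GenePartition("X", c(a = "m")), GenePartition("Y", c(b = "m")),
               GenePartition("Z", c(a = "m", b = "m")))
  expect_identical(consensusCluster(list(X = "m", Y = "m", Z = "m"), disj),
                   character())

  expect_error(consensusCluster(list(M = "m1", P = "p1"), parts),
               "cannot intersect")
})

test_that("extracted consensus clusters are disjoint with faithful provenance", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:100)
  asg <- setNames(sample(paste0("m", 1:5), 100, replace = TRUE), genes)
  parts <- lapply(c("X", "Y", "Z"), function(d) GenePartition(d, asg))
  ig <- buildInformationGraph(parts)
  comms <- detectCommunities(buildTriangleGraph(enumerateTriangles(ig), ig))
  ccs <- extractConsensus(comms, parts)
  cl <- consensusClusters(ccs)
  # identical partitions: the consensus clusters are exactly the modules
  expect_identical(sort(unlist(cl, use.names = FALSE)), genes)
  expect_identical(sort(lengths(cl)), sort(lengths(split(genes, asg))),
                   ignore_attr = TRUE)
  prov <- ccs@provenance
  expect_identical(sort(unique(prov$dataset)), c("X", "Y", "Z"))
  i <- sample(nrow(prov), 25)
  expect_identical(unname(asg[prov$gene[i]]), prov$module[i])
})

test_that("conserved-module counts equal the distinct triangle member nodes", {
  set.seed(43)
  spec <- syntheticSpec(blocks = data.frame(
    block = c("B1", "B2", "B3"), size = 40,
    mode = c("conserved", "split:3", "conserved")), nGenes = 500)
  gen <- generatePartitions(spec, seed = 9)
  ig <- buildInformationGraph(gen$partitions)
  tris <- enumerateTriangles(ig)
  comms <- detectCommunities(buildTriangleGraph(tris, ig))
  ccs <- extractConsensus(comms, gen$partitions)
  st <- consensusStats(ccs)
  m <- triangleMembers(tris)
  nodeCount <- sum(vapply(colnames(m), function(p)
    length(unique(m[, p])), integer(1)))
  expect_identical(sum(st$conservedModules), nodeCount)
})
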