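.nodeId <- function(part, module) paste(part, module, sep = ":")

.edgeKey <- function(pa, ma, pb, mb) {
  a <- .nodeId(pa, ma); b <- .nodeId(pb, mb)
  ifelse(a < b, paste(a, b, sep = "||"), paste(b, a, sep = "||"))
}

#' Enumerate conserved-module triangles in the information graph
#'
#' A triangle — generally, a cross-all-parts k-clique — takes one module from
#' every dataset, all pairwise linked by supra-threshold overlaps, and marks a
#' module conserved across all datasets.  All such cliques are enumerated and
#' returned in canonical (lexicographic by dataset, then module label) order,
#' together with each triangle's triple-overlap gene set, the intersection of
#' all member modules.
#'
#' @param g an [InformationGraph-class] with at least three parts.  A
#'   two-part graph has no triangles; treat its edges directly as conserved
#'   module pairs instead.
#' @return a [TriangleSet-class].
#' @export
enumerateTriangles <- function(g) {
  stopifnot(is(g, "InformationGraph"))
  parts <- graphParts(g)
  k <- length(parts)
  if (k < 3L)
    stop("information graph has only two parts; treat its edges as ",
         "conserved module pairs rather than enumerating triangles")
  e <- graphEdges(g)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(e)))
    assign(.edgeKey(e$part_a[i], e$module_a[i], e$part_b[i], e$module_b[i]),
           TRUE, envir = keys)
  hasEdge <- function(pa, ma, pb, mb)
    exists(.edgeKey(pa, ma, pb, mb), envir = keys)
  nodesPerPart <- lapply(parts, function(p)
    sort(unique(c(e$module_a[e$part_a == p], e$module_b[e$part_b == p]))))
  names(nodesPerPart) <- parts
  found <- list()
  extend <- function(chosen) {
    d <- length(chosen) + 1L
    if (d > k) {
      found[[length(found) + 1L]] <<- chosen
      return(invisible())
    }
    for (m in nodesPerPart[[parts[d]]]) {
      ok <- TRUE
      for (j in seq_len(d - 1L)) {
        if (!hasEdge(parts[j], chosen[j], parts[d], m)) { ok <- FALSE; break }
      }
      if (ok) extend(c(chosen, m))
    }
  }
  extend(character())
  members <- if (length(found)) do.call(rbind, found)
             else matrix(character(), ncol = k)
  colnames(members) <- parts
  if (nrow(members) > 1L) {
    ord <- do.call(order, as.data.frame(members))
    members <- members[ord, , drop = FALSE]
  }
  modsByPart <- lapply(g@partitions, modules)
  overlap <- lapply(seq_len(nrow(members)), function(i)
    sort(Reduce(intersect,
                lapply(parts, function(p) modsByPart[[p]][[members[i, p]]]))))
  new("TriangleSet", parts = parts, members = members, overlap = overlap)
}

#' Build the weighted triangle graph
#'
#' Nodes are the triangles of the information graph; two triangles are joined
#' exactly when they share at least one information-graph edge, i.e. when they
#' agree on the module in at least two datasets.  With the default
#' `"shared-w"` weighting, each triangle-graph edge carries the sum of the
#' W-scores of the shared information-graph edges; `"binary"` sets all weights
#' to 1.
#'
#' @param tris a [TriangleSet-class] from [enumerateTriangles()].
#' @param g the [InformationGraph-class] the triangles came from.
#' @param weightMode `"shared-w"` (default) or `"binary"`.
#' @return an [igraph::igraph] graph whose vertices `T1..Tn` index the rows of
#'   `triangleMembers(tris)` and whose graph attribute `triangles` holds
#'   `tris`.
#' @export
buildTriangleGraph <- function(tris, g, weightMode = c("shared-w", "binary")) {
  weightMode <- match.arg(weightMode)
  stopifnot(is(tris, "TriangleSet"), is(g, "InformationGraph"))
  parts <- tris@parts
  m <- tris@members
  n <- nrow(m)
  e <- graphEdges(g)
  wByKey <- stats::setNames(
    e$weight, .edgeKey(e$part_a, e$module_a, e$part_b, e$module_b))
  from <- integer(); to <- integer(); wt <- numeric()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        agree <- which(m[i, ] == m[j, ])
        if (length(agree) >= 2L) {
          w <- 0
          for (a in seq_len(length(agree) - 1L))
            for (b in seq((a + 1L), length(agree))) {
              pa <- parts[agree[a]]; pb <- parts[agree[b]]
              w <- w + wByKey[[.edgeKey(pa, m[i, agree[a]],
                                        pb, m[i, agree[b]])]]
            }
          from <- c(from, i); to <- c(to, j)
          wt <- c(wt, if (weightMode == "binary") 1 else w)
        }
      }
    }
  }
  tg <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(tg)$name <- sprintf("T%d", seq_len(n))
  if (length(from))
    tg <- igraph::add_edges(tg, rbind(from, to), weight = wt)
  tg$triangles <- tris
  tg
}

#' Detect communities of triangles
#'
#' Clusters the weighted triangle graph by greedy modularity maximization
#' (Clauset-Newman-Moore).  Every triangle lands in exactly one community;
#' isolated triangles become singleton communities; module nodes of the
#' information graph may appear in several communities, but the consensus
#' gene sets derived from the communities are still disjoint.  Communities
#' are numbered deterministically by decreasing triangle count, ties broken by
#' the smallest canonical triangle index.
#'
#' @param tg a triangle graph from [buildTriangleGraph()].
#' @param seed accepted for interface stability; the greedy algorithm is
#'   deterministic given the canonical triangle ordering, so the seed is not
#'   consumed.
#' @return a [CommunitySet-class].
#' @export
detectCommunities <- function(tg, seed = NULL) {
  tris <- tg$triangles
  stopifnot(is(tris, "TriangleSet"))
  n <- nrow(tris@members)
  if (n == 0L)
    return(new("CommunitySet", triangles = tris, membership = integer(),
               modules = list()))
  memb <- if (igraph::ecount(tg) == 0L) seq_len(n)
          else as.integer(igraph::membership(
                 igraph::cluster_fast_greedy(tg,
                   weights = igraph::E(tg)$weight)))
  sizes <- tabulate(memb)
  firstIdx <- vapply(seq_along(sizes), function(cid)
    min(which(memb == cid)), integer(1))
  rank <- order(-sizes, firstIdx)
  relabel <- integer(length(sizes))
  relabel[rank] <- seq_along(sizes)
  memb <- relabel[memb]
  mods <- lapply(seq_len(max(memb)), function(cid) {
    rows <- tris@members[memb == cid, , drop = FALSE]
    stats::setNames(lapply(tris@parts, function(p)
      sort(unique(rows[, p]))), tris@parts)
  })
  new("CommunitySet", triangles = tris, membership = memb, modules = mods)
}

#' Consensus gene set of one community
#'
#' The genes conserved by a community of triangles: within each dataset, take
#' the union of that community's modules; then intersect the unions across
#' datasets.  A gene is a consensus gene exactly when it sits in a community
#' module of every dataset.
#'
#' @param communityModuleList named list, dataset id -> character vector of
#'   that community's module labels (one element of [communityModules()]).
#' @param partitions named list of [GenePartition-class] objects covering
#'   every dataset in the community.
#' @return sorted character vector of consensus genes (possibly empty).
#' @examples
#' parts <- list(
#'   M = GenePartition("M", c(g1="m1",g2="m1",g3="m1",g4="m1",g5="m1")),
#'   P = GenePartition("P", c(g1="p1",g2="p1",g3="p2",g6="p2")),
#'   H = GenePartition("H", c(g1="h1",g2="h1",g3="h1",g4="h1")))
#' consensusCluster(list(M="m1", P=c("p1","p2"), H="h1"), parts)  # g1 g2 g3
#' @export
consensusCluster <- function(communityModuleList, partitions) {
  ids <- vapply(partitions, datasetId, character(1))
  names(partitions) <- ids
  missing <- setdiff(names(communityModuleList), ids)
  if (length(missing))
    stop("no partition supplied for dataset ", missing[1L])
  if (!all(ids %in% names(communityModuleList)))
    stop("community has no module in dataset ",
         setdiff(ids, names(communityModuleList))[1L],
         "; cannot intersect across datasets")
  unions <- lapply(ids, function(d) {
    mods <- modules(partitions[[d]])
    unlist(mods[communityModuleList[[d]]], use.names = FALSE)
  })
  sort(Reduce(intersect, unions))
}

#' Extract all disjoint consensus clusters
#'
#' Applies [consensusCluster()] to every community, verifies the pairwise
#' disjointness that the construction guarantees (a consensus gene occupies
#' exactly one module per dataset, and modules within a dataset do not
#' overlap), and records per-gene provenance plus summary counts: per-dataset
#' conserved-module counts (modules present in at least one triangle), the
#' total consensus gene count, and the number of genes in triple overlaps.
#'
#' @param communities a [CommunitySet-class] from [detectCommunities()].
#' @param partitions named list of [GenePartition-class] objects.
#' @return a [ConsensusClusterSet-class]; clusters are keyed `CC1..CCn` in
#'   community order.
#' @export
extractConsensus <- function(communities, partitions) {
  stopifnot(is(communities, "CommunitySet"))
  ids <- vapply(partitions, datasetId, character(1))
  names(partitions) <- ids
  mods <- communityModules(communities)
  clusters <- lapply(mods, consensusCluster, partitions = partitions)
  names(clusters) <- sprintf("CC%d", seq_along(clusters))
  genes <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(genes))
    stop("internal consistency failure: consensus clusters overlap at gene '",
         genes[duplicated(genes)][1L], "'")
  prov <- if (length(genes)) {
    do.call(rbind, lapply(names(clusters), function(cc) {
      gs <- clusters[[cc]]
      if (!length(gs)) return(NULL)
      do.call(rbind, lapply(ids, function(d)
        data.frame(gene = gs, cluster = cc, dataset = d,
                   module = unname(moduleAssignment(partitions[[d]])[gs]))))
    }))
  } else data.frame(gene = character(), cluster = character(),
                    dataset = character(), module = character())
  tris <- communities@triangles
  conserved <- vapply(tris@parts, function(p)
    length(unique(tris@members[, p])), integer(1))
  stats <- list(
    conservedModules = conserved,
    totalModules = vapply(partitions[tris@parts], nModules, integer(1)),
    nTriangles = nrow(tris@members),
    nCommunities = length(mods),
    nSingletonCommunities =
      sum(tabulate(communityMembership(communities)) == 1L),
    consensusGenes = length(genes),
    tripleOverlapGenes = length(unique(unlist(tripleOverlap(tris)))))
  new("ConsensusClusterSet", clusters = clusters, provenance = prov,
      stats = stats)
}
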