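#' Accessors for partition and consensus objects
#'
#' `datasetId()` returns the dataset identifier of a partition;
#' `moduleAssignment()` the named gene -> module vector; `modules()` a named
#' list of module gene sets; `universe()` all genes the dataset examined
#' (assigned plus outliers); `outlierGenes()` the unassigned genes;
#' `nModules()` the module count.
#'
#' @param x a [GenePartition-class] (or, where noted, another micc object).
#' @return see per-generic description.
#' @examples
#' gp <- GenePartition("toy", c(g1 = "A", g2 = "A", g3 = "B"), outliers = "g4")
#' modules(gp)
#' universe(gp)
#' @name partition-accessors
NULL

#' @rdname partition-accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @rdname partition-accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname partition-accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))
#' @rdname partition-accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))
#' @rdname partition-accessors
#' @export
setGeneric("outlierGenes", function(x) standardGeneric("outlierGenes"))
#' @rdname partition-accessors
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @rdname partition-accessors
setMethod("datasetId", "GenePartition", function(x) x@dataset)
#' @rdname partition-accessors
setMethod("moduleAssignment", "GenePartition", function(x) x@assignment)
#' @rdname partition-accessors
setMethod("modules", "GenePartition", function(x)
  split(names(x@assignment), x@assignment))
#' @rdname partition-accessors
setMethod("universe", "GenePartition", function(x)
  c(names(x@assignment), x@outliers))
#' @rdname partition-accessors
setMethod("outlierGenes", "GenePartition", function(x) x@outliers)
#' @rdname partition-accessors
setMethod("nModules", "GenePartition", function(x)
  length(unique(x@assignment)))

#' Accessors for W-score objects
#'
#' `wMatrix()` returns the module-pair W-score matrix, `totalMI()` the total
#' mutual information between the two partitions, `miThresholdValue()` the
#' MI-positivity threshold, and `keptPairs()` the supra-threshold mask.
#'
#' @param x a [PairScores-class] object.
#' @name pairscores-accessors
NULL

#' @rdname pairscores-accessors
#' @export
setGeneric("wMatrix", function(x) standardGeneric("wMatrix"))
#' @rdname pairscores-accessors
#' @export
setGeneric("totalMI", function(x) standardGeneric("totalMI"))
#' @rdname pairscores-accessors
#' @export
setGeneric("miThresholdValue", function(x) standardGeneric("miThresholdValue"))
#' @rdname pairscores-accessors
#' @export
setGeneric("keptPairs", function(x) standardGeneric("keptPairs"))

#' @rdname pairscores-accessors
setMethod("wMatrix", "PairScores", function(x) x@w)
#' @rdname pairscores-accessors
setMethod("totalMI", "PairScores", function(x) x@totalMI)
#' @rdname pairscores-accessors
setMethod("miThresholdValue", "PairScores", function(x) x@threshold)
#' @rdname pairscores-accessors
setMethod("keptPairs", "PairScores", function(x) x@kept)

#' Accessors for graph, triangle, community and consensus objects
#'
#' `graphParts()` gives the dataset identifiers of a k-partite information
#' graph, `graphEdges()` its supra-threshold edge table, `triangleMembers()`
#' the module-per-dataset member matrix of a triangle set, `tripleOverlap()`
#' the per-triangle gene intersections, `communityMembership()` the community
#' id of every triangle, `communityModules()` the per-community module sets
#' grouped by dataset, `consensusClusters()` the named list of disjoint
#' consensus gene sets, and `consensusStats()` the summary counts.
#'
#' @param x an [InformationGraph-class], [TriangleSet-class],
#'   [CommunitySet-class] or [ConsensusClusterSet-class] object.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
setGeneric("graphParts", function(x) standardGeneric("graphParts"))
#' @rdname graph-accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname graph-accessors
#' @export
setGeneric("triangleMembers", function(x) standardGeneric("triangleMembers"))
#' @rdname graph-accessors
#' @export
setGeneric("tripleOverlap", function(x) standardGeneric("tripleOverlap"))
#' @rdname graph-accessors
#' @export
setGeneric("communityMembership",
           function(x) standardGeneric("communityMembership"))
#' @rdname graph-accessors
#' @export
setGeneric("communityModules",
           function(x) standardGeneric("communityModules"))
#' @rdname graph-accessors
#' @export
setGeneric("consensusClusters",
           function(x) standardGeneric("consensusClusters"))
#' @rdname graph-accessors
#' @export
setGeneric("consensusStats", function(x) standardGeneric("consensusStats"))

#' @rdname graph-accessors
setMethod("graphParts", "InformationGraph", function(x) x@parts)
#' @rdname graph-accessors
setMethod("graphEdges", "InformationGraph", function(x) x@edges)
#' @rdname graph-accessors
setMethod("triangleMembers", "TriangleSet", function(x) x@members)
#' @rdname graph-accessors
setMethod("tripleOverlap", "TriangleSet", function(x) x@overlap)
#' @rdname graph-accessors
setMethod("communityMembership", "CommunitySet", function(x) x@membership)
#' @rdname graph-accessors
setMethod("communityModules", "CommunitySet", function(x) x@modules)
#' @rdname graph-accessors
setMethod("consensusClusters", "ConsensusClusterSet", function(x) x@clusters)
#' @rdname graph-accessors
setMethod("consensusStats", "ConsensusClusterSet", function(x) x@stats)
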