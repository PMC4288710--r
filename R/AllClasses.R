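#' @import methods
#' @importFrom stats median cor sd quantile setNames
NULL

#' GenePartition: one dataset's assignment of genes to co-expression modules
#'
#' A `GenePartition` records, for a single dataset, which module label each
#' clustered gene carries and which genes were examined but left unassigned
#' (outliers, in WGCNA terms the grey genes).  The gene universe of the
#' partition is the union of assigned and outlier genes; outliers count toward
#' the universe size but belong to no module, so they depress overlap scores.
#'
#' @slot dataset single dataset identifier.
#' @slot assignment named character vector mapping gene identifier to module
#'   label; every assigned gene carries exactly one label.
#' @slot outliers character vector of genes in the universe with no module.
#'
#' @seealso [GenePartition()], [readPartition()]
#' @export
setClass("GenePartition",
  representation(dataset = "character",
                 assignment = "character",
                 outliers = "character"))

setValidity("GenePartition", function(object) {
  msg <- character()
  if (length(object@dataset) != 1L || !nzchar(object@dataset))
    msg <- c(msg, "'dataset' must be a single non-empty string")
  g <- names(object@assignment)
  if (length(object@assignment) < 1L)
    msg <- c(msg, "partition must assign at least one gene to a module")
  if (is.null(g) || anyNA(g) || any(!nzchar(g)))
    msg <- c(msg, "'assignment' must be named by gene identifiers")
  else if (anyDuplicated(g))
    msg <- c(msg, sprintf("duplicated gene identifiers in assignment: %s",
                          paste(unique(g[duplicated(g)])[1:3], collapse = ", ")))
  if (anyDuplicated(object@outliers))
    msg <- c(msg, "duplicated gene identifiers in outliers")
  if (length(intersect(g, object@outliers)))
    msg <- c(msg, "a gene cannot be both assigned and an outlier")
  if (anyNA(object@assignment) || any(!nzchar(object@assignment)))
    msg <- c(msg, "module labels must be non-missing, non-empty strings")
  if (length(msg)) msg else TRUE
})

#' Construct a GenePartition
#'
#' @param dataset dataset identifier.
#' @param assignment named character vector, gene -> module label.
#' @param outliers genes in the universe with no module assignment.
#' @return a [GenePartition-class] object.
#' @examples
#' gp <- GenePartition("toy", c(g1 = "A", g2 = "A", g3 = "B"), outliers = "g4")
#' nModules(gp)
#' @export
GenePartition <- function(dataset, assignment, outliers = character()) {
  new("GenePartition", dataset = as.character(dataset),
      assignment = structure(as.character(assignment),
                             names = names(assignment)),
      outliers = as.character(outliers))
}

#' PairScores: W-scores between the modules of two partitions
#'
#' Holds the full matrix of per-module-pair W-scores between two datasets'
#' partitions, the total mutual information they sum to, and the MI-positivity
#' threshold with its supra-threshold mask.
#'
#' @slot datasets the two dataset identifiers.
#' @slot w numeric matrix of W-scores, rows = modules of the first dataset,
#'   columns = modules of the second.
#' @slot totalMI total mutual information between the partitions (sum of `w`).
#' @slot threshold MI-positivity threshold; retained pairs have `w >= threshold`.
#' @slot kept logical matrix marking supra-threshold pairs.
#' @slot N shared-universe size used as the genome size.
#' @slot logBase logarithm base of the information units (2 = bits).
#' @export
setClass("PairScores",
  representation(datasets = "character", w = "matrix", totalMI = "numeric",
                 threshold = "numeric", kept = "matrix", N = "integer",
                 logBase = "numeric"))

setValidity("PairScores", function(object) {
  msg <- character()
  if (length(object@datasets) != 2L)
    msg <- c(msg, "'datasets' must name exactly two datasets")
  if (!identical(dim(object@w), dim(object@kept)))
    msg <- c(msg, "'w' and 'kept' must have identical dimensions")
  if (abs(sum(object@w) - object@totalMI) >
      1e-9 * max(1, abs(object@totalMI)))
    msg <- c(msg, "sum of W-scores must equal the total mutual information")
  if (object@totalMI < -1e-12)
    msg <- c(msg, "total mutual information cannot be negative")
  if (any(object@w[object@kept] < object@threshold))
    msg <- c(msg, "kept pairs must all reach the threshold")
  if (length(msg)) msg else TRUE
})

#' InformationGraph: k-partite graph of supra-threshold module overlaps
#'
#' Nodes are (dataset, module) pairs; an edge joins two modules from different
#' datasets whose overlap W-score survives that dataset pair's MI-positivity
#' threshold.  The graph is k-partite by construction: no edge joins two
#' modules of the same dataset.
#'
#' @slot parts dataset identifiers (the parts of the k-partite graph).
#' @slot edges data.frame with columns `part_a`, `module_a`, `part_b`,
#'   `module_b`, `weight` (the W-score).
#' @slot pairs named list of [PairScores-class], one per unordered dataset pair,
#'   keyed `"a|b"` in `parts` order.
#' @slot partitions the input [GenePartition-class] objects, kept so that
#'   triangle gene overlaps can be computed downstream.
#' @export
setClass("InformationGraph",
  representation(parts = "character", edges = "data.frame",
                 pairs = "list", partitions = "list"))

setValidity("InformationGraph", function(object) {
  msg <- character()
  if (anyDuplicated(object@parts))
    msg <- c(msg, "duplicate dataset identifiers")
  e <- object@edges
  need <- c("part_a", "module_a", "part_b", "module_b", "weight")
  if (!all(need %in% names(e)))
    msg <- c(msg, sprintf("edges must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(e$part_a == e$part_b))
      msg <- c(msg, "graph must be k-partite: no edges within a dataset")
    if (any(!is.finite(e$weight)))
      msg <- c(msg, "edge weights must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' TriangleSet: cross-dataset cliques of the information graph
#'
#' Each triangle (generally, a cross-all-parts k-clique) takes one module from
#' every dataset, all mutually linked in the information graph, and marks a
#' module conserved across all datasets.  `overlap` holds each triangle's
#' triple-overlap gene set (intersection of all member modules).
#'
#' @slot parts dataset identifiers, in canonical order.
#' @slot members character matrix, one row per triangle, one column per part;
#'   entries are module labels.
#' @slot overlap list of character vectors, the per-triangle gene intersection.
#' @export
setClass("TriangleSet",
  representation(parts = "character", members = "matrix", overlap = "list"))

setValidity("TriangleSet", function(object) {
  msg <- character()
  if (ncol(object@members) != length(object@parts) && nrow(object@members) > 0L)
    msg <- c(msg, "'members' must have one column per part")
  if (length(object@overlap) != nrow(object@members))
    msg <- c(msg, "'overlap' must have one element per triangle")
  if (length(msg)) msg else TRUE
})

#' CommunitySet: communities of triangles in the triangle graph
#'
#' Triangle-percolation communities: every triangle belongs to exactly one
#' community, while a module node may appear in several communities.
#'
#' @slot triangles the [TriangleSet-class] that was clustered.
#' @slot membership integer vector, community id (1-based) per triangle.
#' @slot modules list, per community, of named lists mapping dataset id to the
#'   module labels that community contains in that dataset.
#' @export
setClass("CommunitySet",
  representation(triangles = "TriangleSet", membership = "integer",
                 modules = "list"))

setValidity("CommunitySet", function(object) {
  msg <- character()
  n <- nrow(object@triangles@members)
  if (length(object@membership) != n)
    msg <- c(msg, "'membership' must cover every triangle exactly once")
  if (n > 0L && !setequal(unique(object@membership),
                          seq_along(object@modules)))
    msg <- c(msg, "community ids must be 1..number of communities")
  if (length(msg)) msg else TRUE
})

#' ConsensusClusterSet: disjoint consensus gene clusters
#'
#' One gene set per community: the intersection across datasets of the
#' within-dataset unions of that community's modules.  Consensus clusters are
#' pairwise disjoint even though communities may share modules, because a
#' consensus gene must sit in exactly one module of every dataset.
#'
#' @slot clusters named list, community id -> character vector of consensus
#'   genes (possibly empty).
#' @slot provenance data.frame with columns `gene`, `cluster`, `dataset`,
#'   `module` recording which module admitted each consensus gene per dataset.
#' @slot stats list of summary counts: per-dataset conserved-module counts
#'   (modules in >= 1 triangle), total consensus genes, triple-overlap gene
#'   count.
#' @export
setClass("ConsensusClusterSet",
  representation(clusters = "list", provenance = "data.frame",
                 stats = "list"))

setValidity("ConsensusClusterSet", function(object) {
  genes <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(genes))
    return(sprintf("consensus clusters must be pairwise disjoint (gene %s appears twice)",
                   genes[duplicated(genes)][1]))
  TRUE
})

#' SyntheticSpec: parameters of the synthetic multi-cohort generator
#'
#' Describes a simulated study: a shared gene universe, planted gene blocks
#' with a conservation mode per block, per-module subset mean shifts, and
#' noise/missingness levels.  Conservation modes: `"conserved"` (one module in
#' every dataset), `"split:j"` (whole in dataset 1, j pieces elsewhere),
#' `"shuffled"` (labels drawn independently per dataset), `"absent-in:<d>"`
#' (outliers in dataset d, conserved elsewhere).
#'
#' @slot nGenes gene-universe size.
#' @slot nDatasets number of cohorts.
#' @slot nSamples integer vector of per-dataset sample counts.
#' @slot blocks data.frame with columns `block` (label), `size`, `mode`.
#' @slot subsetEffects data.frame with columns `block`, `subset`, `shift`
#'   (mean shift of the module latent factor, in factor SD units).
#' @slot noiseSD residual gene-level noise SD around the module latent factor.
#' @slot missingRate probability an entry is missing at random.
#' @slot subsetProportions named numeric vector of sample-label proportions.
#' @slot nNoiseModules number of dataset-specific noise-module labels used for
#'   `"shuffled"` blocks (drawn independently per dataset).
#' @export
setClass("SyntheticSpec",
  representation(nGenes = "integer", nDatasets = "integer",
                 nSamples = "integer", blocks = "data.frame",
                 subsetEffects = "data.frame", noiseSD = "numeric",
                 missingRate = "numeric", subsetProportions = "numeric",
                 nNoiseModules = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (sum(object@blocks$size) > object@nGenes)
    msg <- c(msg, "planted blocks exceed the gene universe")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "'missingRate' must be in [0, 1)")
  if (length(object@nSamples) != object@nDatasets)
    msg <- c(msg, "'nSamples' must give one count per dataset")
  if (!all(is.finite(object@subsetEffects$shift %||% numeric())))
    msg <- c(msg, "subset-effect shifts must be finite")
  if (abs(sum(object@subsetProportions) - 1) > 1e-8)
    msg <- c(msg, "'subsetProportions' must sum to 1")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- show methods -----------------------------------------------------------

setMethod("show", "GenePartition", function(object) {
  tab <- table(object@assignment)
  cat(sprintf("GenePartition '%s': %d genes in %d modules, %d outliers\n",
              object@dataset, length(object@assignment), length(tab),
              length(object@outliers)))
  cat("  module sizes:", paste(utils::head(sort(as.integer(tab),
                                                decreasing = TRUE), 10),
                               collapse = " "),
      if (length(tab) > 10) "...\n" else "\n")
})

setMethod("show", "PairScores", function(object) {
  cat(sprintf("PairScores %s vs %s: %d x %d module pairs, N = %d\n",
              object@datasets[1], object@datasets[2],
              nrow(object@w), ncol(object@w), object@N))
  cat(sprintf("  total MI = %.4f (base %g), threshold = %.4g, kept %d pairs\n",
              object@totalMI, object@logBase, object@threshold,
              sum(object@kept)))
})

setMethod("show", "InformationGraph", function(object) {
  cat(sprintf("InformationGraph: %d parts (%s), %d supra-threshold edges\n",
              length(object@parts), paste(object@parts, collapse = ", "),
              nrow(object@edges)))
})

setMethod("show", "TriangleSet", function(object) {
  cat(sprintf("TriangleSet: %d conserved-module %d-cliques over parts %s\n",
              nrow(object@members), length(object@parts),
              paste(object@parts, collapse = ", ")))
})

setMethod("show", "CommunitySet", function(object) {
  sizes <- tabulate(object@membership, nbins = length(object@modules))
  cat(sprintf("CommunitySet: %d communities over %d triangles (%d singletons)\n",
              length(object@modules), length(object@membership),
              sum(sizes == 1L)))
})

setMethod("show", "ConsensusClusterSet", function(object) {
  sz <- lengths(object@clusters)
  cat(sprintf("ConsensusClusterSet: %d clusters, %d consensus genes\n",
              length(sz), sum(sz)))
  if (length(sz))
    cat("  sizes:", paste(sort(sz, decreasing = TRUE), collapse = " "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d genes x %d datasets (samples: %s), ",
                     "%d planted blocks, noise SD %.2f, missing %.2f\n"),
              object@nGenes, object@nDatasets,
              paste(object@nSamples, collapse = "/"),
              nrow(object@blocks), object@noiseSD, object@missingRate))
})
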