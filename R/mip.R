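#' Module-pair overlap W-score
#'
#' The additive term of the mutual information of two genomic partitions that
#' is contributed by one pair of modules.  For modules of sizes `sizeA` and
#' `sizeB` sharing `overlap` genes out of a universe of `N`,
#' \deqn{W = \frac{o}{N}\,\log_b\!\frac{N\,o}{|C_i|\,|C_j|},}
#' with the convention \eqn{0 \log 0 = 0}.  `W` is positive exactly when the
#' overlap exceeds the independence expectation `sizeA * sizeB / N`, zero at
#' the expectation or for empty overlap, and negative for depleted overlaps.
#' Summed over all module pairs of two partitions, the W-scores give the total
#' mutual information between the partitions.
#'
#' @param sizeA,sizeB module sizes (counts within the shared universe).
#' @param overlap number of genes in both modules.
#' @param N shared gene-universe size.
#' @param logBase logarithm base; 2 (the default) yields bits.
#' @return the W-score (finite numeric); vectorized over the first three
#'   arguments.
#' @examples
#' wScore(10, 10, 10, 100)          # perfectly conserved module: 0.332 bits
#' wScore(50, 50, 10, 100)          # depleted overlap: negative
#' @export
wScore <- function(sizeA, sizeB, overlap, N, logBase = 2) {
  if (length(N) != 1L || is.na(N) || N < 1)
    stop("'N' must be a single positive count")
  if (any(overlap < 0))
    stop("'overlap' cannot be negative")
  if (any(overlap > pmin(sizeA, sizeB)))
    stop("'overlap' cannot exceed the smaller module size")
  if (any((sizeA < 1 | sizeB < 1) & overlap > 0))
    stop("module sizes must be >= 1 where the overlap is positive")
  w <- numeric(length(overlap))
  pos <- overlap > 0
  w[pos] <- (overlap[pos] / N) *
    log(N * overlap[pos] / (sizeA[pos] * sizeB[pos]), base = logBase)
  w
}

#' MI-positivity threshold over a set of W-scores
#'
#' Sorts the W-scores in descending order and keeps the smallest prefix whose
#' cumulative sum first reaches the total mutual information; the threshold is
#' the last kept value.  This retains exactly the scores that contribute
#' positively to the total mutual information: everything below the threshold
#' (including every negative score) sums to zero with the discarded tail.
#' When several equal scores straddle the crossing, all of them are kept.
#'
#' @param scores numeric vector of W-scores (any order).
#' @param total their total mutual information; defaults to `sum(scores)` and
#'   is checked against it.
#' @return the threshold value `t`; scores `>= t` are the retained set.
#' @examples
#' miThreshold(c(0.6, 0.5, 0.02, -0.12))   # 0.5: keep 0.6 and 0.5
#' @export
miThreshold <- function(scores, total = sum(scores)) {
  tol <- 1e-9 * max(1, abs(total))
  if (total < -tol)
    stop("total mutual information cannot be negative")
  if (abs(sum(scores) - total) > tol)
    stop("'total' must equal the sum of the scores")
  if (!length(scores))
    stop("no scores to threshold")
  s <- sort(scores, decreasing = TRUE)
  idx <- which(cumsum(s) >= total - tol)[1L]
  s[idx]
}

.sharedUniverse <- function(a, b, universePolicy) {
  ua <- universe(a); ub <- universe(b)
  if (identical(universePolicy, "pair-intersection")) {
    shared <- intersect(ua, ub)
    list(shared = shared, N = length(shared))
  } else if (identical(universePolicy, "union")) {
    shared <- intersect(ua, ub)
    list(shared = shared, N = length(union(ua, ub)))
  } else if (grepl("^fixed:[0-9]+$", universePolicy)) {
    shared <- intersect(ua, ub)
    list(shared = shared, N = as.integer(sub("^fixed:", "", universePolicy)))
  } else {
    stop("unknown universe policy: ", universePolicy,
         " (use 'pair-intersection', 'union' or 'fixed:<n>')")
  }
}

#' All W-scores between two partitions
#'
#' Computes the full module-by-module W-score matrix between two datasets'
#' partitions over their shared gene universe, the total mutual information
#' (the sum of all W-scores), and the MI-positivity threshold with its
#' supra-threshold mask.  Outlier genes belong to the universe but to no
#' module, so they count toward `N` and depress overlaps.
#'
#' @param a,b [GenePartition-class] objects from two datasets.
#' @param logBase logarithm base for the information units (default 2, bits).
#' @param universePolicy how the genome size `N` is determined:
#'   `"pair-intersection"` (default; genes in both datasets' universes),
#'   `"union"`, or `"fixed:<n>"` for an externally known genome size.  Overlap
#'   counts are always taken over the intersection of the universes.
#' @return a [PairScores-class].
#' @examples
#' a <- GenePartition("d1", c(g1 = "a", g2 = "a", g3 = "b", g4 = "b"))
#' b <- GenePartition("d2", c(g1 = "a", g2 = "a", g3 = "b", g4 = "b"))
#' totalMI(pairScores(a, b))    # identical half/half partitions: 1 bit
#' @export
pairScores <- function(a, b, logBase = 2,
                       universePolicy = "pair-intersection") {
  stopifnot(is(a, "GenePartition"), is(b, "GenePartition"))
  su <- .sharedUniverse(a, b, universePolicy)
  if (!length(su$shared))
    stop(sprintf("partitions '%s' and '%s' share no genes",
                 datasetId(a), datasetId(b)))
  asgA <- moduleAssignment(a)[intersect(names(moduleAssignment(a)), su$shared)]
  asgB <- moduleAssignment(b)[intersect(names(moduleAssignment(b)), su$shared)]
  modsA <- sort(unique(moduleAssignment(a)))
  modsB <- sort(unique(moduleAssignment(b)))
  sizeA <- table(factor(asgA, levels = modsA))
  sizeB <- table(factor(asgB, levels = modsB))
  both <- intersect(names(asgA), names(asgB))
  ct <- table(factor(asgA[both], levels = modsA),
              factor(asgB[both], levels = modsB))
  w <- matrix(wScore(as.numeric(sizeA)[row(ct)], as.numeric(sizeB)[col(ct)],
                     as.numeric(ct), su$N, logBase),
              nrow = length(modsA), dimnames = list(modsA, modsB))
  tot <- sum(w)
  thr <- miThreshold(as.numeric(w), tot)
  new("PairScores", datasets = c(datasetId(a), datasetId(b)), w = w,
      totalMI = tot, threshold = thr, kept = w >= thr,
      N = as.integer(su$N), logBase = logBase)
}

#' Build the k-partite information graph
#'
#' For every unordered pair of datasets, computes the W-scores between their
#' modules, thresholds them by MI positivity (per pair), and collects the
#' surviving positive overlaps as edges of a k-partite module-module graph.
#' Triangles (cross-all-parts cliques) of this graph mark modules conserved
#' across all datasets.
#'
#' @param partitions list of [GenePartition-class] objects (>= 2, distinct
#'   dataset ids).
#' @param logBase logarithm base (default 2).
#' @param universePolicy see [pairScores()].
#' @return an [InformationGraph-class].  The result is invariant to the order
#'   in which the partitions are listed: parts are canonicalized by sorting
#'   dataset identifiers.
#' @export
buildInformationGraph <- function(partitions, logBase = 2,
                                  universePolicy = "pair-intersection") {
  stopifnot(length(partitions) >= 2L)
  ids <- vapply(partitions, datasetId, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate dataset id: '%s'", ids[duplicated(ids)][1L]))
  ord <- order(ids)
  partitions <- partitions[ord]
  ids <- ids[ord]
  names(partitions) <- ids
  pairs <- list()
  edges <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq((i + 1L), length(ids))) {
      ps <- pairScores(partitions[[i]], partitions[[j]], logBase,
                       universePolicy)
      pairs[[paste(ids[i], ids[j], sep = "|")]] <- ps
      keep <- which(ps@kept & ps@w > 0, arr.ind = TRUE)
      if (nrow(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          part_a = ids[i], module_a = rownames(ps@w)[keep[, 1L]],
          part_b = ids[j], module_b = colnames(ps@w)[keep[, 2L]],
          weight = ps@w[keep], row.names = NULL)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(part_a = character(), module_a = character(),
                           part_b = character(), module_b = character(),
                           weight = numeric())
  edges <- edges[order(edges$part_a, edges$module_a,
                       edges$part_b, edges$module_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("InformationGraph", parts = ids, edges = edges, pairs = pairs,
      partitions = partitions)
}
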