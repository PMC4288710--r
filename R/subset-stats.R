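## Sample subset annotations are plain named character vectors
## (sample -> label) over a closed vocabulary.

.subsetVocabulary <- c("inflammatory", "fibroproliferative", "normal-like",
                       "limited", "healthy-control", "morphea", "unknown")

.sscLabels <- c("inflammatory", "fibroproliferative", "normal-like", "limited")

.checkAnnotation <- function(ann) {
  if (is.null(names(ann)) || anyNA(names(ann)))
    stop("annotation must be a named character vector (sample -> label)")
  bad <- setdiff(unique(ann), .subsetVocabulary)
  if (length(bad))
    stop("unknown subset label '", bad[1L], "'; expected one of: ",
         paste(.subsetVocabulary, collapse = ", "))
  invisible(ann)
}

.testRow <- function(module, contrast, direction, p, nTests, alpha,
                     tie = FALSE) {
  data.frame(dataset = module[1L], module = module[2L], contrast = contrast,
             direction = direction, p_raw = p,
             p_bonferroni = min(1, p * nTests),
             n_tests_corrected = nTests,
             significant = min(1, p * nTests) < alpha, tie = tie)
}

#' Omnibus Kruskal-Wallis test of a module eigengene across subsets
#'
#' Screens a module for any association with the intrinsic subsets: a
#' tie-corrected Kruskal-Wallis test of the eigengene scores grouped by
#' subset label, Bonferroni-corrected over the number of modules tested.
#'
#' @param e an [Eigengene-class].
#' @param ann named character vector, sample -> subset label.
#' @param groups labels to compare (default: all labels present among the
#'   eigengene's samples); each group must have at least 2 samples.
#' @param nTests Bonferroni multiplier (number of modules screened).
#' @param alpha significance level applied to the corrected p-value.
#' @return one-row data.frame: dataset, module, contrast (`"omnibus-KW"`),
#'   direction (`"none"`), p_raw, p_bonferroni, n_tests_corrected,
#'   significant, tie.
#' @export
kruskalWallisModule <- function(e, ann, groups = NULL, nTests = 1,
                                alpha = 0.05) {
  .checkAnnotation(ann)
  sc <- e@scores[intersect(names(e@scores), names(ann))]
  lab <- ann[names(sc)]
  if (is.null(groups)) groups <- sort(unique(lab))
  keep <- lab %in% groups
  sc <- sc[keep]; lab <- lab[keep]
  cnt <- table(factor(lab, levels = groups))
  if (length(groups) < 2L)
    stop("need at least two groups for a Kruskal-Wallis test")
  if (any(cnt < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  p <- stats::kruskal.test(sc, factor(lab))$p.value
  .testRow(e@module, "omnibus-KW", "none", p, nTests, alpha)
}

.directionalRankTest <- function(subsetScores, complementScores, nTests,
                                 alpha, module, contrast,
                                 twoSided = FALSE) {
  popMedian <- stats::median(c(subsetScores, complementScores))
  subMedian <- stats::median(subsetScores)
  tie <- subMedian == popMedian
  direction <- if (subMedian >= popMedian) "up" else "down"
  exact <- length(subsetScores) <= 25L && length(complementScores) <= 25L
  alternative <- if (twoSided) "two.sided"
                 else if (direction == "up") "greater" else "less"
  p <- suppressWarnings(stats::wilcox.test(
    subsetScores, complementScores, alternative = alternative,
    exact = exact, correct = TRUE))$p.value
  .testRow(module, contrast, direction, p, nTests, alpha, tie)
}

#' Directional one-tailed Wilcoxon test of a module eigengene in a subset
#'
#' Determines whether the subset's median eigengene score lies above or below
#' the whole population's median, then tests that direction with a one-tailed
#' Wilcoxon rank-sum test of subset versus complement.  Median ties are broken
#' to `"up"` and flagged in the `tie` column.  P-values are exact (when both
#' arms have at most 25 samples and no ties) or use the normal approximation
#' with tie and continuity correction otherwise.  Note the returned p is the
#' pure one-tailed tail in the selected direction: at a fixed threshold this
#' roughly doubles the type-I rate relative to a prespecified direction, which
#' is why [subsetSpecificityTable()] calls significance on the two-sided
#' p-value instead.
#'
#' @param e an [Eigengene-class].
#' @param ann named character vector, sample -> subset label.
#' @param subset label (or labels) defining the subset of interest.
#' @param population labels defining the comparison population; default all
#'   other annotated labels.
#' @param nTests Bonferroni multiplier.  For module-wise subset screens the
#'   convention is (total modules across datasets) x (number of contrasts).
#' @param alpha significance level applied to the corrected p-value.
#' @return one-row data.frame as in [kruskalWallisModule()].
#' @export
directionalWilcoxon <- function(e, ann, subset, population = NULL,
                                nTests = 1, alpha = 0.05) {
  .checkAnnotation(ann)
  sc <- e@scores[intersect(names(e@scores), names(ann))]
  lab <- ann[names(sc)]
  inSub <- lab %in% subset
  if (is.null(population)) population <- setdiff(unique(lab), subset)
  inPop <- lab %in% population & !inSub
  if (!any(inSub)) stop("subset has no samples")
  if (!any(inPop)) stop("subset covers all samples; no complement to test")
  .directionalRankTest(sc[inSub], sc[inPop], nTests, alpha, e@module,
                       paste(subset, collapse = "+"))
}

.contrastArms <- function(ann, contrast) {
  labs <- unique(ann)
  switch(contrast,
    "allSSc-vs-control" = {
      if (!"healthy-control" %in% labs)
        stop("dataset has no healthy controls; cannot run the ",
             "allSSc-vs-control contrast")
      list(subset = .sscLabels, population = "healthy-control")
    },
    "nonNormal-vs-normalHealthy" = list(
      subset = c("inflammatory", "fibroproliferative", "limited"),
      population = c("normal-like", "healthy-control")),
    {
      if (!contrast %in% .subsetVocabulary)
        stop("unknown contrast '", contrast, "'")
      list(subset = contrast, population = setdiff(labs, contrast))
    })
}

#' Subset-specificity table over all modules and contrasts
#'
#' For every dataset's every module, computes the module eigengene, reports
#' the direction of the subset's median shift, and tests each requested
#' contrast with a single Bonferroni correction over (total modules across
#' datasets) x (number of contrasts).  Because the direction is selected from
#' the data, the significance call uses the two-sided rank-sum p-value — the
#' valid p-value for a data-selected one-tailed alternative — while the
#' `direction` column reports which side the subset falls on; a raw one-tailed
#' p for a prespecified direction is available from [directionalWilcoxon()].  Available contrasts: the subset labels themselves (subset vs
#' all other annotated samples), `"allSSc-vs-control"` (all SSc subsets vs
#' healthy controls), and `"nonNormal-vs-normalHealthy"` (inflammatory,
#' fibroproliferative and limited SSc vs normal-like SSc plus healthy
#' controls).
#'
#' @param partitions named list of [GenePartition-class], one per dataset.
#' @param matrices named list of `SummarizedExperiment`s aligned to
#'   `partitions` by dataset id.
#' @param annotations named list of named character vectors (sample -> label).
#' @param contrasts character vector of contrast names.
#' @param alpha significance level on the corrected p-values.
#' @param minModuleGenes skip modules with fewer usable genes than this
#'   (eigengenes need at least 2).
#' @return data.frame, one row per module x contrast.
#' @export
subsetSpecificityTable <- function(partitions, matrices, annotations,
                                   contrasts = c("inflammatory",
                                                 "fibroproliferative",
                                                 "normal-like"),
                                   alpha = 0.05, minModuleGenes = 2L) {
  ids <- vapply(partitions, datasetId, character(1))
  names(partitions) <- ids
  stopifnot(all(ids %in% names(matrices)), all(ids %in% names(annotations)))
  nModTotal <- sum(vapply(partitions, nModules, integer(1)))
  nTests <- nModTotal * length(contrasts)
  rows <- list()
  for (d in ids) {
    ann <- .checkAnnotation(annotations[[d]])
    se <- matrices[[d]]
    for (m in names(modules(partitions[[d]]))) {
      gs <- modules(partitions[[d]])[[m]]
      if (length(intersect(gs, rownames(se))) < minModuleGenes) next
      e <- moduleEigengene(se, gs, module = c(d, m))
      for (ct in contrasts) {
        arms <- .contrastArms(ann, ct)
        # a contrast with an empty arm (e.g. a subset absent from this
        # cohort) is untestable here and contributes no row
        if (!any(ann %in% arms$subset) || !any(ann %in% arms$population))
          next
        sc <- eigengeneScores(e)[intersect(names(eigengeneScores(e)),
                                           names(ann))]
        lab <- ann[names(sc)]
        res <- .directionalRankTest(sc[lab %in% arms$subset],
                                    sc[lab %in% arms$population &
                                         !(lab %in% arms$subset)],
                                    nTests, alpha, c(d, m), ct,
                                    twoSided = TRUE)
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (!length(rows))
    return(data.frame(dataset = character(), module = character(),
                      contrast = character(), direction = character(),
                      p_raw = numeric(), p_bonferroni = numeric(),
                      n_tests_corrected = numeric(),
                      significant = logical(), tie = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hub-gene enrichment of the consensus genes
#'
#' Module eigengenes are the hubs of their co-expression modules: a gene
#' highly correlated with its own module eigengene is central in its module.
#' This computes, per dataset, the correlation of every clustered gene to the
#' eigengene of its own module, then asks whether the consensus genes are more
#' hub-like than the remaining genes with a one-sided two-sample Wilcoxon
#' rank-sum test.
#'
#' @param matrices named list of `SummarizedExperiment`s, one per dataset.
#' @param partitions named list of [GenePartition-class] objects.
#' @param consensus a [ConsensusClusterSet-class] (or a character vector of
#'   consensus genes).
#' @param minModuleGenes modules with fewer usable genes are skipped.
#' @return list with `consensusCorrelations`, `backgroundCorrelations`
#'   (non-consensus), `statistic` (rank-sum W) and `p` (one-sided).
#' @export
hubnessEnrichment <- function(matrices, partitions, consensus,
                              minModuleGenes = 2L) {
  consGenes <- if (is(consensus, "ConsensusClusterSet"))
    unique(unlist(consensusClusters(consensus), use.names = FALSE))
  else unique(as.character(consensus))
  if (!length(consGenes))
    stop("consensus gene set is empty")
  ids <- vapply(partitions, datasetId, character(1))
  names(partitions) <- ids
  corVals <- numeric(); corGenes <- character()
  for (d in ids) {
    se <- matrices[[d]]
    mat <- SummarizedExperiment::assay(se)
    for (m in names(modules(partitions[[d]]))) {
      gs <- intersect(modules(partitions[[d]])[[m]], rownames(mat))
      if (length(gs) < minModuleGenes) next
      e <- moduleEigengene(se, gs, module = c(d, m))
      cc <- apply(mat[gs, , drop = FALSE], 1L, function(v)
        suppressWarnings(stats::cor(v, e@scores,
                                    use = "pairwise.complete.obs")))
      ok <- is.finite(cc)
      corVals <- c(corVals, cc[ok])
      corGenes <- c(corGenes, gs[ok])
    }
  }
  isCons <- corGenes %in% consGenes
  if (!any(isCons))
    stop("no consensus gene has a computable eigengene correlation")
  wt <- suppressWarnings(stats::wilcox.test(
    corVals[isCons], corVals[!isCons], alternative = "greater"))
  list(consensusCorrelations = corVals[isCons],
       backgroundCorrelations = corVals[!isCons],
       statistic = unname(wt$statistic), p = wt$p.value)
}
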