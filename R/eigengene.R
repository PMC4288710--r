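#' Eigengene: one-dimensional summary of a module's expression
#'
#' @slot module character of length 2: dataset id and module label.
#' @slot scores named numeric vector, one unit-norm score per sample.
#' @slot varExplained fraction of variance of the normalized module expression
#'   captured by the first principal component, in `[0, 1]`.
#' @slot orientationSign +1 or -1; the sign applied so the eigengene
#'   correlates positively with the module's mean expression profile.
#' @export
setClass("Eigengene",
  representation(module = "character", scores = "numeric",
                 varExplained = "numeric", orientationSign = "numeric"))

setMethod("show", "Eigengene", function(object) {
  cat(sprintf("Eigengene %s:%s over %d samples (%.1f%% variance explained)\n",
              object@module[1], object@module[2], length(object@scores),
              100 * object@varExplained))
})

#' Compute a module eigengene
#'
#' The module eigengene is the first principal component of the module's gene
#' expression vectors after each gene vector is scaled to unit Euclidean
#' length.  It summarizes the module's expression across samples in one score
#' per sample and corresponds to the module's most central (hub-like) profile.
#' Missing values are imputed with the gene's median over non-missing samples
#' (zero for median-centered data) before normalization.  The sign is oriented
#' so the eigengene correlates positively with the module's mean expression
#' profile.
#'
#' @param se a `SummarizedExperiment` with assay `"exprs"` (samples in
#'   columns).
#' @param moduleGenes character vector of the module's gene identifiers; at
#'   least two must be present in `se`.
#' @param module optional c(dataset, label) identifier carried on the result.
#' @return an [Eigengene-class]; `scores` has unit Euclidean norm.
#' @export
moduleEigengene <- function(se, moduleGenes, module = c("", "")) {
  mat <- SummarizedExperiment::assay(se)
  present <- intersect(moduleGenes, rownames(mat))
  if (length(present) < 2L)
    stop("module has fewer than two genes present in the expression matrix")
  x <- mat[present, , drop = FALSE]
  for (i in seq_len(nrow(x))) {
    miss <- is.na(x[i, ])
    if (all(miss))
      stop(sprintf("gene '%s' has no non-missing values", present[i]))
    if (any(miss))
      x[i, miss] <- stats::median(x[i, !miss])
  }
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0))
    stop(sprintf("gene '%s' has zero expression norm; cannot normalize",
                 present[nrm == 0][1L]))
  x <- x / nrm
  sv <- svd(x)
  if (sv$d[1L] == 0)
    stop("module has zero variance; eigengene undefined")
  eg <- sv$v[, 1L]
  meanProfile <- colMeans(x)
  s <- sum(eg * meanProfile)
  sgn <- if (s < 0) -1 else 1
  eg <- sgn * eg
  new("Eigengene", module = as.character(module),
      scores = stats::setNames(eg, colnames(mat)),
      varExplained = sv$d[1L]^2 / sum(sv$d^2),
      orientationSign = sgn)
}

#' @rdname partition-accessors
#' @export
setGeneric("eigengeneScores", function(x) standardGeneric("eigengeneScores"))
#' @rdname partition-accessors
setMethod("eigengeneScores", "Eigengene", function(x) x@scores)
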