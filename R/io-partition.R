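#' Read or write a gene-partition table
#'
#' A partition table is a two-column tab-delimited file `gene<TAB>module`
#' (header optional, detected when the first line reads `gene<TAB>module`).
#' Genes carrying the reserved outlier label are recorded as unassigned but
#' remain part of the partition's gene universe.
#'
#' @param path path to the partition TSV.
#' @param dataset dataset identifier; defaults to the file name without
#'   extension.
#' @param outlierLabel module label marking unassigned genes (default
#'   `"outlier"`; WGCNA exports often use `"grey"`).
#' @return a [GenePartition-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("g1\tA", "g2\tA", "g3\tB", "g4\toutlier", "g5\tB"), f)
#' readPartition(f, dataset = "toy")
#' @export
readPartition <- function(path, dataset = NULL,
                          outlierLabel = "outlier") {
  if (is.null(dataset))
    dataset <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) != 2L)
    stop("partition table must have exactly two columns (gene, module)")
  if (identical(tolower(tab[1L, 1L]), "gene") &&
      identical(tolower(tab[1L, 2L]), "module"))
    tab <- tab[-1L, , drop = FALSE]
  genes <- tab[[1L]]
  labels <- tab[[2L]]
  dup <- duplicated(genes)
  if (any(dup)) {
    for (g in unique(genes[dup])) {
      if (length(unique(labels[genes == g])) > 1L)
        stop(sprintf("gene '%s' listed with conflicting module labels", g))
    }
    genes <- genes[!dup]
    labels <- labels[!dup]
  }
  isOut <- labels == outlierLabel
  GenePartition(dataset,
                stats::setNames(labels[!isOut], genes[!isOut]),
                outliers = genes[isOut])
}

#' @rdname readPartition
#' @param p a [GenePartition-class] to write.
#' @param outPath output path.
#' @export
writePartition <- function(p, outPath, outlierLabel = "outlier") {
  stopifnot(is(p, "GenePartition"))
  tab <- rbind(
    data.frame(gene = names(moduleAssignment(p)),
               module = unname(moduleAssignment(p))),
    if (length(outlierGenes(p)))
      data.frame(gene = outlierGenes(p), module = outlierLabel))
  utils::write.table(tab, outPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(outPath)
}
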