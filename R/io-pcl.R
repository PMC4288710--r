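#' Read a Stanford PCL expression file
#'
#' Parses the tab-delimited Stanford PCL layout: a header row with `ID`,
#' `NAME`, an optional `GWEIGHT` column and sample names; an optional
#' `EWEIGHT` row of per-sample weights; and one row per gene.  Empty cells,
#' `NA` and `null` (case-insensitive) denote missing values.  Both dialects
#' (with or without GWEIGHT/EWEIGHT) are detected from the header.
#'
#' @param path path to the PCL file.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"exprs"` holding log-ratio values (`NA` = missing), `rowData` columns
#'   `NAME` and (if present) `GWEIGHT`, and `metadata(x)$EWEIGHT` holding
#'   sample weights when an EWEIGHT row is present.  Gene and sample order is
#'   file order.
#' @examples
#' f <- tempfile(fileext = ".pcl")
#' writeLines(c("ID\tNAME\ts1\ts2", "g1\tgene one\t1.5\t-0.2",
#'              "g2\tgene two\t\t0.4"), f)
#' se <- readPCL(f)
#' SummarizedExperiment::assay(se)
#' @export
readPCL <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines, "right")) | nzchar(lines)]
  if (length(lines) < 2L)
    stop("PCL file must contain a header and at least one gene row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; restore them so missing values in
  # the last sample column do not look like ragged rows
  nFields <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  cells <- Map(function(x, n) c(x, rep("", n - length(x))), cells, nFields)
  header <- cells[[1L]]
  if (length(header) < 3L || toupper(header[1L]) != "ID")
    stop("not a PCL header: expected 'ID', 'NAME', then sample names")
  hasGW <- length(header) >= 3L && toupper(header[3L]) == "GWEIGHT"
  firstSample <- if (hasGW) 4L else 3L
  samples <- header[firstSample:length(header)]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in PCL header")
  body <- cells[-1L]
  rowno <- seq_along(body) + 1L  # line numbers in the file
  eweight <- NULL
  if (length(body) && toupper(body[[1L]][1L]) == "EWEIGHT") {
    ew <- body[[1L]]
    if (length(ew) != length(header))
      stop("EWEIGHT row has ", length(ew), " columns; expected ",
           length(header))
    eweight <- stats::setNames(
      suppressWarnings(as.numeric(ew[firstSample:length(ew)])), samples)
    body <- body[-1L]
    rowno <- rowno[-1L]
  }
  if (!length(body)) stop("PCL file contains no gene rows")
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop(sprintf("ragged PCL row: line %d has %d columns, expected %d",
                 rowno[bad[1L]], lengths(body)[bad[1L]], length(header)))
  tab <- do.call(rbind, body)
  ids <- tab[, 1L]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene ID in PCL file: '%s'",
                 ids[duplicated(ids)][1L]))
  vals <- tab[, firstSample:length(header), drop = FALSE]
  vals[toupper(trimws(vals)) %in% c("", "NA", "NULL")] <- NA_character_
  mat <- matrix(suppressWarnings(as.numeric(vals)), nrow = nrow(tab),
                dimnames = list(ids, samples))
  rd <- S4Vectors::DataFrame(NAME = tab[, 2L], row.names = ids)
  if (hasGW)
    rd$GWEIGHT <- suppressWarnings(as.numeric(tab[, 3L]))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat), rowData = rd)
  if (!is.null(eweight))
    S4Vectors::metadata(se)$EWEIGHT <- eweight
  se
}

#' Write a Stanford PCL expression file
#'
#' Inverse of [readPCL()]: missing values become empty cells; the GWEIGHT
#' column and EWEIGHT row are emitted only when present on the object.
#'
#' @param se a `SummarizedExperiment` as returned by [readPCL()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePCL <- function(se, path) {
  mat <- SummarizedExperiment::assay(se)
  rd <- SummarizedExperiment::rowData(se)
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                 scientific = FALSE,
                                                 digits = 15))
  hasGW <- "GWEIGHT" %in% names(rd)
  header <- c("ID", "NAME", if (hasGW) "GWEIGHT", colnames(mat))
  out <- paste(header, collapse = "\t")
  ew <- S4Vectors::metadata(se)$EWEIGHT
  if (!is.null(ew))
    out <- c(out, paste(c("EWEIGHT", "", if (hasGW) "",
                          fmt(as.numeric(ew[colnames(mat)]))),
                        collapse = "\t"))
  nm <- if ("NAME" %in% names(rd)) as.character(rd$NAME) else rownames(mat)
  rows <- cbind(rownames(mat), nm,
                if (hasGW) fmt(rd$GWEIGHT),
                matrix(fmt(mat), nrow = nrow(mat)))
  out <- c(out, apply(rows, 1L, paste, collapse = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Drop genes with too much missing data
#'
#' Retains exactly the genes whose fraction of non-missing values is at least
#' `minFraction`; the conventional preprocessing cut is 80% good data.
#'
#' @param se a `SummarizedExperiment` with assay `"exprs"`.
#' @param minFraction minimum fraction of non-missing values per gene, in
#'   `[0, 1]`.  Default 0.8.
#' @return the filtered `SummarizedExperiment`; samples unchanged.
#' @export
filterGeneCompleteness <- function(se, minFraction = 0.8) {
  stopifnot(minFraction >= 0, minFraction <= 1)
  mat <- SummarizedExperiment::assay(se)
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop("cannot filter an empty expression matrix")
  keep <- rowSums(!is.na(mat)) / ncol(mat) >= minFraction
  se[keep, ]
}

#' Median-center each gene, optionally flipping sign
#'
#' Subtracts each gene's median over non-missing values (appropriate for
#' common-reference two-channel designs); with `negate = TRUE` the centered
#' values are then multiplied by -1, converting Cy5/Cy3 ratios to Cy3/Cy5.
#'
#' @param se a `SummarizedExperiment` with assay `"exprs"`.
#' @param negate flip the sign of all values after centering.
#' @return the centered `SummarizedExperiment`; missing entries stay missing.
#' @export
medianCenterGenes <- function(se, negate = FALSE) {
  mat <- SummarizedExperiment::assay(se)
  nOK <- rowSums(!is.na(mat))
  if (any(nOK == 0L))
    stop(sprintf("gene '%s' has no non-missing values; cannot center",
                 rownames(mat)[nOK == 0L][1L]))
  med <- apply(mat, 1L, stats::median, na.rm = TRUE)
  mat <- mat - med
  if (negate) mat <- -mat
  SummarizedExperiment::assay(se) <- mat
  se
}
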