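#' Read or write a three-column weighted edge list
#'
#' The exchange format for gene-gene and module-module networks: a
#' tab-delimited table `node_a<TAB>node_b<TAB>weight` (header detected and
#' skipped when the third field is not numeric).
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns `from`, `to`, `weight`.
#' @export
readEdgeList <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) != 3L)
    stop("edge list must have exactly three columns (node, node, weight)")
  if (is.na(suppressWarnings(as.numeric(tab[1L, 3L]))))
    tab <- tab[-1L, , drop = FALSE]
  data.frame(from = tab[[1L]], to = tab[[2L]],
             weight = as.numeric(tab[[3L]]))
}

#' @rdname readEdgeList
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param outPath output path.
#' @export
writeEdgeList <- function(edges, outPath) {
  utils::write.table(edges[, c("from", "to", "weight")], outPath,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(outPath)
}

#' Write an undirected weighted network as GEXF 1.2
#'
#' Emits Graph Exchange XML Format 1.2 (undirected, weighted) readable by
#' Gephi-class viewers.  Node labels default to node ids; an optional
#' categorical `component` attribute (e.g. community or subnetwork membership)
#' is attached per node.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`; no self-loops;
#'   weights must be finite.
#' @param path output path.
#' @param nodeAttrs optional named character vector (or single-column mapping)
#'   of a categorical `component` attribute per node id; nodes not named get
#'   an empty value.
#' @param nodeLabels optional named character vector of display labels.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".gexf")
#' writeGEXF(data.frame(from = "a", to = "b", weight = 0.5), f,
#'           nodeAttrs = c(a = "left", b = "right"))
#' @export
writeGEXF <- function(edges, path, nodeAttrs = NULL, nodeLabels = NULL) {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (nrow(edges) && any(!is.finite(edges$weight)))
    stop("GEXF edge weights must be finite")
  if (nrow(edges) && any(edges$from == edges$to))
    stop("self-loops are not allowed in the exported network")
  nodes <- sort(unique(c(edges$from, edges$to,
                         names(nodeAttrs), names(nodeLabels))))
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph",
                               defaultedgetype = "undirected",
                               mode = "static")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "component",
                      type = "string")
  nodesEl <- xml2::xml_add_child(graph, "nodes")
  for (n in nodes) {
    lab <- if (!is.null(nodeLabels) && n %in% names(nodeLabels))
      unname(nodeLabels[n]) else n
    nd <- xml2::xml_add_child(nodesEl, "node", id = n, label = lab)
    if (!is.null(nodeAttrs) && n %in% names(nodeAttrs)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      xml2::xml_add_child(av, "attvalue", "for" = "0",
                          value = as.character(unname(nodeAttrs[n])))
    }
  }
  edgesEl <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(edges))) {
    xml2::xml_add_child(edgesEl, "edge", id = paste0("e", i - 1L),
                        source = edges$from[i], target = edges$to[i],
                        weight = format(edges$weight[i], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Parse a GEXF file back into an edge table
#'
#' Round-trip companion of [writeGEXF()]; recovers the edge multiset (source,
#' target, weight) and node attributes from a GEXF 1.x document.
#'
#' @param path path to a GEXF file.
#' @return list with `edges` (data.frame `from`, `to`, `weight`) and `nodes`
#'   (data.frame `id`, `label`, `component`).
#' @export
readGEXF <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[[1L]])
  nodeEls <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(nodeEls, "id"),
    label = xml2::xml_attr(nodeEls, "label"),
    component = vapply(nodeEls, function(nd) {
      av <- xml2::xml_find_first(nd, ".//g:attvalue", ns)
      if (inherits(av, "xml_missing")) NA_character_
      else xml2::xml_attr(av, "value")
    }, character(1)))
  edgeEls <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edgeEls, "source"),
    to = xml2::xml_attr(edgeEls, "target"),
    weight = as.numeric(xml2::xml_attr(edgeEls, "weight")))
  list(edges = edges, nodes = nodes)
}
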