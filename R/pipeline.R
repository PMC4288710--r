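#' Run the full consensus-clustering pipeline
#'
#' Orchestrates every stage — read inputs, score module overlaps, build the
#' information graph, enumerate triangles, cluster the triangle graph,
#' extract consensus clusters, and (when expression and annotations are
#' available) run the subset-specificity tests — writing every intermediate
#' artifact plus a machine-readable `summary.json` and a run `manifest.json`
#' into the output directory.
#'
#' @param config either a path to a JSON run configuration or an equivalent
#'   list.  Fields: `datasets` (list of entries with `id`, `partition` and
#'   optionally `pcl`, `annotation` paths), `log_base` (default 2),
#'   `universe_policy` (default `"pair-intersection"`), `weight_mode`
#'   (default `"shared-w"`), `contrasts` (optional character vector),
#'   `alpha` (default 0.05), `seed` (default 1).
#' @param outDir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    configPath <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else configPath <- NULL
  if (is.null(outDir)) outDir <- config$out_dir %||% stop("no output directory")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ds <- config$datasets
  if (is.data.frame(ds)) ds <- split(ds, seq_len(nrow(ds)))
  ids <- vapply(ds, function(x) as.character(x$id), character(1))
  if (anyDuplicated(ids))
    stop("configuration error: duplicate dataset id '",
         ids[duplicated(ids)][1L], "'")
  logBase <- config$log_base %||% 2
  universePolicy <- config$universe_policy %||% "pair-intersection"
  weightMode <- config$weight_mode %||% "shared-w"
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  partitions <- stage("read-partitions", lapply(ds, function(x)
    readPartition(x$partition, dataset = as.character(x$id))))
  names(partitions) <- ids
  matrices <- list(); annotations <- list()
  for (x in ds) {
    id <- as.character(x$id)
    if (!is.null(x$pcl) && !is.na(x$pcl) && nzchar(x$pcl))
      matrices[[id]] <- stage("read-pcl", readPCL(x$pcl))
    if (!is.null(x$annotation) && !is.na(x$annotation) && nzchar(x$annotation)) {
      tab <- utils::read.table(x$annotation, sep = "\t", header = FALSE,
                               colClasses = "character")
      annotations[[id]] <- stats::setNames(tab[[2L]], tab[[1L]])
    }
  }

  ig <- stage("information-graph",
              buildInformationGraph(partitions, logBase, universePolicy))
  e <- graphEdges(ig)
  writeEdgeList(data.frame(from = .nodeId(e$part_a, e$module_a),
                           to = .nodeId(e$part_b, e$module_b),
                           weight = e$weight),
                file.path(outDir, "information_graph.tsv"))
  nodeParts <- c(stats::setNames(e$part_a, .nodeId(e$part_a, e$module_a)),
                 stats::setNames(e$part_b, .nodeId(e$part_b, e$module_b)))
  writeGEXF(data.frame(from = .nodeId(e$part_a, e$module_a),
                       to = .nodeId(e$part_b, e$module_b),
                       weight = e$weight),
            file.path(outDir, "information_graph.gexf"),
            nodeAttrs = nodeParts[!duplicated(names(nodeParts))])

  tris <- stage("triangles", enumerateTriangles(ig))
  triTab <- as.data.frame(triangleMembers(tris))
  triTab$triple_overlap_size <- lengths(tripleOverlap(tris))
  utils::write.table(cbind(triangle = sprintf("T%d", seq_len(nrow(triTab))),
                           triTab),
                     file.path(outDir, "triangles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  tg <- stage("triangle-graph", buildTriangleGraph(tris, ig, weightMode))
  comms <- stage("communities", detectCommunities(tg, seed = seed))
  if (length(communityMembership(comms)))
    utils::write.table(
      data.frame(triangle = sprintf("T%d", seq_along(communityMembership(comms))),
                 community = communityMembership(comms)),
      file.path(outDir, "communities.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

  ccs <- stage("consensus", extractConsensus(comms, partitions))
  ccTab <- do.call(rbind, lapply(names(consensusClusters(ccs)), function(cc)
    if (length(consensusClusters(ccs)[[cc]]))
      data.frame(gene = consensusClusters(ccs)[[cc]], cluster = cc)))
  if (!is.null(ccTab))
    utils::write.table(ccTab, file.path(outDir, "consensus_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  subsetTab <- NULL
  if (length(matrices) == length(ids) && length(annotations) == length(ids)) {
    contrasts <- config$contrasts %||%
      c("inflammatory", "fibroproliferative", "normal-like")
    subsetTab <- stage("subset-stats",
      subsetSpecificityTable(partitions, matrices, annotations,
                             contrasts = contrasts, alpha = alpha))
    utils::write.table(subsetTab, file.path(outDir, "subset_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  st <- consensusStats(ccs)
  summary <- list(
    datasets = ids,
    modules_per_dataset = as.list(st$totalModules),
    conserved_modules_per_dataset = as.list(st$conservedModules),
    n_triangles = st$nTriangles,
    n_communities = st$nCommunities,
    n_singleton_communities = st$nSingletonCommunities,
    consensus_cluster_sizes =
      as.list(lengths(consensusClusters(ccs))),
    consensus_genes = st$consensusGenes,
    triple_overlap_genes = st$tripleOverlapGenes,
    subset_significant_modules = if (!is.null(subsetTab))
      sum(tapply(subsetTab$significant,
                 paste(subsetTab$dataset, subsetTab$module), any)) else NULL)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    config = config,
    config_md5 = if (!is.null(configPath))
      unname(tools::md5sum(configPath)) else NA,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
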