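# Independent oracles and fixture builders used across the suite.

# Uniform-random partition of `genes` into `k` labels (all labels used are
# whatever sample() drew; modules may be empty in expectation terms only).
randomPartition <- function(dataset, genes, k) {
  GenePartition(dataset,
                stats::setNames(sample(paste0("m", seq_len(k)), length(genes),
                                       replace = TRUE), genes))
}

# Textbook mutual information of two partitions from the full contingency
# table: sum over cells of (n_ij/N) log2(N n_ij / (n_i. n_.j)).  Independent
# of the per-pair W-score path (no shared code).
contingencyMI <- function(a, b, logBase = 2) {
  ga <- moduleAssignment(a); gb <- moduleAssignment(b)
  common <- intersect(names(ga), names(gb))
  N <- length(union(universe(a), universe(b)))
  stopifnot(N == length(common))  # oracle assumes fully assigned shared set
  tab <- table(ga[common], gb[common])
  ri <- rowSums(tab); cj <- colSums(tab)
  mi <- 0
  for (i in seq_along(ri)) for (j in seq_along(cj)) {
    n <- tab[i, j]
    if (n > 0) mi <- mi + (n / N) * log(N * n / (ri[i] * cj[j]), base = logBase)
  }
  unname(mi)
}

# Exhaustive descending-prefix search for the MI-positivity threshold: try
# every prefix length of the descending-sorted scores and return the value at
# the shortest prefix whose sum reaches the total.
bruteThreshold <- function(scores) {
  total <- sum(scores)
  s <- sort(scores, decreasing = TRUE)
  for (i in seq_along(s)) {
    if (sum(s[seq_len(i)]) >= total - 1e-9 * max(1, abs(total)))
      return(s[i])
  }
  stop("no prefix reached the total")  # unreachable: full sum == total
}

# Build an InformationGraph directly from an edge table, with one unique
# gene per module so overlap bookkeeping stays valid.
graphFromEdges <- function(edges, parts) {
  mods <- unique(rbind(data.frame(part = edges$part_a, mod = edges$module_a),
                       data.frame(part = edges$part_b, mod = edges$module_b)))
  partitions <- lapply(parts, function(p) {
    m <- mods$mod[mods$part == p]
    if (!length(m)) m <- "empty"
    GenePartition(p, stats::setNames(m, paste0(p, "_", m)))
  })
  names(partitions) <- parts
  new("InformationGraph", parts = parts, edges = edges,
      pairs = list(), partitions = partitions)
}

# Brute-force enumeration of cross-all-parts triangles by triple loop.
bruteTriangles <- function(edges, parts) {
  stopifnot(length(parts) == 3)
  key <- function(pa, ma, pb, mb) {
    a <- paste(pa, ma, sep = ":"); b <- paste(pb, mb, sep = ":")
    ifelse(a < b, paste(a, b), paste(b, a))
  }
  keys <- key(edges$part_a, edges$module_a, edges$part_b, edges$module_b)
  has <- function(pa, ma, pb, mb) key(pa, ma, pb, mb) %in% keys
  nodes <- function(p) unique(c(edges$module_a[edges$part_a == p],
                                edges$module_b[edges$part_b == p]))
  out <- list()
  for (x in nodes(parts[1])) for (y in nodes(parts[2])) for (z in nodes(parts[3])) {
    if (has(parts[1], x, parts[2], y) && has(parts[2], y, parts[3], z) &&
        has(parts[1], x, parts[3], z))
      out[[length(out) + 1L]] <- c(x, y, z)
  }
  m <- if (length(out)) do.call(rbind, out) else matrix(character(), ncol = 3)
  colnames(m) <- parts
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Random sparse tripartite edge table over <= nPerPart nodes per part.
randomTripartiteEdges <- function(nPerPart, pEdge = 0.35) {
  parts <- c("A", "B", "C")
  rows <- list()
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    for (i in seq_len(nPerPart)) for (j in seq_len(nPerPart)) {
      if (stats::runif(1) < pEdge)
        rows[[length(rows) + 1L]] <- data.frame(
          part_a = pr[1], module_a = paste0(pr[1], i),
          part_b = pr[2], module_b = paste0(pr[2], j),
          weight = stats::runif(1, 0.01, 1))
    }
  }
  if (!length(rows))
    return(data.frame(part_a = character(), module_a = character(),
                      part_b = character(), module_b = character(),
                      weight = numeric()))
  do.call(rbind, rows)
}

# Eigengene stub: wrap precomputed scores for the statistics layer.
eigengeneFromScores <- function(scores, module = c("toy", "m")) {
  new("Eigengene", module = module, scores = scores,
      varExplained = 1, orientationSign = 1)
}

# Small complete expression SummarizedExperiment from a plain matrix.
seFromMatrix <- function(mat) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    rowData = S4Vectors::DataFrame(NAME = rownames(mat),
                                   row.names = rownames(mat)))
}
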