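#' Specify a synthetic multi-cohort study
#'
#' Builds a [SyntheticSpec-class] describing a simulated multi-cohort
#' transcriptomic study over a shared gene universe.  The defaults plant 10
#' conserved 50-gene blocks in 3 cohorts of 40 samples each, with residual
#' noise SD 0.5 around each module's latent factor and 5% of entries missing
#' at random — a desk-scale emulation of multi-center microarray cohorts with
#' a few dozen arrays each.
#'
#' @param nGenes gene-universe size.
#' @param nDatasets number of cohorts.
#' @param nSamples per-dataset sample counts (recycled to `nDatasets`).
#' @param blocks data.frame with columns `block`, `size`, `mode`; modes are
#'   `"conserved"`, `"split:j"`, `"shuffled"`, `"absent-in:<dataset-index>"`.
#'   Default: 10 conserved blocks of 50 genes.
#' @param subsetEffects data.frame with columns `block`, `subset`, `shift`:
#'   mean shift (in latent-factor SD units) of that block's expression in
#'   samples of that subset.
#' @param noiseSD residual per-gene noise SD.
#' @param missingRate probability of an entry being missing at random.
#' @param subsetProportions named proportions for sample subset labels.
#' @param nNoiseModules number of dataset-specific noise-module labels used
#'   for `"shuffled"` blocks.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes = 2000L, nDatasets = 3L,
                          nSamples = 40L,
                          blocks = data.frame(
                            block = sprintf("B%02d", 1:10),
                            size = 50L, mode = "conserved"),
                          subsetEffects = data.frame(
                            block = character(), subset = character(),
                            shift = numeric()),
                          noiseSD = 0.5, missingRate = 0.05,
                          subsetProportions = c(
                            "inflammatory" = 0.35,
                            "fibroproliferative" = 0.26,
                            "normal-like" = 0.17,
                            "limited" = 0.09,
                            "healthy-control" = 0.13),
                          nNoiseModules = 5L) {
  new("SyntheticSpec", nGenes = as.integer(nGenes),
      nDatasets = as.integer(nDatasets),
      nSamples = rep_len(as.integer(nSamples), nDatasets),
      blocks = blocks, subsetEffects = subsetEffects,
      noiseSD = noiseSD, missingRate = missingRate,
      subsetProportions = subsetProportions,
      nNoiseModules = as.integer(nNoiseModules))
}

.synGenes <- function(spec) sprintf("g%05d", seq_len(spec@nGenes))

.synDatasets <- function(spec) sprintf("D%d", seq_len(spec@nDatasets))

#' Generate per-dataset partitions with planted structure
#'
#' Emits one [GenePartition-class] per simulated cohort.  `"conserved"`
#' blocks appear as one identically-membered module in every dataset;
#' `"split:j"` blocks appear whole in the first dataset and as `j` contiguous
#' pieces elsewhere, with piece boundaries rotated by half a piece per dataset
#' so the pieces re-assort across datasets; `"shuffled"` block genes are
#' assigned to one of `nNoiseModules` dataset-specific noise modules
#' independently at random per dataset; `"absent-in:<d>"` blocks are
#' outliers in dataset `d` and conserved modules elsewhere.  Genes outside
#' every block are outliers in every dataset, mimicking the unassigned (grey)
#' genes a clustering run leaves behind.
#'
#' @param spec a [SyntheticSpec-class].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `partitions` (list of [GenePartition-class]) and `truth`
#'   (list with `blockGenes`, `consensusSets` — the planted gene sets a
#'   perfect consensus recovery would return — and `expectedTriangles`).
#' @export
generatePartitions <- function(spec, seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(seed)
  genes <- .synGenes(spec)
  dsets <- .synDatasets(spec)
  blocks <- spec@blocks
  if (sum(blocks$size) > spec@nGenes)
    stop("planted blocks exceed the gene universe")
  blockGenes <- list()
  at <- 1L
  for (i in seq_len(nrow(blocks))) {
    blockGenes[[blocks$block[i]]] <- genes[at:(at + blocks$size[i] - 1L)]
    at <- at + blocks$size[i]
  }
  background <- if (at <= spec@nGenes) genes[at:spec@nGenes] else character()
  parts <- list()
  expectedTriangles <- 0L
  consensusSets <- list()
  for (di in seq_along(dsets)) {
    asg <- character(); asgNames <- character(); outl <- background
    bg <- character()
    for (i in seq_len(nrow(blocks))) {
      b <- blocks$block[i]; mode <- blocks$mode[i]; bg_i <- blockGenes[[b]]
      if (identical(mode, "conserved")) {
        asg <- c(asg, rep(b, length(bg_i))); asgNames <- c(asgNames, bg_i)
      } else if (grepl("^split:[0-9]+$", mode)) {
        j <- as.integer(sub("^split:", "", mode))
        if (di == 1L || j == 1L) {
          asg <- c(asg, rep(b, length(bg_i))); asgNames <- c(asgNames, bg_i)
        } else {
          # piece boundaries rotate by half a piece per dataset, so pieces
          # re-assort (overlap) across datasets instead of replicating
          len <- length(bg_i)
          off <- ((di - 2L) * (len %/% (2L * j))) %% len
          piece <- (((seq_len(len) - 1L + off) %% len) * j) %/% len + 1L
          asg <- c(asg, paste0(b, ".", piece)); asgNames <- c(asgNames, bg_i)
        }
      } else if (identical(mode, "shuffled")) {
        bg <- c(bg, bg_i)
      } else if (grepl("^absent-in:[0-9]+$", mode)) {
        d0 <- as.integer(sub("^absent-in:", "", mode))
        if (di == d0) outl <- c(outl, bg_i)
        else { asg <- c(asg, rep(b, length(bg_i))); asgNames <- c(asgNames, bg_i) }
      } else stop("unknown block mode: ", mode)
    }
    if (length(bg)) {
      lab <- sample(sprintf("noise%d", seq_len(spec@nNoiseModules)),
                    length(bg), replace = TRUE)
      asg <- c(asg, lab); asgNames <- c(asgNames, bg)
    }
    parts[[dsets[di]]] <- GenePartition(
      dsets[di], stats::setNames(asg, asgNames), outliers = outl)
  }
  for (i in seq_len(nrow(blocks))) {
    mode <- blocks$mode[i]
    if (identical(mode, "conserved")) {
      expectedTriangles <- expectedTriangles + 1L
      consensusSets[[blocks$block[i]]] <- blockGenes[[blocks$block[i]]]
    } else if (grepl("^split:", mode)) {
      j <- as.integer(sub("^split:", "", mode))
      # whole module in dataset 1 + half-piece-rotated pieces elsewhere:
      # each piece overlaps two neighbours, closing 2j cliques (j if unsplit)
      expectedTriangles <- expectedTriangles + if (j == 1L) 1L else 2L * j
      consensusSets[[blocks$block[i]]] <- blockGenes[[blocks$block[i]]]
    }
  }
  list(partitions = parts,
       truth = list(blockGenes = blockGenes,
                    consensusSets = consensusSets,
                    expectedTriangles = expectedTriangles,
                    background = background))
}

#' Generate expression matrices and subset annotations
#'
#' Latent-factor model: each module of each dataset carries a standard-normal
#' latent factor per sample; a gene's value is its module's factor plus
#' `noiseSD` Gaussian noise.  Sample subset labels are allocated in exact
#' proportion (largest-remainder rounding) and shuffled, so arm sizes are
#' deterministic given the sample count.  Planted subset effects add their shift to the
#' block's factor in samples of the named subset.  Outlier genes (and nothing
#' else) are pure noise of matched variance.  Entries are then dropped at
#' `missingRate` uniformly at random; a mask that would wipe out a whole gene
#' row is redrawn for that gene.
#'
#' @param spec a [SyntheticSpec-class].
#' @param generated output of [generatePartitions()] for the same spec.
#' @param seed integer seed for the expression layer.
#' @return list with `matrices` (named list of `SummarizedExperiment`s) and
#'   `annotations` (named list of named character vectors sample -> subset).
#' @export
generateExpression <- function(spec, generated, seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(seed + 1L)
  dsets <- .synDatasets(spec)
  parts <- generated$partitions
  eff <- spec@subsetEffects
  matrices <- list(); annotations <- list()
  for (di in seq_along(dsets)) {
    d <- dsets[di]
    n <- spec@nSamples[di]
    samples <- sprintf("%s_s%02d", d, seq_len(n))
    # largest-remainder allocation: label counts match the proportions
    # exactly (up to integer rounding), then the order is shuffled
    prop <- spec@subsetProportions
    cnt <- floor(prop * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(prop * n - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    ann <- stats::setNames(
      sample(rep(names(prop), times = cnt)), samples)
    p <- parts[[d]]
    asg <- moduleAssignment(p)
    mods <- unique(asg)
    factors <- matrix(stats::rnorm(length(mods) * n), nrow = length(mods),
                      dimnames = list(mods, samples))
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        hit <- mods == eff$block[i] |
          startsWith(mods, paste0(eff$block[i], "."))
        who <- ann == eff$subset[i]
        if (any(hit) && any(who))
          factors[hit, who] <- factors[hit, who] + eff$shift[i]
      }
    }
    allGenes <- universe(p)
    mat <- matrix(NA_real_, length(allGenes), n,
                  dimnames = list(allGenes, samples))
    gAsg <- names(asg)
    mat[gAsg, ] <- factors[asg, , drop = FALSE] +
      spec@noiseSD * stats::rnorm(length(gAsg) * n)
    out <- outlierGenes(p)
    if (length(out))
      mat[out, ] <- stats::rnorm(length(out) * n,
                                 sd = sqrt(1 + spec@noiseSD^2))
    if (spec@missingRate > 0) {
      for (i in seq_len(nrow(mat))) {
        repeat {
          drop <- stats::runif(n) < spec@missingRate
          if (!all(drop)) break
        }
        mat[i, drop] <- NA_real_
      }
    }
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat),
      rowData = S4Vectors::DataFrame(NAME = allGenes, row.names = allGenes))
    matrices[[d]] <- se
    annotations[[d]] <- ann
  }
  list(matrices = matrices, annotations = annotations)
}
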