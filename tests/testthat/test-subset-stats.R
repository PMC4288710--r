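annFor <- function(scores, labels) setNames(labels, names(scores))

test_that("directional Wilcoxon reproduces the exact rank-sum tail", {
  sc <- setNames(c(3, 4, 5, 0, 1, 2), sprintf("s%d", 1:6))
  ann <- annFor(sc, c(rep("inflammatory", 3), rep("normal-like", 3)))
  e <- eigengeneFromScores(sc)
  res <- directionalWilcoxon(e, ann, "inflammatory")
  expect_identical(res$direction, "up")
  expect_equal(res$p_raw, 1 / 20)   # 1 of choose(6,3) arrangements
  expect_false(res$tie)
})

test_that("direction down on negated scores mirrors direction up exactly", {
  set.seed(61)
  sc <- setNames(rnorm(30), sprintf("s%d", 1:30))
  ann <- annFor(sc, sample(c(rep("inflammatory", 12), rep("normal-like", 18))))
  up <- directionalWilcoxon(eigengeneFromScores(sc + 2 * (ann == "inflammatory")),
                            ann, "inflammatory")
  dn <- directionalWilcoxon(eigengeneFromScores(-(sc + 2 * (ann == "inflammatory"))),
                            ann, "inflammatory")
  expect_identical(up$direction, "up")
  expect_identical(dn$direction, "down")
  expect_equal(up$p_raw, dn$p_raw)
})

test_that("median ties break to 'up' and are flagged", {
  sc <- setNames(c(1, 2, 3, 1, 2, 3), sprintf("s%d", 1:6))
  ann <- annFor(sc, c(rep("inflammatory", 3), rep("normal-like", 3)))
  res <- directionalWilcoxon(eigengeneFromScores(sc), ann, "inflammatory")
  expect_identical(res$direction, "up")
  expect_true(res$tie)
})

test_that("degenerate subset designs are rejected", {
  sc <- setNames(1:4, sprintf("s%d", 1:4))
  allOne <- annFor(sc, rep("inflammatory", 4))
  expect_error(directionalWilcoxon(eigengeneFromScores(sc), allOne,
                                   "inflammatory"), "complement")
  expect_error(directionalWilcoxon(eigengeneFromScores(sc), allOne,
                                   "fibroproliferative"), "no samples")
  badLab <- annFor(sc, rep("mystery", 4))
  expect_error(directionalWilcoxon(eigengeneFromScores(sc), badLab,
                                   "mystery"), "unknown subset label")
})

test_that("Bonferroni correction is monotone, capped, and scales with n_tests", {
  set.seed(63)
  sc <- setNames(rnorm(20), sprintf("s%d", 1:20))
  ann <- annFor(sc, rep(c("inflammatory", "normal-like"), 10))
  e <- eigengeneFromScores(sc)
  r1 <- directionalWilcoxon(e, ann, "inflammatory", nTests = 1)
  r100 <- directionalWilcoxon(e, ann, "inflammatory", nTests = 100)
  expect_equal(r100$p_bonferroni, min(1, r1$p_raw * 100))
  expect_lte(r100$p_bonferroni, 1)
  expect_gte(r100$p_bonferroni, r1$p_bonferroni)
})

test_that("Kruskal-Wallis screen handles identical groups and calibrates type I", {
  sc <- setNames(rep(c(5, 7, 9), 2), sprintf("s%d", 1:6))
  ann <- annFor(sc, c(rep("inflammatory", 3), rep("normal-like", 3)))
  res <- kruskalWallisModule(eigengeneFromScores(sc), ann)
  expect_equal(res$p_raw, 1)   # identical value multisets: H = 0

  set.seed(64)
  labels <- c(rep("inflammatory", 12), rep("fibroproliferative", 10),
              rep("normal-like", 8))
  rejections <- vapply(1:1000, function(i) {
    sc <- setNames(rnorm(30), sprintf("s%d", 1:30))
    kruskalWallisModule(eigengeneFromScores(sc),
                        annFor(sc, labels))$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)

  tiny <- annFor(setNames(1:3, sprintf("s%d", 1:3)),
                 c("inflammatory", "inflammatory", "normal-like"))
  expect_error(kruskalWallisModule(eigengeneFromScores(
    setNames(1:3, sprintf("s%d", 1:3))), tiny), "normal-like")
})

test_that("two-group Kruskal-Wallis p approximates the exact permutation law", {
  set.seed(65)
  for (i in 1:5) {
    sc <- setNames(rnorm(8), sprintf("s%d", 1:8))
    ann <- annFor(sc, c(rep("inflammatory", 4), rep("normal-like", 4)))
    pKW <- kruskalWallisModule(eigengeneFromScores(sc), ann)$p_raw
    # exhaustive permutation of the group labels: exact null of H
    idx <- combn(8, 4)
    hOf <- function(sel) {
      g <- factor(ifelse(seq_len(8) %in% sel, "a", "b"))
      kruskal.test(sc, g)$statistic
    }
    hObs <- hOf(1:4)
    hAll <- apply(idx, 2, hOf)
    pPerm <- mean(hAll >= hObs - 1e-12)
    # at n = 4 + 4 the chi-square reference for H is accurate to roughly
    # one part in ten of the exact permutation tail
    expect_lt(abs(pKW - pPerm), 0.15)
  }
})

test_that("planted subset shifts are flagged in the right subset and direction", {
  spec <- syntheticSpec(
    nGenes = 300, nDatasets = 1L, nSamples = 40L,
    blocks = data.frame(block = c("B1", "B2", "B3"), size = 40,
                        mode = "conserved"),
    subsetEffects = data.frame(block = "B2", subset = "inflammatory",
                               shift = 2),
    missingRate = 0)
  gen <- generatePartitions(spec, seed = 71)
  expr <- generateExpression(spec, gen, seed = 71)
  tab <- subsetSpecificityTable(gen$partitions, expr$matrices,
                                expr$annotations,
                                contrasts = c("inflammatory",
                                              "fibroproliferative"))
  hit <- tab[tab$significant, ]
  expect_identical(unique(hit$module), "B2")
  expect_identical(unique(hit$contrast), "inflammatory")
  expect_identical(unique(hit$direction), "up")
})

test_that("single-label annotations yield an empty, zero-significant table", {
  spec <- syntheticSpec(nGenes = 100, nDatasets = 1L, nSamples = 20L,
                        blocks = data.frame(block = "B1", size = 30,
                                            mode = "conserved"),
                        subsetProportions = c("inflammatory" = 1),
                        missingRate = 0)
  gen <- generatePartitions(spec, seed = 3)
  expr <- generateExpression(spec, gen, seed = 3)
  tab <- subsetSpecificityTable(gen$partitions, expr$matrices,
                                expr$annotations)
  expect_identical(sum(tab$significant), 0L)
})

test_that("missing healthy controls fail the all-SSc contrast loudly", {
  sc <- setNames(rnorm(10), sprintf("s%d", 1:10))
  ann <- annFor(sc, rep(c("inflammatory", "normal-like"), 5))
  expect_error(micc:::.contrastArms(ann, "allSSc-vs-control"),
               "healthy controls")
})

test_that("hub enrichment is extreme for eigengene copies, calibrated under null", {
  set.seed(73)
  spec <- syntheticSpec(nGenes = 150, nDatasets = 1L, nSamples = 30L,
                        blocks = data.frame(block = c("B1", "B2", "B3"),
                                            size = 40, mode = "conserved"),
                        noiseSD = 1, missingRate = 0)
  gen <- generatePartitions(spec, seed = 5)
  expr <- generateExpression(spec, gen, seed = 5)
  p <- gen$partitions[[1]]
  se <- expr$matrices[[1]]

  # make every B1 gene a literal copy of the module eigengene so the module
  # profile (and hence each gene-eigengene correlation) is exact
  e <- moduleEigengene(se, modules(p)$B1, module = c("D1", "B1"))
  copies <- modules(p)$B1
  mat <- SummarizedExperiment::assay(se)
  mat[copies, ] <- matrix(rep(eigengeneScores(e), each = length(copies)),
                          nrow = length(copies))
  seCopy <- seFromMatrix(mat)
  res <- hubnessEnrichment(list(D1 = seCopy), list(D1 = p), copies)
  expect_true(all(res$consensusCorrelations > 0.999))
  expect_lt(res$p, 1e-6)

  # random consensus choice: mostly non-significant
  sig <- vapply(1:20, function(i) {
    cons <- sample(names(moduleAssignment(p)), 30)
    hubnessEnrichment(expr$matrices, list(D1 = p), cons)$p < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.2)

  # degenerate single-module dataset still defines the test
  single <- GenePartition("D1", setNames(rep("B1", 40), modules(p)$B1))
  res1 <- hubnessEnrichment(expr$matrices, list(D1 = single),
                            modules(p)$B1[1:10])
  expect_true(is.finite(res1$p))
  expect_error(hubnessEnrichment(expr$matrices, list(D1 = p), character()),
               "empty")
})
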