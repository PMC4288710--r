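# micc — Mutual Information Consensus Clustering

`micc` identifies gene co-expression modules that are **conserved across
multiple independently clustered transcriptomic datasets**, and extracts the
disjoint "consensus clusters" of genes those conserved modules agree on.

It is aimed at meta-analyses of multi-cohort expression studies: each cohort
has been clustered on its own (for example by WGCNA), the resulting
gene-to-module partitions differ in detail because of cohort composition,
platform handling and clinical heterogeneity, and the question is which
modules — and which genes inside them — reproduce in *every* cohort.  The
motivating use case is multi-center skin transcriptomics in systemic
sclerosis, where the inflammatory, fibroproliferative and normal-like
intrinsic patient subsets recur across cohorts but the module boundaries do
not.

## The method

Let `C_i` and `C_j` be modules from two datasets' partitions over a shared
universe of `N` genes, with `o = |C_i ∩ C_j|`.  Each module pair gets an
overlap score

```
W(C_i, C_j) = (o / N) · log2( N · o / (|C_i| · |C_j|) )
```

which is the additive term of the **mutual information of partitions**:
summed over all module pairs, the W-scores equal the total mutual information
between the two genomic partitions.  `W > 0` exactly when the overlap exceeds
the independence expectation `|C_i||C_j|/N`.

The pipeline then:

1. **Thresholds by MI positivity** — per dataset pair, the W-scores are
   sorted in descending order and the smallest prefix whose cumulative sum
   reaches the total mutual information is kept; everything below (including
   every negative score) is discarded.  No p-value or tuning parameter is
   involved.
2. **Builds the k-partite information graph** — nodes are (dataset, module)
   pairs, edges are the surviving positive overlaps.  A triangle (in general
   a cross-all-parts k-clique) marks a module conserved in *every* dataset.
3. **Clusters the triangle graph** — triangles sharing an information-graph
   edge are linked (edge weight = sum of shared W-scores) and communities are
   found by greedy modularity maximization, a variant of triangle (clique)
   percolation.  Communities capture modules that split and re-assort across
   datasets.
4. **Extracts consensus clusters** — per community: union of its modules
   within each dataset, then intersection across datasets.  The resulting
   gene sets are pairwise disjoint, asserted on every run.
5. **Tests subset specificity** — each module is summarized by its
   eigengene (first principal component of the unit-normalized module
   expression) and screened against sample subset annotations with
   Kruskal-Wallis and directional Wilcoxon rank-sum tests under Bonferroni
   correction, plus a hub-gene (gene-eigengene correlation) enrichment check
   for the consensus genes.

A synthetic multi-cohort generator with planted conserved / split / absent
blocks, subset mean shifts and missing-at-random entries makes every stage
testable without any external download.

## Worked example

Three simulated 500-gene cohorts: an "IFN" block conserved everywhere and
shifted +2 SD in inflammatory samples, a "CellCycle" block that is whole in
cohort D1 but split into re-assorting pieces in D2/D3, and a conserved "ECM"
block.

```r
library(micc)

spec <- syntheticSpec(nGenes = 500,
                      blocks = data.frame(block = c("IFN", "CellCycle", "ECM"),
                                          size = c(60, 50, 40),
                                          mode = c("conserved", "split:2", "conserved")),
                      subsetEffects = data.frame(block = "IFN",
                                                 subset = "inflammatory", shift = 2))
gen  <- generatePartitions(spec, seed = 42)
expr <- generateExpression(spec, gen, seed = 42)

ig <- buildInformationGraph(gen$partitions)
ig
#> InformationGraph: 3 parts (D1, D2, D3), 14 supra-threshold edges

ig@pairs[["D1|D2"]]
#> PairScores D1 vs D2: 3 x 4 module pairs, N = 500
#>   total MI = 0.9908 (base 2), threshold = 0.1661, kept 4 pairs

tris <- enumerateTriangles(ig)
tris
#> TriangleSet: 6 conserved-module 3-cliques over parts D1, D2, D3

comms <- detectCommunities(buildTriangleGraph(tris, ig))
comms
#> CommunitySet: 3 communities over 6 triangles (2 singletons)

ccs <- extractConsensus(comms, gen$partitions)
ccs
#> ConsensusClusterSet: 3 clusters, 150 consensus genes
#>   sizes: 60 50 40
```

The split CellCycle block produces four triangles (the whole D1 module paired
with every overlapping piece combination) that merge into one community, so
its consensus cluster reunites all 50 genes; the two conserved blocks appear
as singleton-triangle communities.  The planted subset shift is recovered in
every cohort:

```r
tab <- subsetSpecificityTable(gen$partitions, expr$matrices, expr$annotations,
                              contrasts = c("inflammatory", "fibroproliferative"))
subset(tab, significant,
       select = c(dataset, module, contrast, direction, p_bonferroni))
#>    dataset module     contrast direction p_bonferroni
#> 5       D1    IFN inflammatory        up 1.752475e-04
#> 13      D2    IFN inflammatory        up 1.648232e-05
#> 21      D3    IFN inflammatory        up 1.534446e-04
```

`runPipeline()` (or the `inst/cli/micc.R` script) chains all stages from PCL
expression files, partition TSVs and annotation TSVs to a `summary.json` of
counts, GEXF network exports and the consensus-cluster table.

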