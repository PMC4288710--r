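---
title: "Consensus clustering of co-expression modules by mutual information of partitions"
author: "micc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of co-expression modules by mutual information of partitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micc)
```

## The problem

Co-expression clustering of a single transcriptomic dataset partitions the
expressed genes into modules — groups of genes whose expression covaries and
which usually map onto biological processes.  When several independent
cohorts profile the same disease, each cohort yields its own partition, and
the partitions never agree exactly: cohort composition, treatment, RNA
handling and the clustering algorithm's own instabilities all move module
boundaries.  Intersecting per-cohort gene lists is far too conservative,
because a gene that narrowly misses significance in one cohort disappears
from the consensus even when its whole module reproduces.

`micc` takes a modules-first view: first decide which *modules* are conserved
across all cohorts, then collect the genes those conserved modules agree on.
The multiple-testing burden falls on a few dozen modules instead of tens of
thousands of genes.

## Overlap scores and the information graph

For modules $C_i$ (dataset $A$) and $C_j$ (dataset $B$) over a shared
universe of $N$ genes with overlap $o = |C_i \cap C_j|$, the overlap score is

$$W(C_i, C_j) \;=\; \frac{o}{N}\,\log_2\!\frac{N\,o}{|C_i|\,|C_j|},
\qquad 0 \log 0 := 0 .$$

These are precisely the additive terms of the mutual information of the two
partitions: $\sum_{i,j} W(C_i, C_j) = I(A; B)$, verified in the test suite
against an independent contingency-table computation to $10^{-9}$ relative
tolerance.  $W$ is positive when the overlap exceeds the independence
expectation $|C_i||C_j|/N$, negative when depleted, and zero at independence.

**Thresholding by MI positivity.**  Per dataset pair, the W-scores are sorted
in descending order and the shortest prefix whose cumulative sum reaches the
total mutual information is retained; the threshold is the last retained
value.  The discarded tail — every negative score and the small positive
scores that merely cancel them — sums to zero, so the retained edges carry
essentially all of the mutual information between the two partitions.  When
several equal scores straddle the crossing, all are kept, which makes the
rule deterministic and order-independent.  There is no tuning parameter: the
data decide how many overlaps are informative.

Surviving positive overlaps become edges of the **information graph**, which
is $k$-partite by construction (one part per dataset; no edges within a
dataset).  The `universePolicy` argument controls the genome size $N$:

* `"pair-intersection"` (default): genes present in both datasets' universes.
  Per-dataset filtering makes a single global $N$ ill-defined, so the
  pairwise intersection is the safest default.
* `"union"`, or `"fixed:<n>"` when an external genome size is known.

Outlier genes — examined but left unassigned by the upstream clustering —
count toward $N$ but belong to no module, so they depress all overlaps, as
they should.

## Triangles, the triangle graph, and communities

A triangle (for $k$ datasets, a cross-all-parts $k$-clique) joins one module
per dataset, all pairwise conserved: a module conserved across *all*
datasets.  All triangles are enumerated exactly (the per-part node counts are
small, so exhaustive clique extension is cheap and is cross-checked against a
brute-force triple loop in the tests).

Modules rarely map one-to-one across datasets; a module in one cohort breaks
into pieces that re-assort into the modules of another.  This shows up as
triangles sharing information-graph edges.  The **triangle graph** has the
triangles as nodes and joins two triangles when they share at least one
information-graph edge (equivalently, agree on the module in at least two
datasets).  Edge weights default to the sum of the shared edges' W-scores
(`"shared-w"`), preserving overlap strength; a `"binary"` mode is available.
The weighting is a design choice of this package — the shared-edge criterion
fixes the topology, but no canonical weight exists.

Communities of triangles are found by greedy modularity maximization
(Clauset–Newman–Moore, via `igraph::cluster_fast_greedy`) on the weighted
triangle graph — a variant of clique percolation in which modularity, rather
than bare connectivity, separates densely edge-sharing triangle groups.
Every triangle lands in exactly one community; isolated triangles become
singleton communities; a *module* may appear in several communities.  The
algorithm is deterministic given the canonical (lexicographic) triangle
ordering, so the `seed` argument is accepted for interface stability but not
consumed.  Communities are numbered by decreasing triangle count with
first-triangle tie-breaks.

One known degeneracy: a perfectly symmetric ring of triangles (as produced by
an exactly half-rotated synthetic split block) ties the modularity of "one
community" against "two arcs", and the greedy merge order then decides.  Real
overlaps are never exactly symmetric, so this arises only in adversarially
regular synthetic input; the test suite asserts in that case that the
communities jointly reunite the block rather than prescribing their number.

## Consensus clusters

For a community, the consensus cluster is

$$CC \;=\; \bigcap_{d \in \text{datasets}} \;\bigcup_{m \in \text{community
modules of } d} m ,$$

the genes assigned to a community module in *every* dataset.  Consensus
clusters are pairwise disjoint in every run of the pipeline and this is
asserted at extraction time: a gene occupies exactly one module per dataset,
so two communities can both claim it only if they share its entire module
tuple, which the community structure of real and planted inputs does not
produce.  The assertion turns any counterexample into a loud
internal-consistency error rather than a silent double count.

## Module eigengenes and subset statistics

Each module is summarized by its **eigengene**: every gene's expression
vector is scaled to unit Euclidean norm (after imputing missing entries with
the gene's median, which is 0 for median-centered data) and the first right
singular vector across samples is taken, oriented to correlate positively
with the module's mean profile.  The eigengene is the module's most central
("hub") expression pattern; the fraction of variance it explains is reported.

Subset association uses sample annotations over a closed vocabulary
(inflammatory, fibroproliferative, normal-like, limited, healthy-control,
morphea, unknown):

* `kruskalWallisModule()` — omnibus tie-corrected Kruskal–Wallis screen of an
  eigengene across subsets.
* `directionalWilcoxon()` — picks the direction from the subset median versus
  the whole population's median (ties break to "up" and are flagged), then
  reports the one-tailed Wilcoxon rank-sum p in that direction.  P-values are
  exact for arms of at most 25 samples without ties, otherwise
  normal-approximated with tie and continuity correction.
* `subsetSpecificityTable()` — one row per module × contrast, Bonferroni
  corrected over (total modules across datasets) × (number of contrasts),
  e.g. 178 × 4 for a three-cohort screen with four contrasts.

**A calibration subtlety.**  Selecting the test direction from the data and
then testing one-tailed at a fixed threshold roughly doubles the type-I rate:
on permuted labels the literal procedure shows ~8–10% family-wise error at a
nominal 5% even under Bonferroni.  The screening table therefore reports the
*direction* from the medians but calls *significance* on the two-sided
rank-sum p — the valid p-value for a data-selected direction — which restores
family-wise control (measured ≤ 0.05 over 100 permuted-label simulations in
the acceptance suite).  `directionalWilcoxon()` itself keeps the pure
one-tailed tail for prespecified directions and documents the caveat.

Contrast definitions: each subset label against all other annotated samples;
`allSSc-vs-control` (all disease subsets vs healthy controls — it is an error
to request this in a cohort without controls); and
`nonNormal-vs-normalHealthy` (inflammatory + fibroproliferative + limited vs
normal-like + healthy controls).  Both composite readings of a "fourth
contrast" are provided because published usage varies between them; the
caller chooses.

`hubnessEnrichment()` closes the loop: consensus genes should be
*hub-enriched*, i.e. more correlated with their own module eigengene than the
remaining clustered genes.  A one-sided two-sample Wilcoxon test compares the
two correlation distributions; on random "consensus" choices the test is
calibrated (non-significant in the expected fraction of simulations).

## The synthetic cohort generator

`syntheticSpec()` describes a simulated study; `generatePartitions()` and
`generateExpression()` realize it deterministically from a seed.  The
generator emulates the structure that matters to the method — and nothing
else:

* **Planted blocks** with per-block conservation modes: `conserved` (same
  module everywhere), `split:j` (whole in dataset 1; `j` contiguous pieces
  elsewhere, boundaries rotated by half a piece per dataset so the pieces
  re-assort and the triangles chain into a community), `shuffled` (labels
  drawn independently per dataset from `nNoiseModules` noise modules),
  `absent-in:<d>` (outliers in dataset *d*, conserved elsewhere).
* **Background genes** outside every block are outliers in every dataset,
  mimicking the unassigned (grey) remainder a clustering run leaves behind.
  Scattering the background into random modules instead creates uniform
  random partitions of the same large gene pool in every dataset — a
  combinatorially pathological input real clustering output does not
  resemble.
* **Expression** follows a single latent factor per module (standard normal
  per sample) plus `noiseSD` gene-level noise; subset effects add a mean
  shift, in factor SD units, to a block's factor in samples of one subset.
  Missing entries are dropped at `missingRate` uniformly; a mask that would
  empty a gene row is redrawn.
* **Subset labels** are allocated in exact proportion (largest-remainder
  rounding, then shuffled), so arm sizes are deterministic: default
  proportions 0.35 / 0.26 / 0.17 / 0.09 inflammatory / fibroproliferative /
  normal-like / limited plus 0.13 healthy controls, echoing the rough mix of
  published multi-center skin cohorts while retaining a control arm.

Default study conditions: 3 datasets of 40 samples, 2000 genes, 10 conserved
50-gene blocks, `noiseSD = 0.5`, `missingRate = 0.05`.  At these conditions
the full pipeline recovers the planted blocks with mean per-block Jaccard
≥ 0.9 over 20 seeds (in practice 1.0, because the partitions are generated,
not re-estimated from the noisy expression).  What the generator deliberately
does *not* model: upstream clustering itself (WGCNA is out of scope — the
package consumes partitions), dye or spatial microarray artifacts, correlated
missingness, and overlapping or nested modules.  Passing tests on synthetic
data therefore certify the consensus machinery and the statistics, not the
behavior of any particular clustering algorithm on real arrays.

## Numerical and interface choices

* **Log base** defaults to 2 (bits) and is configurable; thresholding and
  graph topology are invariant to the base, since all scores scale together.
* **Tolerances**: the W-score/MI identity is enforced at $10^{-9}$ relative;
  the cumulative-sum crossing in the threshold uses the same relative guard
  so that floating-point noise cannot drop the final tied score.
* **Determinism**: partitions are canonicalized by sorting dataset ids, and
  triangles lexicographically, so results are invariant to input order;
  identical seeds give byte-identical generator output and pipeline
  summaries.
* **Degenerate inputs**: a single-module partition carries zero information
  (all W = 0); two-dataset graphs are valid but triangle enumeration refuses
  them and directs the caller to conserved pairs; empty triangle sets yield
  empty community and consensus sets, not errors.
* **File formats**: Stanford PCL (both dialects, with and without
  GWEIGHT/EWEIGHT; empty cell, `NA`, `null` read as missing; missing written
  as empty cell), two-column partition TSV with a configurable outlier label,
  GEXF 1.2 undirected weighted networks, three-column weighted edge lists.
  Gene identity is the probe-identifier column, not the display name.

## Problem sizes

The shipped test and acceptance runs use cohorts of 120–2000 genes, 3
datasets, up to 16 modules per dataset, 1000 random partition pairs for the
MI identity, 200 random tripartite graphs against the brute-force triangle
oracle, and 100-replicate calibration simulations — sizes at which every
property is checked exactly or at tight simulation resolution while the whole
suite stays fast on a single core.

## Known limitations

* The MI-positivity threshold has a finite-size bias: very small modules can
  exceed their (tiny) independence expectation with a single overlapping gene,
  so partitions consisting of many small random modules over the same gene
  pool can sprout spurious supra-threshold edges.  Real clustering output
  (few, large, structured modules plus an unassigned remainder) does not
  behave this way.
* Consensus disjointness is a structural property of realistic community
  configurations, asserted — not proved — for arbitrary adversarial input.
* Greedy modularity can split a perfectly symmetric ring of triangles
  (see above); community *counts* are therefore more sensitive than the
  consensus gene sets themselves, and downstream reporting should lean on
  the latter.
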