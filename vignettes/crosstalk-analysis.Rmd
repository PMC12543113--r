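---
title: "Quantifying altered crosstalk between gene sets on interaction networks"
author: "pathXtalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying altered crosstalk between gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathXtalk)
```

## The problem

Disease phenotypes arise not only from the alteration of individual
processes but from the impairment of the *interconnections* between
processes — within a cell (pathway crosstalk) and between cells
(cell-cell communication). Given

* a gene-centric interaction network (protein-protein, protein-RNA,
  protein-DNA interactions collapsed onto gene pairs),
* a collection of gene sets (pathways, complexes, cell-type marker sets), and
* one or more vectors of gene-level alteration weights in $[0, 1]$
  (typically derived from differential expression),

pathXtalk asks, for every pair of gene sets, whether the interconnectivity
between them is more affected by the gene-level alterations than expected
by chance, and which genes mediate that alteration.

## The crosstalk score

For gene sets $X$ and $Y$ with weight vectors $\mathbf{u}_X$,
$\mathbf{u}_Y$ (positive only on the members of $X$, resp. $Y$) and the
binary adjacency $\mathbf{A} = (a_{ij})$ over the $N_G$ network genes,
the crosstalk score is the bilinear form

$$C(X, Y) = \mathbf{u}_X^\top \mathbf{A}\, \mathbf{u}_Y
          = \sum_{i=1}^{N_G} \sum_{j=1}^{N_G} a_{ij}\, u_X(i)\, u_Y(j).$$

Two link counts complete the decomposition: $L_{XY}$, the number of
network links between $X$ and $Y$ regardless of weights, and
$\delta L_{XY}$, the number of those links whose *both* endpoints carry
positive weight (the altered links; their endpoints are the *contributing
genes*). The saturation

$$r_C = \delta L_{XY} / L_{XY}$$

distinguishes a broad impairment of the interconnection from a
concentrated one: similar scores can come from many weakly weighted links
or from a few strongly weighted ones.

Three scenarios fix how the ingredients are defined:

* **intra** — both sets are states of the same cell; shared genes are
  excluded from both sides ($X \cap Y = \emptyset$, otherwise intra-set
  interactions would be counted) and both sides use the same weight
  source, over a general-purpose interactome.
* **inter** — the sets are marker/DEG sets of two cell types over a
  ligand-receptor network; cell types are expected to share expressed
  genes, so the overlap is kept (a shared gene still never pairs with
  itself: the diagonal of $\mathbf{A}$ is zero), and each side uses its
  own cell type's weight source.
* **integrated** — $X$ is the set of mediator genes of a cell type's
  significant communications, $Y$ ranges over that cell type's pathways;
  the intra rules apply.

In the tables, $\|u_X\|$ and $\|u_Y\|$ are the sums of the
*contributing* genes' weights only, not of the whole set — they summarise
the weight actually engaged in the crosstalk.

## Statistical assessment: two complementary nulls

An observed score $c$ depends on set sizes, the weight distribution and
the degree sequence. Both null models therefore preserve gene-set sizes,
the degree sequence, and (approximately) the association between gene
weight and gene degree, by permuting *gene labels only within degree
bins*:

* $M_A$ relabels the network's genes: memberships and weights stay put
  while the interactions move, probing whether $c$ depends on the network
  proximity of $X$ and $Y$.
* $M_u$ relabels the weights: the full weight vector is relocated within
  degree bins over the fixed network and memberships, probing whether $c$
  depends on the particular placement of the weights.

Degree bins are built by sorting genes by degree (ties broken by gene ID)
and cutting the sorted sequence into $k$ contiguous equal-count
($\pm 1$) groups. `makeDegreeBins()` takes $k$ as the highest value not
exceeding 15 that guarantees non-empty bins; with equal-count bins this
is simply $\min(15, N_G)$, and an explicit `nBins` (e.g. coarser bins for
small ligand-receptor networks) is accepted everywhere. Equal-count
(quantile) bins were chosen over equal-width degree bins because they
never produce empty bins on heavy-tailed degree distributions and keep
the within-bin exchangeable group sizes balanced; the cost is that very
high-degree hubs can share a bin with moderately connected genes, which
makes the nulls slightly more conservative for hub-dominated pairs.

The empirical tail probability uses the add-one convention over
$n_{perm}$ permutations (default 999),

$$\rho = \frac{1 + \#\{c_{null} \ge c_{obs}\}}{1 + n_{perm}},$$

with ties counted towards the tail. The add-one form keeps $\rho > 0$ so
the logarithm below stays finite, and gives the exact floor
$\rho = 0.001$ at 999 permutations. One permutation stream per model is
drawn once per run and shared across pairs (each pair's null is
marginally exact; sharing is faster and keeps runs reproducible from a
single seed); both models share the same binning, so they are strictly
complementary — each disrupts exactly one ingredient.

The two probabilities are combined as the tail probability of a product
of two independent uniforms,

$$p = P(\hat\rho \le \rho_A \rho_u) = z - z\ln z, \qquad z = \rho_A\rho_u,$$

which is Fisher's combined probability test in closed form. Crosstalks
are ranked by the summary score $s = -C(X,Y)\log_{10}(p)$, and classified
by which nulls individually support them at level $\alpha$ (default
0.01): `both`, `MA_only`, `MU_only`, or `neither`. No multiplicity
correction is applied to the classification (the raw-$\rho$ threshold is
the published convention); a Benjamini-Hochberg column `p_bh` over the
combined $p$ is emitted for convenience.

## Pre-filters

Before pair enumeration: genes without any interaction are dropped from
every set; only sets with at least 3 networked members and at least one
positively weighted member are kept; and pairs with $C(X,Y) = 0$ are
discarded (`dropZero = TRUE`), purely to reduce the number of pairs
carried into the permutation stage.

That last filter deliberately conditions on the observed score being
positive, which inflates the tail of $\rho$ *among retained pairs*: if a
fraction $q$ of a pair's null ensemble is zero, then conditionally on
$c_{obs} > 0$ the rejection rate at level $\alpha$ is roughly
$\alpha / (1 - q)$. This is why the calibration checks in the test suite
run with `dropZero = FALSE`: unconditionally, the permutation
probabilities are exactly calibrated (up to the conservativeness induced
by ties at zero), and that is the property a null-model diagnostic should
measure.

## Gene weights from differential expression

Weights are derived per source (condition or cell type) from fold change
$x_i$ and BH-adjusted p-value $p_i$:

$$y_i = -\log_2(x_i)\,\log_{10}(p_i) \quad\text{when } p_i < 0.05
\text{ and } \log_2(x_i) \ge 0.5,\qquad y_i = 0 \text{ otherwise},$$

then $u_i = y_i / \max_i(y_i)$ so each source's maximum is exactly 1.
The effect column may be given as a ratio (`fc`) or already on the log2
scale (`log2fc`); the threshold comparison is non-strict ($\ge 0.5$) by
default with a `strict` switch, since the boundary convention differs
between common DEG-filter phrasings. Adjusted p-values of exactly 0 are
clamped to `pFloor` ($10^{-300}$) with a warning rather than producing
infinite scores. Genes absent from a source's DE table get weight 0,
which the "non-null weight" set filter relies on. Running the
differential expression itself (and its multiplicity correction) is out
of scope: the package consumes DE tables.

```{r weights}
de <- data.frame(gene = c("MDK", "MFGE8", "KRT5"),
                 fc = c(2.2, 1.9, 1.1), p_adj = c(1e-4, 3e-3, 1e-6))
round(normalizeWeights(computeRawScores(de)), 3)
```

## Mediator genes

Given the significant crosstalks (by default those supported by at least
one null at $\alpha$; a `rule = "both"` switch restricts to both-null
support), each contributing gene $g$ receives:

* **crosstalk diversity** $d_X$ — the number of distinct gene sets that
  are partners of significant crosstalks mediated by $g$ (sets containing
  interactors of $g$, which partner sets are by construction). Because
  one partner set can recur across pairs, the pair count `d_x_pairs` is
  emitted alongside the set count. The saturation $r_X$ divides by the
  number of *tested* sets containing at least one interactor of $g$.
* **interactor diversity** $d_A$ — the number of $g$'s network
  interactors belonging to partner sets of its significant crosstalks,
  with saturation $r_A$ dividing by the interactors belonging to any
  tested set.

Saturation denominators count only sets that survived the pre-filters:
the tested universe is the only one in which "all sets containing
interactors of $g$" is a meaningful ceiling. High-diversity genes are
broad mediators; high-saturation genes are selective ones. These scores
are intentionally distinct from topological centralities — a low-degree,
modestly altered gene can still dominate the mediator ranking through
the placement of its interactions.

## Synthetic data: what the generator emulates

`simulateCrosstalkData()` builds the complete study fixture from one
seed (per-stage substreams keep it bit-reproducible):

* **network** — a configuration-model draw with a regular (default
  $k = 8$) or truncated power-law degree sequence, simplified to a simple
  graph. A regular degree of 8 sits in the range of confidence-filtered
  functional interactomes (a few to a few tens of interactions per gene)
  while keeping toy networks sparse.
* **gene sets** — default 20 sets of 25 networked genes; with
  `overlapFrac` $> 0$ every set shares a fixed common core so the
  pairwise overlap is controlled exactly.
* **weights** — for each of `nPlanted` (default 3) randomly chosen set
  pairs, the endpoints of *every* cross-link between the two sets get
  weight `effect` (default 1); the alternative hypothesis of the method
  lives on inter-set links, not on set membership, so planting on links
  (rather than enriching membership) is what distinguishes crosstalk
  from over-representation. A planted pair without cross-links is
  rewired by adding a few edges, so every planted pair carries signal.
  All other genes get weight
  $\mathrm{Bernoulli}(backgroundRate) \cdot U(0, effect/2)$
  (default rate 0.05) as false-positive stress.

What it does **not** emulate: the topology of real interactomes beyond
the degree sequence (no clustering, no community structure, no
ascertainment bias), realistic scRNA-seq noise, or correlated weights
between functionally related genes. Passing the fixture-based tests
therefore shows that the statistics behave as designed under their own
assumptions — not that any particular biological dataset's results are
reproduced. Headline numbers of a real single-cell study (marker counts,
specific significant pairs, named mediator genes) depend on the external
data and database versions and are covered only qualitatively by the
fixture-based workflow test.

```{r fixture}
sim <- simulateCrosstalkData(nGenes = 150, nSets = 8, setSize = 15,
                             nPlanted = 2, seed = 42)
run <- runIntra(sim$network, sim$sets, sim$weights, nPerm = 199, seed = 42)
run
sim$truth
head(run$geneScores)
```

## Numerical and design choices

* **Binary adjacency.** Edge confidence scores (STRING-style) are used
  only by the upstream filter — high-confidence edges plus, per gene
  independently, its top-3 medium-confidence edges, kept as the union
  over genes with ties at the k-th score retained (deterministic and
  order-independent); high-confidence edges do not consume medium
  slots. The score formula multiplies gene weights, not edge scores.
* **Tie handling in $\rho$.** Null samples equal to the observed score
  (within a $10^{-9}$ relative guard for floating-point noise) count
  towards the tail; on degenerate configurations (e.g. $M_A$ on a
  vertex-transitive graph with one bin) this yields $\rho = 1$ exactly
  rather than a spuriously small probability.
* **Determinism.** Pair enumeration is lexicographic; result tables are
  sorted by $s$ descending with set names as tie-breaks; the two null
  streams derive from one user seed. Two runs with the same inputs and
  seed are identical.
* **Degenerate inputs.** $L = 0$ gives $c = 0$, $\delta L = 0$, $r_C = 0$;
  an all-zero weight source, an empty screen, or an empty mediator set
  are errors at the point of cause, not downstream `NaN`s.
* **`n_sources`.** Mediator tables report in how many weight sources a
  gene is altered, useful in multi-cell-type runs.

## Problem sizes

The shipped tests and examples run on synthetic instances of 60–500
genes, 4–20 sets and 99–999 permutations; the statistical checks use
199 permutations with 50 seeds (calibration) and 100 replicates
(recovery). These sizes were chosen so the full statistical behaviour —
calibration within binomial tolerance and $\ge 95\%$ planted-pair
recovery — is exercised in about two minutes on one core; the method
itself scales to interactome-sized inputs (tens of thousands of genes)
since each pair's null costs one sparse matrix-vector product per
permutation.

## Known limitations

* Interactions are undirected and unsigned; ligand→receptor orientation
  is not modelled.
* Interaction databases are biased towards well-studied genes; the nulls
  condition on the observed degree sequence but cannot remove coverage
  bias.
* The $C > 0$ screen makes the *retained-pair* probabilities
  conservative-breaking as analysed above; interpret $\rho$ thresholds
  as ranking devices on screened sets, as the classification does.
* Weight amplification by network diffusion (for sparse inputs) is not
  implemented.
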