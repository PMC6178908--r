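---
title: "Model and methods behind hierbaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind hierbaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierbaps)
```

## The model

`hierbaps` clusters haploid sequences by treating the partition itself as
the unknown. A partition $S$ assigns each of $n$ sequences to one of
$K \le K_{\max}$ clusters. Within a cluster, the alleles at each locus are
independent multinomial draws from cluster-specific frequencies; those
frequencies carry a symmetric Dirichlet prior and are integrated out
analytically. Writing $n_{ijl}$ for the count of allele $l$ at locus $j$
in cluster $i$ and $N_A(j)$ for the number of distinct alleles observed at
locus $j$, the marginal likelihood factorises over clusters and loci:

$$
P(\mathrm{data} \mid S) \;=\; \prod_{i=1}^{K}\prod_{j=1}^{L}
\frac{\Gamma\!\left(\sum_l \alpha_j\right)}
     {\Gamma\!\left(\sum_l \alpha_j + \sum_l n_{ijl}\right)}
\prod_{l=1}^{N_A(j)}
\frac{\Gamma(\alpha_j + n_{ijl})}{\Gamma(\alpha_j)},
\qquad \alpha_j = \frac{1}{N_A(j)} .
$$

With $\alpha_j = 1/N_A(j)$ the prior pseudo-counts at every locus sum to
one regardless of how many alleles segregate there, so no locus dominates
through its allele richness alone. The factor rewards homogeneous clusters:
at a binary locus with $\alpha = 1/2$, counts $(2,0)$ score $\log 0.375$
while $(1,1)$ scores $\log 0.125$. All arithmetic is done in natural-log
space through `lgamma`; raw gamma values would overflow at the first
realistic count. Missing cells contribute to no count: the likelihood is
over observed alleles only.

## The prior over partitions

The prior on the number of clusters $K$ is discretised uniform on
$1..K_{\max}$, and we take it flat over the partitions within each $K$
without any further combinatorial weighting. Under this reading the prior
contributes the same constant $-\log K_{\max}$ to every admissible
partition, so the maximum a posteriori partition is exactly the
marginal-likelihood maximiser and the cached likelihood can serve directly
as the search objective. We prefer this to re-weighting each $K$ by the
number of set partitions of that size (Stirling numbers): such a weighting
would penalise intermediate $K$ by hundreds of log units at realistic $n$,
make the acceptance of a move depend on quantities unrelated to the data,
and break the property — useful both for reasoning and for testing — that
the likelihood is non-decreasing along the greedy search path. At fixed
$K$ the two readings agree identically.

## From alignment to SNP matrix

Only `a`, `c`, `g`, `t` (case-insensitive) count as alleles; gaps, `n` and
IUPAC ambiguity codes are treated as missing. This keeps $N_A(j) \le 4$
and matches the dominant convention for SNP alignments; treating partial
ambiguity codes as fractional observations would complicate the count
model for little gain on typical data.

Columns with fewer than two distinct observed alleles carry no grouping
information and are dropped. By default the encoder additionally applies a
singleton filter: a locus is retained only when at least two of its
alleles are each carried by at least two sequences, and an allele observed
exactly once at a retained locus is recoded as missing rather than the
whole locus being discarded — the singleton observation is the noise, the
major-allele signal at that site is not. $N_A(j)$, and hence $\alpha_j$,
is computed after this recoding. Singleton sites matter for phylogenies
but under this model they mostly let single sequences buy themselves
private clusters. The filter can be disabled (`keep_singletons = TRUE`).

## The greedy stochastic search

The search starts from a complete-linkage cut of the pairwise Hamming
distances (counted over loci where both sequences are observed; pairs
sharing no observed locus get the maximal distance). Complete linkage is
conservative about chaining, which suits an initial over-partitioning at
$K_{\max}$ that the merge moves then collapse.

Three move families are cycled until a full cycle brings no improvement:

* **Individual reassignment** — each sequence, visited in a freshly
  shuffled order, moves to the cluster (or to a new cluster while
  $K < K_{\max}$) with the best positive delta; moves apply immediately.
* **Pairwise merge** — all $K(K-1)/2$ merge deltas are evaluated exactly
  via the likelihood's additivity over clusters; the best strictly
  improving merge applies, repeatedly.
* **Subgroup relocation** — inside each cluster of at least four members,
  the member sets under the internal nodes of a complete-linkage subtree
  are candidate subgroups; each is scored for relocation to every other
  cluster or to a new one. This is the split move: without it the search
  could never escape an initialisation that fused two subpopulations.

Acceptance is strictly greedy; randomness only shapes visit orders and the
restart perturbations (each later restart reassigns a quarter of the
sequences to random clusters before searching). Deltas for single-sequence
moves use $\log\Gamma(x+1)-\log\Gamma(x)=\log x$, so a move costs one
vectorised pass over the sequence's observed loci; group and merge deltas
re-evaluate only the affected clusters. A move counts as an improvement
only when its delta exceeds $10^{-10}$, which prevents floating-point
cycling; the cached objective is bounded above and strictly increases by
more than that tolerance at every applied move, so every sweep terminates.
Ties between equal deltas go to the lowest cluster index (and, for merges,
the lexicographically smallest pair) so results are reproducible across
platforms. Emptied clusters are removed at once and labels compacted, and
the final labelling is renumbered in order of first appearance.

Restarts are independent and each seeds the generator from
`seed + restart`, so they may run in parallel; results are reduced in
restart order and the outcome is byte-identical to the serial run.

## The hierarchy

Level 1 is the search on the full matrix with $K_{\max}$ = `n_pops`. Each
level-$d$ cluster with at least four members is then re-searched on its
own subset with `k_max = min(n_pops, cluster size)`. Two details matter:

* **Locus re-filtering.** Within a cluster many loci become invariant, and
  some alleles become subset-singletons. The subset matrix is rebuilt with
  the same filter rules, and $N_A(j)$ — hence $\alpha_j$ — is recomputed on
  the subset. Loci invariant within the cluster would otherwise contribute
  split penalties that have nothing to do with the structure being sought
  at this level; removing them is what lets the deeper level see weaker
  signal than the level above could justify globally.
* **Stop rule.** A cluster is left unsplit exactly when the searched
  optimum on its subset is the single-cluster partition (or when fewer
  than four members or no polymorphic loci remain — below four members the
  merge and subgroup moves degenerate). No ad-hoc significance threshold
  is involved; the integrated likelihood's own Occam penalty decides.

Subset searches draw their seeds from a fixed hash of (master seed, level,
parent cluster), so the hierarchy is reproducible regardless of traversal
order or worker count. Global labels at each level are assigned by
ascending parent label then sub-cluster index, which makes every level a
nested refinement of the previous one and keeps cluster numbers stable
across runs.

## The synthetic-data generator

`simulate_alignment()` generates data from the model's own generative
direction: per-cluster allele frequencies drawn from a symmetric Dirichlet
(`concentration`, default 0.05 per allele — strongly skewed draws, the
near-fixed differences typical of clonal SNP data), sequences drawn
i.i.d. per locus, and missingness applied completely at random
(`missing_rate`, default 0), matching the likelihood's indifference to
missing cells. A fraction `divergence` (default 0.5) of loci are
*divergent*: each group they separate receives its own frequency draw,
rotated so that each group's dominant allele is distinct — a locus that is
supposed to differ between clusters genuinely does, rather than
coinciding by chance a quarter of the time.

Nested specifications plant two scales. Most divergent loci separate the
macro clusters; a fraction `sub_fraction` (default 0.06) separate the
sub-clusters within each macro cluster. The default was set from the
model's own arithmetic rather than by trial: splitting a macro cluster at
the top level pays an Occam penalty of roughly 1.9 log units at every
locus that is invariant within it (those loci vanish from the subset
search after re-filtering, which is exactly the asymmetry the hierarchy
exploits), while each sub-divergent locus contributes on the order of 20
log units of split gain. With 100 divergent loci, six of them
sub-divergent, the sub-split gain sits comfortably above the subset noise
floor and comfortably below the top-level penalty, so the planted macro
structure is the top-level optimum and the planted sub-structure is the
subset optimum — genuine two-scale data, not a search artefact. Margin
checks across twenty seeds gave top-level split margins of −216 to −127
and within-cluster split margins of +18 to +92 log units.

The generator emulates unlinked loci in panmictic subpopulations. It does
not emulate recombination, linkage between loci, genealogical correlation
within clusters, or informative missingness — so recovery of planted
structure here shows the estimator and search work as designed, not that
real data satisfy the model. On real alignments, linkage makes loci
pseudo-replicated and the method (like the model family it belongs to)
will be overconfident about fine structure.

## Sizes and tolerances used in the tests

The suite validates the likelihood against an independent
sequential-predictive evaluation (1,000 random count vectors, tolerance
$10^{-9}$), the search against exhaustive enumeration of all set
partitions on 50 instances with $n \le 8$, $M \le 20$, $K_{\max} \le 3$
(the greedy score must never exceed the enumerated optimum and must attain
it in at least 90% of instances), the incremental deltas against
from-scratch recomputation over 10,000 applied moves (drift $\le 10^{-9}$),
and two-scale recovery on the generator's default nested scenario
(2 macro × 2 sub-clusters of 20 sequences, 200 loci). These sizes keep the
whole suite in the tens of seconds while leaving each property with real
room to fail.

## Known limitations

* The hierarchy reveals finer structure only where the top level chose not
  to split; when sub-structure is strong enough to pay the global split
  penalty, level 1 already resolves it and deeper levels inherit it
  unchanged. The levels are a resolution schedule, not a dendrogram.
* On very small or weakly informative subsets the integrated likelihood
  can genuinely prefer several small clusters (the exhaustive-enumeration
  tests confirm such optima); interpret deep levels of small clusters with
  care.
* One sequence belongs to exactly one cluster: no admixture estimation,
  no linked-loci model, no spatial prior.
* `n_pops` caps the number of clusters; structure beyond the cap folds
  into the available clusters. Set it above the number of clusters you
  consider plausible.
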