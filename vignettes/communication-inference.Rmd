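---
title: "Modeling intercellular communication with commscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intercellular communication with commscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commscape)
```

# The model and its assumptions

`commscape` treats intercellular communication as mass-action binding
between a ligand expressed by a sender cell group and a receptor expressed
by a receiver group. Three modeling commitments follow from the biology:

* **Complexes are all-or-nothing.** Many ligands and most receptors are
  heteromeric. The level of a complex is the geometric mean of its subunit
  levels, so a single silent subunit inactivates the whole complex. This is
  the main structural difference from single-gene-pair tools, and it is
  what the partial-complex false-positive metric quantifies: a method that
  scores `Tgfb1 -> Tgfbr1` without `Tgfbr2` has not found TGFb signaling.
* **Cofactors modulate, they do not gate.** Soluble agonists multiply the
  score by `1 + AG/(Kh+AG)` in both sender and receiver (saturating at 2),
  antagonists by `Kh/(Kh+AN)` (decaying to 0); co-stimulatory and
  co-inhibitory membrane receptors rescale the receptor linearly by
  `(1+RA)/(1+RI)`. Cofactor sets are gene sets averaged arithmetically —
  they tune an interaction that must already have ligand and receptor.
* **Abundant populations shout louder.** For unsorted tissue data each
  score is multiplied by `n_i n_j / n^2`, the product of group population
  fractions. For sorted or enriched designs this artifact is removable
  (`population_size = FALSE`); the toggle rescales every tensor entry by
  exactly that factor and nothing else.

Group expression uses Tukey's trimean (`0.5 Q2 + 0.25 (Q1 + Q3)`, type-7
quantiles). Its key property is a hard zero whenever fewer than a quarter
of a group's cells express the gene, which makes the score conservative
under scRNA-seq dropout: a communication is only called when expression is
broad within the group, not when a few cells spike. The cost is
sensitivity — relative to a 10% truncated mean the trimean drops weakly or
narrowly expressed ligand-receptor pairs, a trade we accept for precision.

Significance is a permutation test on cell group labels: labels are
reshuffled `M = 100` times, trimeans and scores recomputed end to end, and
the p-value of an entry is the fraction of permutations whose score reaches
the observed one. One permutation is drawn per round and shared by all
interactions, preserving their correlation under the null. The observed
statistic is not added to the permutation set, so p has resolution `1/M`
and can be exactly 0. We use the upper tail (permuted >= observed): strong
observed scores get small p-values, matching the use of `p < 0.05` to
select communications. (The mirrored lower tail is available via
`tail = "lower"` for completeness.)

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kh` | 0.5 | Hill half-saturation, on the scale of the expression data; 0.5 assumes input normalized to roughly [0, 1] |
| `hill_n` | 1 | Hill exponent applied to the product L·R; values > 1 sharpen the on/off transition |
| `permutations` | 100 | permutation count M; p-value resolution is 1/M |
| `alpha` | 0.05 | significance level of the permutation test |
| `de_alpha` | 0.05 | raw (uncorrected) one-sided Wilcoxon level of the over-expression pre-filter |
| `strictness` | "any" | a pair enters scoring if any subunit is over-expressed somewhere ("all" requires a complete complex side) |
| `min_cells` | 10 | groups below this size are excluded; trimeans and permutations are unstable for tiny groups |
| `population_size` | TRUE | include the n_i n_j / n^2 factor |

The DE pre-filter is deliberately permissive (raw p < 0.05, no multiple
testing correction): it prunes pairs with no expression signal anywhere so
the permutation test — the actual significance gate — is not spent on them.
The expression scale matters more than any other input property: `kh = 0.5`
is meaningful for data in [0, 1], so `infer_communication()` warns when the
matrix maximum exceeds `max_expression` (default 10) and rescaling is
advisable. Calls are empirically stable under `kh` in [0.25, 0.75] and
`hill_n` in {1, 2}; the acceptance script reports the Jaccard overlap of
significant sets across those settings.

# What the synthetic generator emulates

`synthetic_spec()` defines the study conditions used throughout the tests:
4 groups x 50 cells, 50 interactions over 5 pathways, 30% heteromeric
receptors, 20% cofactor-bearing pairs, 10 planted directed communications
at 10x baseline effect, 20% dropout. Baseline genes follow a log-normal
(median 0.03, log-sd 0.5) but are *detected in only 15% of cells*
(`baseline_detection`), mirroring the sparsity of real scRNA-seq where
lowly expressed genes drop out in most cells; a baseline gene's group
trimean is therefore exactly 0, which is the regime the trimean is chosen
for. Planted ligands (in the source group) and receptors plus
co-stimulatory genes (in the target group) are expressed throughout their
group before dropout. Dropout is independent Bernoulli zeroing at a
constant rate — the simplest adversarial case for the trimean; an
expression-dependent variant (`dropout_shape > 0`) zeroes low values
preferentially.

Two regimes of the generator serve different validation questions:

* **Type-I calibration** needs a continuous exchangeable null — a
  permutation test's p-values are only uniform when the statistic has no
  atoms. Calibration therefore runs on `baseline_detection = 1`,
  `dropout = 0`, `n_planted = 0`: dense i.i.d. expression, where the
  significant fraction at `alpha = 0.05` should sit near 5% (it does;
  `p < 0.05` has exact probability 5/101 per entry under exchangeability).
* **Recovery** runs on the sparse default regime with planted structure,
  where ground truth is known and TPR/FPR are well defined.

What the generator does **not** emulate: UMI counting noise, library-size
variation, batch effects, doublets, correlated gene modules, or
expression-magnitude-dependent dropout (by default). Passing the planted
tests therefore shows the machinery is correct and well calibrated under
its own assumptions, not that real-tissue calls are correct — on real data
the quality of the interaction database and the grouping dominate.

# Downstream analyses

**Centrality.** Pathway networks (sums of significant pair scores) are
weighted directed graphs. Out- and in-degree identify dominant senders and
receivers; Freeman flow betweenness (total reduction in pairwise max-flow
when a group is removed) identifies mediators; Stephenson-Zelen information
centrality identifies influencers. Information centrality is defined for
undirected graphs, so the adjacency is symmetrized as `(A + t(A))/2`; it is
computed per connected component via `C = (L + J)^{-1}` and
`I_i = n/(n C_ii + tr(C) - 2 R_i)`, with isolated vertices scoring 0 by
convention. "Relative importance" values are per-measure min-max scalings
to [0, 1]. Both bespoke centralities are verified against independent
oracles (brute-force max-flow enumeration; the harmonic-mean form of the
information-centrality definition).

**Patterns.** The outgoing (incoming) role matrix sums the significant
tensor over targets (sources), giving groups x pathways. Frobenius NMF by
multiplicative updates factorizes it into R communication patterns,
best-of-10 random initializations. The pattern count is chosen by running
repeated factorizations per candidate R, building a consensus co-assignment
matrix from the dominant-pattern labels, and watching the cophenetic
correlation and mean silhouette of its hierarchical clustering. We select
the largest R before *either* metric first drops more than 0.025 below its
running maximum. A conjunctive rule (both metrics dropping) was considered
and rejected: the cophenetic correlation of a near-binary consensus stays
above 0.99 even past the stable rank because the hierarchical fit remains
good, so the silhouette carries the signal and a both-metrics rule never
fires. With no detected drop the count defaults to 5, clipped to the
candidate range. Display thresholds follow two conventions: 0.5 on min-max
normalized loadings for alluvial-style "one pattern per group" views, `1/R`
for dot-plot views; normalization precedes thresholding, and contribution
scores `W H` are computed from unthresholded loadings by default.

**Similarity and manifolds.** Functional similarity is the Jaccard index
of directed edge sets (the printed symmetric-difference denominator form,
which is undefined for identical networks, sits behind a flag with a
zero-denominator guard); it requires identical group composition. Structural
dissimilarity combines Jensen-Shannon divergences of node-distance
distributions, network node dispersion, and alpha-centrality distributions
of graph and complement with weights 0.45/0.45/0.1. Numerical conventions:
graphs are binarized (edge iff weight > 0) and symmetrized; distances use
the undirected graph with disconnected pairs binned at diameter + 1 so each
node's distance profile remains a distribution; the alpha-centrality
damping is 0.9 of the inverse spectral radius (guaranteeing the Neumann
series converges) with an exogenous vector of ones; empty-vs-empty graphs
have dissimilarity 0. The implementation matches a brute-force oracle
(Floyd-Warshall distances, truncated power series) on all non-isomorphic
graphs up to 5 nodes.

Before embedding, the similarity matrix is smoothed by its shared-nearest-
neighbor graph (`k = round(sqrt(N))` neighbors, shared-fraction weights,
`Gs S`, symmetrized), which suppresses weak similarities. Because smoothing
rescales each row by its neighborhood mass, the smoothed matrix is
normalized like a correlation (`s_ij / sqrt(s_ii s_jj)`) before converting
to distance `1 - s`; identical networks are then at distance 0. Pathways at
distance 0 are a single point of the metric space, so they are embedded
once and share UMAP coordinates — stochastic layout repulsion would
otherwise separate exact duplicates arbitrarily, which matters for
cross-condition comparisons where an unchanged pathway should land on
itself. UMAP uses `n_neighbors = k`, `min_dist = 0.3`, fixed seed. Pathway
groups come from consensus k-means over candidate counts 2-10: co-assignment
probabilities below 0.3 are pruned, and the count is read off the largest
Laplacian eigenvalue gap (the second-largest is available by flag, default
first).

**Cell clustering.** Label-free grouping builds a shared-nearest-neighbor
graph (k = 20) in the user's embedding and applies Louvain; without a
resolution the group number comes from the eigen-gap of a consensus matrix
over a resolution sweep. Cells are processed in lexicographic name order
internally so the partition is invariant to input row order.

# Numerical choices and degenerate inputs

* Trimeans use type-7 quantile interpolation throughout.
* Constant genes short-circuit to Wilcoxon p = 1 and are never flagged.
* Database subunits absent from the expression matrix count as zero
  (inactivating their complex, with a warning); absent cofactor genes are
  dropped from their set mean.
* Zero rows/columns of a role matrix are removed before NMF and restored
  as zero loadings; min-max normalization maps all-equal positive rows to 1.
* Two empty networks have functional similarity 1 and structural
  dissimilarity 0 by convention.
* PPI smoothing (off by default, restart 0.5) preserves each cell's total
  mass over PPI genes and leaves non-PPI genes untouched; `restart = 1` is
  the identity.

# Problem sizes used in validation

The test-suite simulations use the generator defaults (200 cells, 50
interactions, M = 100 permutations, 5-10 seeds per property), equation
oracles run exhaustively over all non-isomorphic graphs with up to 5 nodes,
and the full suite plus the acceptance script each complete in about a
minute on one CPU. These sizes were chosen so that every stochastic check
pools enough replicates for its stated tolerance (e.g. 4,000 null p-values
for the 99% binomial band around 0.05) while the whole validation remains
cheap to re-run.

# Known limitations

* mRNA stands in for protein: ligand-receptor binding is a protein-level
  event, and no dissociation constants are gene-specific — `kh` and
  `hill_n` are global phenomenological parameters.
* The permutation test calibrates specificity of *group-label* structure;
  it cannot rescue a wrong grouping or an incomplete database.
* Trimean conservatism costs sensitivity for narrowly expressed ligands
  (for example, signals from small subpopulations inside a group).
* Functional similarity requires identical group sets across datasets;
  structural similarity ignores identity entirely — neither measures
  partial overlap of cell compositions.
* Spatial constraints, orthology mapping across species, and
  trajectory-continuous (rather than discrete-group) communication are out
  of scope.
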