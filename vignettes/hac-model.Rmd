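---
title: "Hierarchical block-model agglomeration: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical block-model agglomeration: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hacnet)
```

## The model

`hacnet` clusters a simple undirected graph $G = (V, E)$ — typically a
protein–protein or genetic interaction network — under a Bernoulli
stochastic block model.  For any pair of vertex groups $i, j$ let $e_{ij}$
be the number of observed edges among the $t_{ij}$ vertex pairs spanning
them ($t_{ij} = n_i n_j$ between groups, $n_i(n_i-1)/2$ within), and
$h_{ij} = t_{ij} - e_{ij}$ the number of *holes* (absent edges).  Each
block is a run of $t_{ij}$ independent Bernoulli trials with its own
parameter $\theta_{ij}$, so a block contributes

$$L_{ij} = \left(\frac{e_{ij}}{t_{ij}}\right)^{e_{ij}}
           \left(\frac{h_{ij}}{t_{ij}}\right)^{h_{ij}}
\qquad\text{(profile likelihood, } 0^0 = 1\text{)},$$

$$P_{ij} = \int_0^1 \theta^{e_{ij}} (1-\theta)^{h_{ij}}\,d\theta
         = B(e_{ij}+1,\, h_{ij}+1)
\qquad\text{(uniform prior integrated out)}.$$

A *flat* model with $K$ groups multiplies the $K(K+1)/2$ block terms
(`flat_model_scores()`).  The *hierarchical* model replaces the within-group
terms by a merge forest: every branching node contributes one term on the
edges/holes crossing between its left and right subtrees, every collapsed
terminal contributes a within-group term, and the top-level roots interact
through a full block model over root pairs (`tree_model_scores()`).  Every
vertex pair is governed by exactly one term — the package tests verify that
the $t$'s of all terms add up to $\binom{|V|}{2}$.  For several edge types
the model is a product over layers, so all log scores are additive.

## Greedy agglomeration

`run_hac()` starts from singletons and repeatedly merges the candidate
pair with the best score.  The default HAC-ML score is the likelihood
ratio of the model after versus before merging top-level clusters $1, 2$:

$$\lambda^{\mathrm{ML}} = \prod_{k \neq 1,2}
  \frac{L(e_{1k}+e_{2k},\, t_{1k}+t_{2k})}{L(e_{1k}, t_{1k})\,L(e_{2k}, t_{2k})}.$$

The $(1,2)$ crossing term is absent because it moves unchanged from the
top-level block into the new internal node: the ratio depends only on how
compatible the two clusters' connectivity *profiles to third parties* are.
For two singletons it reduces to $(1/4)^m$ with $m$ the number of outside
vertices adjacent to exactly one of them — shared-neighbour information,
which is what lets the score work on disassortative networks whose groups
have no internal edges at all.  $\log\lambda^{\mathrm{ML}} \le 0$ always,
and the accepted scores telescope to the final tree log-likelihood.

Candidates are restricted to cluster pairs joined by an edge or sharing a
neighbouring cluster; disconnected components therefore never merge and
the result is a forest.  Scores live in a max-heap with version stamps.
One subtlety discovered while validating against a brute-force oracle: a
third-party merge can *raise* an existing pair's score, so the classic
"recompute lazily when popped" queue is incorrect (an entry sitting too
low is never reconsidered).  The engine instead updates the affected
pairs eagerly — a merge changes only their third-cluster terms for $i$,
$j$ and the new cluster, an $O(1)$ delta each — pushes freshly stamped
entries, and discards stale copies when popped.  Merges can also *create*
candidates: two neighbours of the merged cluster now share it.  Ties are
broken by the lexicographically smallest pair of smallest member ids, so
runs are deterministic and stable under order-preserving relabelling.

The alternative merge scores are selected with `method`: `"bayes"`
(the integrated form of the same ratio), `"e"` (edge density
$\rho_e = e_{12}/t_{12}$), `"es"` ($\rho_e + \rho_s$ with $\rho_s$ the
fraction of outside vertices adjacent to both clusters) and `"q"` (the
decomposed Newman modularity increment
$\Delta Q = e_{12}/E - D_1 D_2 / 2E^2$, whose accepted values sum to the
global modularity).

## Bayesian model selection

Two Beta-ratio statistics are recorded at every accepted merge:

* $\lambda^B$, the fully Bayesian analogue of $\lambda^{\mathrm{ML}}$
  (same product over third clusters with $B(e+1, h+1)$ in place of the
  profile likelihood, no merge-multiplicity factor);
* the *internal coherence* ratio — the collapse statistic
  $$\lambda^C = \frac{B(e_w+1,\, h_w+1)}
    {B(e_{11}+1, h_{11}+1)\,B(e_{22}+1, h_{22}+1)\,B(e_{12}+1, h_{12}+1)},
    \qquad e_w = e_{11}+e_{22}+e_{12},$$
  which compares "one homogeneous group" against "two groups plus a
  between-block".  When both children are already collapsed this is the
  collapse criterion proper: the merged cluster becomes a single terminal
  iff $\lambda^C \ge 1$.  Two singletons always collapse
  ($\lambda^C = 1$ exactly, whatever their adjacency).  A node that fails
  collapse can never become collapsible again.  The statistic itself is
  computable from the maintained counts for *every* join, and the package
  records it for every join because the top-level cut needs it (below).

### Why the top-level cut is a tree cut, not a stopping step

The natural reading "stop when the best merge has $\lambda^B < 1$" turns
out to be structurally unable to find block structure, for two reasons
the test suite pins down exactly:

1. **$K=2$ degeneracy.**  For the final merge of any two-root state the
   entire product is empty — $\lambda^B = 1$ exactly — so no trajectory
   rule can ever cut a connected graph into exactly two clusters.  On two
   5-cliques joined by one edge the recorded $\lambda^B$ sequence ends
   $(1.349,\, 630/650,\, 1)$: the literal first-drop rule cuts at *three*
   clusters (the second bridge vertex has just been pulled in).
2. **The partition need not be a trajectory state.**  On a 4-block
   planted graph the greedy order can merge two *completed* blocks before
   finishing the other two; the true partition exists as four subtree
   nodes but never as the active cluster set, and $\lambda^B$ of the
   cross-block merge is even $> 1$ — both blocks show the same profile to
   the remaining clusters, and the one term that distinguishes them (the
   sparse $(1,2)$ block against the dense interiors) is exactly the term
   that cancels.

The default extraction (`stop_criterion = "subtree"`) therefore performs
Bayesian model selection on the *tree*: each join is scored by its full
evidence for "these two children are one group",

$$\log\Lambda \;=\; \log\lambda^B \;+\; \log\lambda^C
  \;+\; \log\!\left(2^{\,n-1}-1\right),$$

combining the third-party profile terms, the internal-coherence ratio and
the prior odds for the $2^{n-1}-1$ bipartitions the split hypothesis must
choose among (the standard multiplicity term of Bayesian hierarchical
clustering; without it, small noisy fragments of one true group are
over-split, because a handful of mildly mismatched profile terms outweighs
a weak coherence signal).  The top level is the set of maximal subtrees
containing no disfavoured join ($\log\Lambda < 0$), made consistent by a
final fixpoint pass: if two reported clusters would themselves join with
positive evidence (which happens precisely when the greedy order tore one
group across subtrees), they are merged, highest evidence first, until no
such pair remains.  True block boundaries are unaffected — their
coherence deficit grows with the squared cluster size while the
multiplicity term grows only linearly.

The literal trajectory rules remain available (`"first-drop"`, `"cummax"`
— the earliest maximum of cumulative $\log\lambda^B$, i.e. the visited
state of maximal model probability — and `"none"`), and
`top_level_clusters()` re-derives any cut from a finished run.  The
reported bottom level is the set of collapsed terminals, restricted to
terminals inside the top-level cut so that the bottom level always
refines the top level.  Collapse decisions themselves use $\lambda^C$
alone, without the multiplicity factor.

On the planted benchmarks this extraction recovers 4 blocks of 8
(p_in = 0.8, p_out = 0.05) with ARI $\ge 0.9$ in 19/20 seeds and a
disassortative 2x12 structure (p_in = 0.05, p_out = 0.8) in 20/20; the
residual failures are genuine guide-tree chimeras (a vertex greedily
attached to the wrong block), which no post-hoc cut can repair.

## Link prediction

`cross_validate()` implements the hold-out protocol: delete a fraction of
the target layer's observed edges (at least one; vertices are kept, and
the degree filter is applied once before splitting, never re-applied), fit
the clustering on the training data — jointly over all layers for
multi-layer input — and rank the held-out edges against an equal number of
holes sampled uniformly from the *original* network, so a held-out edge
can never serve as a negative.  A pair's score is the training density of
its governing term: the collapsed terminal containing both vertices, else
the lowest common ancestor's crossing density, else the top-level block
density of the two roots.  Evaluation reports precision TP/(TP+FP) and
recall TP/(TP+FN) at every cutoff, the F-score (maximum harmonic mean over
cutoffs) and the midrank AUC, with deterministic canonical tie-breaking in
the ranking.

On networks of a few dozen vertices the raw maximum-likelihood densities
are mostly 0- or 1-valued (a held-out edge often leaves its LCA with no
surviving crossing edge), which ranks true edges below sparse cross-block
holes; `smooth = TRUE` switches to the Laplace form $(e+1)/(t+2)$, which
orders empty blocks by their size instead of collapsing them all to zero.
Raw densities remain the default; the smoothed mode is recommended (and
used by the package's own acceptance checks) whenever $t$ per block is
small.  F and AUC are invariant under monotone transformations of the
scores, so smoothing matters exactly when it changes the order of raw
ties and near-ties.

## Synthetic generators

`sample_planted()` draws the classic planted partition (independent
Bernoulli edges, probability p_in within and p_out between blocks);
`sample_hrg()` draws from an explicit dendrogram whose nodes carry
crossing/within probabilities (the generative reading of the hierarchical
model); `sample_multilayer()` draws independent layers conditioned on one
shared block assignment.  All take a seed and return ground-truth labels
for ARI scoring.  The benchmark defaults used throughout the tests — 4
blocks of 8 at 0.8/0.05, 2 blocks of 12 at 0.05/0.8, 10% edge hold-out,
20 replicates — are the regime where the fixtures are small enough for
brute-force oracles yet structured enough that chance recovery is
essentially impossible.  What these generators deliberately do *not*
emulate: degree heterogeneity (no degree correction in the model either),
long-tailed block-size distributions, and the ascertainment biases of
real interactome screens.  A green recovery test therefore establishes
correctness of the inference machinery on its own model class, not
performance on BioGRID-scale data.

## Numerical and engineering notes

* Everything is computed in log space via `lbeta()`/`lgamma`-backed
  kernels; no factorials or raw products, so counts up to ~10^7 pairs are
  safe.  `log_ml_bernoulli()` honours the $0^0 = 1$ convention and
  returns 0 for empty blocks ($t = 0$).
* Exact-zero comparisons (collapse at $\lambda^C \ge 1$, evidence signs,
  first-drop) use a $10^{-9}$ guard band; the identities that should be
  exact (singleton collapse, layer additivity, telescoping) hold to
  machine precision and are asserted as such.
* Counts are maintained incrementally (sparse between-cluster map keyed
  by cluster pair) but `tree_model_scores(..., check_counts = TRUE)`
  re-tallies everything from the network and fails loudly on any
  mismatch; the tests run this audit routinely.
* Degenerate inputs: an empty network is an error; a single vertex is a
  trivial one-cluster result; graphs left empty by the degree filter are
  the caller's responsibility.
* This is a pure-R reference implementation: comfortable up to a few
  hundred vertices (the whole test suite, with its hundreds of engine
  runs, takes about two minutes), not tuned for the 5,000-vertex,
  100,000-edge regime, which needs the same algorithm in a compiled
  language.

## Known limitations

Greedy agglomeration commits to one tree and can lodge individual
vertices in the wrong group early; there is no refinement or sampling
stage.  The model is not degree-corrected, treats edges as error-free
observations, and the multiplicity-corrected evidence used for the
top-level cut — although standard in Bayesian clustering — is a package
design choice layered on the collapse machinery, with the trajectory
rules retained for comparison.
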