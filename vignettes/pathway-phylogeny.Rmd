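---
title: "Phylogenies from multi-pathway alignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenies from multi-pathway alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathphylo)
```

## The problem

Organisms can be classified by comparing their metabolism rather than their
gene sequences: two organisms whose common metabolic pathways are wired
similarly are, in this metabolic sense, close. `pathphylo` reconstructs a
distance-based phylogeny for a set of $k$ organisms from $p$ metabolic
pathways shared by all of them. Each pathway is a directed reaction graph
$G = (V, E)$: nodes are enzymatic reactions, and an edge $u \to v$ exists
whenever an output compound of $u$ is an input compound of $v$ (both
directions when both reactions are reversible).

The method proceeds in three phases: (I) align the $k$ copies of each common
pathway into a single edge-less *union graph* of one-to-one reaction
mappings; (II) cluster the union graph's composite nodes to obtain mapped
*functional modules*; (III) score each organism pair from the largest common
connected sub-graph (LCCS) of their largest mapped modules, average over
pathways, and build a tree from the complement distances.

## Phase I — reaction similarity and the union graph

Two reactions $u$ and $v$ are compared by

$$S(u,v) \;=\; \alpha\,\mathrm{Esim}(u_e,v_e) \;+\;
  \beta\,\mathrm{Csim}(u_{ic},v_{ic}) \;+\;
  \gamma\,\mathrm{Csim}(u_{oc},v_{oc}),
  \qquad \alpha+\beta+\gamma=1,$$

with defaults $\alpha=0.4$, $\beta=\gamma=0.3$. $\mathrm{Esim}$ scores the
enzymes' EC numbers by shared leading fields: 1, 0.75, 0.5, 0.25, 0 for 4,
3, 2, 1, 0 matching fields. Comparison stops at the first mismatching or
wildcard (`-`) field; partial EC numbers score by the fields they have (so
`1.2` vs `1.2` scores 0.5), and reactions annotated with several EC numbers
take the best pair. $\mathrm{Csim}$ is the mean compound similarity over the
full Cartesian product of the two compound sets; compound similarities come
from a user-supplied symmetric lookup table with an identity fallback
(same compound scores 1, unknown pairs 0).

For each common pathway, the largest copy $G_{max}$ (ties broken by
lexicographic organism ID) anchors the alignment. For every other copy,
one-to-one reaction mappings are extracted by maximum-weight bipartite
matching on the $S$ matrix. Following the operational description of the
matching as a sequential heaviest-edge selection, the default matcher is
*greedy*: it repeatedly takes the globally heaviest remaining admissible
edge, with deterministic (row ID, column ID) tie-breaking so the result does
not depend on input order. Edges of weight 0 are never taken — a zero-weight
mapping is indistinguishable from a gap — and `minWeight` can raise that
floor. An optimal-assignment mode (`matching = "exact"`, an $O(n^3)$
Hungarian solver) is available behind a flag for comparison.

Each anchor reaction yields one *composite node* holding its mapped partner
(or a gap). The homological similarity of two composite nodes
$c_1 = (u_1,v_1)$, $c_2 = (u_2,v_2)$ combines the cross terms
$S(u_1,v_2), S(u_2,v_1)$ with the within-mapping terms
$S(u_1,v_1), S(u_2,v_2)$. The raw half-sum formulation reaches 2 when all
four terms are 1, while the similarity is specified to live in $[0,1]$; we
therefore divide by 4 by default (`rescale = TRUE`), which preserves the
stated range and leaves the clustering invariant (it is a positive affine
rescaling). Gap members contribute 0 to every term. The $k-1$ pairwise union
graphs are merged on their anchors; the merged homological matrix
$H^U$ is the element-wise **sum** of the pairwise matrices (entries in
$[0, k-1]$), as affinity propagation accepts unnormalised similarities; a
`hMean` option divides by $k-1$ instead.

## Phase II — module detection by affinity propagation

Composite nodes are clustered by affinity propagation on $H^U$: standard
damped responsibility/availability message passing, preference (the
self-similarity) defaulting to the median of the off-diagonal values,
damping 0.9, at most 1000 iterations, convergence declared after 50
iterations of a stable exemplar set. A tiny seeded jitter (relative scale
$10^{-12}$) breaks symmetry-induced oscillation, as in reference
implementations, and makes results reproducible for a given seed. After
convergence each cluster's exemplar is re-centred on the member maximising
within-cluster similarity.

One degenerate case needs an explicit rule. When the off-diagonal of $H^U$
is (near-)constant — which happens systematically when the aligned pathways
are identical, since every composite-node pair then shares the same
within-mapping terms — the median preference equals the off-diagonal
similarity and the affinity-propagation objective ties across *every*
exemplar count: the jitter alone would pick an arbitrary clustering. A
deterministic post-pass therefore merges clusters whenever absorbing one
cluster into another does not decrease the net-similarity objective
(preferences of exemplars plus member-to-exemplar similarities), breaking
exact ties toward fewer clusters. Clusterings supported by actual similarity
contrasts are unaffected (any strictly negative merge is rejected), while
the degenerate uniform case collapses to a single cluster — which is what
makes the self-alignment identity below hold exactly.

For every cluster and every organism, the member reactions (gaps skipped)
induce a sub-graph of that organism's pathway: a functional module. Modules
in the same cluster are mutually mapped.

## Phase III — LCCS, pathway and organism similarity

General largest-common-subgraph computation is NP-hard, but the only
reaction correspondence the method defines is the union-graph mapping, so
the LCCS is computed *under that fixed mapping*: the conserved-edge graph
has a node for every mapped module reaction and an edge where both the
module edge and its image exist; its largest weakly connected component is
the LCCS (ties: more edges, then smallest reaction ID). Weak connectivity is
used because reversibility makes edge directions unstable across organisms;
requiring strong connectivity would discard biologically conserved regions.

For pathways $G_i, G_j$, each side's largest module ($Mmax$, independently
per pathway; a `jointMmax` flag instead selects the single cluster
maximising the smaller module) gives conserved edge counts $|E_{lccs}|$, and

$$\mathrm{SimScore}(G_i,G_j) =
  \frac{\min\{|E_{lccs_i}|, |E_{lccs_j}|\}}{\max\{|E_i|, |E_j|\}}.$$

If both pathways have no edges at all the score is 1 when at least one
reaction mapping exists and 0 otherwise (a 0/0 guard). Organism similarity
is the plain mean of the $p$ per-pathway scores; $BSim$ has unit diagonal,
and the distance matrix is $D = 1 - BSim$.

## Tree building and comparison

Trees are built from $D$ with neighbor joining (default) or UPGMA; NJ output
is cleaned by clamping negative branch lengths to zero (transferring the
deficit to the descendant branches) and rooted at the midpoint, since the
cousin-pair comparison needs a root. An all-zero distance matrix returns a
star tree with zero branch lengths directly, and two organisms return a
cherry with half the distance on each side.

Two rooted trees over the same leaves are compared through *cousin pairs*:
for leaves $x, y$ with $d_1, d_2$ generations below their last common
ancestor, the cousin degree is $(d_1 + d_2)/2 - 1$ — siblings 0, uncle/niece
0.5, first cousins 1, and so on, each generation difference adding 0.5. The
similarity of two trees is the Jaccard index of their (pair, degree) tuple
sets, restricted to degrees up to `maxDegree` (default 2). The exact
statistic used by the original COUSINS tool is not published; the Jaccard
convention adopted here is therefore a package convention, and published
similarity values from other implementations are not directly comparable.

## The synthetic generator

`generateOrganismSet()` produces organism sets with a known generating tree
so the whole pipeline can be validated without external data. A random
binary tree is drawn with one clade per lineage; each pathway starts from a
random ancestral template (a reaction chain through shared compounds with
occasional branch shortcuts and cofactor-like extras, so the derived
substrate-product graph is connected but not a pure path) and evolves down
the tree. Every within-lineage edge applies one round of mutations at the
configured rates — EC-digit redraws biased toward the deeper digits (so all
enzyme-similarity levels are exercised), compound substitutions, and
reaction indels — while the edge into each lineage applies
$\lceil \text{interScale} \times d \rceil$ rounds, $d$ being the deepest
root-to-leaf mutation-round total in that lineage. Inter-lineage organism
pairs are therefore at least `interScale` times as diverged as intra-lineage
pairs. Edges are always re-derived from compounds, so compound mutations
perturb topology organically. A `clockLike` option instead doubles the
mutation rounds with the height of the subtree below each edge (capped at
8), emulating approximately clock-like branch lengths whose divergence
signal spans several nested scales.

The defaults — 10 organisms in 2 lineages, 20 common pathways, 20-reaction
templates, rates 0.1 and `interScale` 3 — describe a moderate-divergence
study at the scale of published pathway-based phylogenies, which aligned
20–64 common pathways for 8–16 organisms and found tree quality stabilises
only above roughly 15 pathways. What the generator does *not* emulate:
realistic KEGG topology statistics (hub metabolites, pathway cross-talk),
unequal pathway sizes across organisms, missing annotations, or correlated
mutation between pathways. Passing tests therefore demonstrate the
correctness and internal consistency of the algorithms under controlled
divergence, not classification accuracy on real organisms.

## Robustness experiment

Mirroring the published error-injection analysis, `perturbPathway()` deletes
a fraction of reactions (replacing them with random ones drawn from the
pathway's own compound/EC alphabet, re-connected by the substrate rule) or a
fraction of edges (replaced by random new ones), and the test suite tracks
the mean cousin-pair similarity between trees from perturbed inputs and the
unperturbed tree over error rates 0–30% (10 seeded replicates each). This
experiment uses the `clockLike` panel (8 organisms, 10 pathways of 40
reactions, rates 0.05): published robustness checks use real organism panels
whose divergence spans nested scales from strains to domains, and only under
such nested signal does error injection erode the tree *gradually* — the
shallowest splits go first, the deepest last. In a flat two-level panel the
injected errors are immediately comparable to the entire within-lineage
signal and the similarity curve collapses to the random-tree floor at the
first non-zero rate, measuring noise rather than robustness. Node errors are
expected to hurt at least as much as edge errors at high rates, since a
deleted reaction also removes its incident edges and shifts the bipartite
matching.

## Numerical choices and degenerate inputs

* Greedy matching ties: (row ID, column ID) lexicographic, C locale.
* Zero-weight mappings are never made; `minWeight` defaults to 0.
* LCCS component ties: node count, then edge count, then smallest node ID.
* Self-loops are dropped; the reversible closure is enforced by the
  `Pathway` validity check and re-applied after perturbation.
* Missing EC annotations become the single wildcard field `-`, scoring 0
  against everything.
* Identity compound pairs with a stored score other than 1 are overridden
  to 1 with a warning.
* Affinity propagation falls back to the highest-evidence node as a single
  exemplar (with a warning, `converged = FALSE`) if no exemplar emerges.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at $k = 10$ organisms, $p = 20$
pathways of 20 reactions (generator defaults) for the lineage-recovery
study, the clock-like panel above for the robustness study, and smaller
($k \le 6$, $n \le 8$) instances for the exhaustive oracles (brute-force
LCCS enumeration, assignment enumeration, greedy traces). These sizes were
chosen so each property is measured on the smallest instance family where
it is meaningful.

## Limitations

Only one-to-one reaction mappings are aligned; one-to-many mappings (enzyme
families, alternative routes) are out of scope. The greedy matcher is the
specified default and is not an optimal assignment; the `exact` mode exists
for sensitivity analysis. The pathway similarity uses only each pathway's
largest mapped module, discarding signal in smaller modules — a property of
the method, visible as coarse score quantisation on small pathways. Distances
$1 - BSim$ are not guaranteed additive, so neighbor joining is a heuristic
here, as in all distance-based pathway phylogenetics.

## A minimal run

```{r example, eval = FALSE}
g <- generateOrganismSet(generatorConfig(k = 6, p = 8, templateSize = 12,
                                         seed = 1))
res <- runPipeline(g$organisms, seed = 1, verbose = TRUE)
round(res$bsim, 2)
ape::write.tree(res$tree)
compareTrees(res$tree, g$tree)$similarity
```
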