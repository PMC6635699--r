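---
title: "Hypergraph random walks for microbe-disease association ranking: model and methods"
author: "hyperMDA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypergraph random walks for microbe-disease association ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperMDA)
```

## The problem

Curated catalogs of experimentally supported microbe-disease associations
are sparse: a few hundred confirmed pairs over a few hundred microbes and a
few dozen diseases. Ranking the *unconfirmed* pairs by plausibility helps
prioritise which associations to test next. hyperMDA does this with a
network-propagation model in which the association table itself is the only
input: no taxonomy, ontology, or literature features are used.

The representation is a **hypergraph** rather than a pairwise graph. Every
disease is a hyperedge containing all of its associated microbes
(vertices); a microbe belongs to as many hyperedges as it has disease
associations. This keeps each disease's full microbe set together as one
object instead of decomposing it into pairwise links, so co-membership
information is preserved.

## The model

### Input and notation

The input is a binary matrix $A \in \{0,1\}^{n_d \times n_m}$ with
$A(i,j)=1$ iff disease $i$ has a recorded association with microbe $j$
(`BipartiteAssociations`). The incidence matrix of the hypergraph is
$H = A^\top$ ($n_m$ vertices $\times$ $n_d$ hyperedges); $d(v)$ is the
number of hyperedges containing vertex $v$ and $\delta(e)$ the number of
vertices in hyperedge $e$. The unweighted hyperedge-degree matrix is built
and exposed for completeness but plays no role in the weighted transition
formula below.

### Vertex weights from the GIP kernel

Microbes inside a hyperedge are not interchangeable: a walker should prefer
microbes whose overall association profile resembles the others'. The
similarity used is the Gaussian interaction profile (GIP) kernel over the
binary profile columns $IP_j = A_{\cdot j}$:

$$ GM(i,j) = \exp\!\left(-r\,\lVert IP_i - IP_j \rVert^2\right), \qquad
   r = r' \Big/ \left(\tfrac{1}{n_m}\sum_{k=1}^{n_m}\lVert IP_k \rVert^2\right), $$

with $r' = 1$ by default, i.e. the bandwidth is normalised by the average
number of known associations per microbe. The kernel is computed once per
unordered pair, so it is exactly symmetric with an exactly unit diagonal,
and is kept dense ($n_m \approx 300$ in realistic catalogs, so sparsity
buys nothing). The node weight of microbe $i$ is the row sum
$w(v_i) = \sum_j GM(i,j)$ **including** the self-similarity term. The
defining texts for this weight ("sum of the row" vs "similarity with all
*other* nodes") differ by exactly that constant $+1$ per vertex; we adopt
the operational row-sum reading and expose
`nodeWeights(K, includeSelf = FALSE)` for the other. Since the term is the
same for every vertex, it only mildly flattens the within-edge preference
and does not change which microbes are preferred.

Microbes with all-zero profiles are retained and handled by the same
formula (their squared distance to a profile with $k$ ones is $k$); no
special-casing is needed because $\exp$ is defined everywhere.

### The two-step walk and its transition matrix

One step of the walk from vertex $u$ is: (1) choose a hyperedge $e$ among
those incident to $u$, proportional to the hyperedge weight $w(e)$; all
hyperedge weights are uniform $1/|E|$, so this choice is uniform over
incident hyperedges; (2) move to a vertex $v \in e$ with probability
proportional to its node weight, $W(v,e)/\delta'(e)$, where
$W(v,e) = w(v)\,h(v,e)$ and $\delta'(e) = \sum_{v} W(v,e)$ is the weighted
hyperedge degree. Summing over hyperedges:

$$ P(u,v) = \sum_{e}
   \frac{w(e)\,h(u,e)}{\sum_{\hat e} w(\hat e)\,h(u,\hat e)}
   \cdot \frac{W(v,e)}{\delta'(e)}. $$

A note on normalisation: the plain product form
$D_v^{-1} H W_e D_{ve}^{-1} W^\top$ normalises the step-1 choice by the
total edge weight over **all** hyperedges, under which each row sums to
$1/|E|$, not 1 — it cannot be the transition matrix of the sampling
procedure it describes. Normalising over the hyperedges *incident to* $u$
(the denominator above) is what the two-step sampling semantics implies and
restores exact row-stochasticity; `buildTransition()` does this by default
and keeps the product form available via `normalization = "printed"` for
comparison (the two differ only by a per-row constant when edge weights
are uniform, as a unit test verifies). Transition construction is checked
entry-wise against an exhaustive enumeration oracle on hundreds of random
small hypergraphs.

Vertices incident to no hyperedge (possible in cross-validation folds and
synthetic data) have no defined step; their rows are filled by policy —
uniform over all vertices by default (the standard teleport fix, which
keeps the chain well defined), or a self-loop via `dangling = "self_loop"`.
Hyperedges with no members are dropped before weighting, and $|E|$ and the
uniform edge weights refer to the reduced set.

### Random walk with restart

For a query disease, its known microbes are seeds; $v_0$ is uniform on the
seed set. The walk iterates

$$ v_{t+1} = (1-\alpha)\,P^\top v_t + \alpha\,v_0 $$

until the $L_1$ change between successive iterates falls below `tol`. The
map is a contraction with factor $(1-\alpha)$ in $L_1$, so convergence is
geometric and the iterate count respects the $(1-\alpha)^t$ bound (tested).
The fixed point satisfies $(I - (1-\alpha)P^\top)v = \alpha v_0$;
`rwrSolveDirect()` solves this dense system exactly and serves as the
independent cross-check of the iteration in the test suite. Candidate
microbes (non-seeds) are ranked by their stationary probability; seeds keep
their mass in the score vector but are excluded from rankings. Tied scores
receive midranks and are flagged.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | 0.2 | restart probability per step (dimensionless); the standard default for association propagation — small enough to explore the hypergraph, large enough to stay disease-specific. `alpha = 1` is admitted as the degenerate restart-only limit. |
| `tol` | 1e-6 | $L_1$ convergence threshold between iterates. |
| `maxIter` | 1000 | safeguard; at `alpha = 0.2`, $0.8^t < 10^{-6}$ needs $t \approx 62$, so 1000 leaves an order-of-magnitude margin. Non-convergence is flagged on the result, never silent. |
| `rPrime` | 1 | GIP bandwidth normalisation constant. |
| `dangling` | `"uniform"` | zero-degree vertex row policy. |
| `emptySeedPolicy` | `"uniform"` | start distribution when a disease has no seeds (possible only in LOOCV folds); folds using it are retained and flagged. |
| `kernelRefit` | `"per_fold"` | see below. |

## Cross-validation design

`runLoocv()` leaves each known association out in turn. By default the
kernel, node weights and transition matrix are **rebuilt from the masked
matrix in every fold** (`kernelRefit = "per_fold"`): the held-out pair then
contributes to no quantity in the fold's pipeline, which a test verifies by
recomputing a fold from scratch off the masked matrix. The cheaper
`kernelRefit = "once"` variant reuses the full-data transition matrix and
is provided because much of the link-prediction literature evaluates that
way; it leaks the held-out pair through the kernel and typically inflates
the AUC, so it is not the default.

*Global* mode scores every disease and compares the held-out pair against
all pairs unknown in the original matrix, pooled across diseases — pooling
is justified because every disease's stationary vector sums to 1, so
scores live on a comparable scale. *Local* mode compares only against the
unknown microbes of the same disease. In both modes all folds are pooled
into one Mann-Whitney AUC (ties counted one half, computed through
midranks and verified against exhaustive pair enumeration); how a single
local AUC should aggregate across diseases is genuinely underdetermined in
this method family, so a `aggregation = "macro"` per-disease average is
available as the alternative reading, and pooled results should be quoted
as such. ROC curves come from a threshold sweep over distinct score
values; their trapezoidal area equals the Mann-Whitney statistic to
floating-point accuracy (tested on random score sets).

Diseases with a single association deserve note: leaving it out empties
the seed set, the walk starts uniform, and the fold is flagged rather than
dropped, so fold counts always equal association counts.

## The synthetic generator, and what passing tests mean

`simulatePlanted()` draws a planted-block bipartite matrix: diseases and
microbes are split into `nBlocks` groups and each cell is Bernoulli
(`pIn` within blocks, `pOut` outside). The shipped fixtures are
`blocks-sep` (10 × 40, 2 blocks, `pIn = 1`, `pOut = 0`, seed 7),
`blocks-noisy` (same shape, `pIn = 0.5`, `pOut = 0.02`, seed 7), and
`hmdad-like` (39 × 292 i.i.d. at density 0.04, seed 11 — the sparsity
regime of a curated catalog: a few hundred ones in ~11,000 cells). The
generator pins the RNG (Mersenne-Twister, inversion) and restores the
caller's RNG state, so fixtures regenerate byte-identically anywhere.

The generator emulates the *sparsity and block co-occurrence* of real
association catalogs. It does not emulate their heavy-tailed degree
distributions, label noise, curation bias toward well-studied diseases, or
taxonomic correlation between microbes. Passing the planted-structure
checks therefore demonstrates that the pipeline recovers strong
co-occurrence signal without leakage — not that it attains any particular
accuracy on a real catalog, which depends on curation choices
(deduplication, label canonicalisation) outside the model. Real catalogs
are read from user-supplied TSV snapshots via `readAssociationCatalog()`;
duplicate records are collapsed by exact string match after whitespace
trimming (case preserved) — an auditable rule, though one that may count
differently from any specific curated export if that export relied on
synonym merging.

## Numerical choices and degenerate inputs

- Row/column order of the adjacency is fixed by a locale-independent
  lexicographic (radix) sort of labels, so all matrices are reproducible
  across platforms.
- Kernel symmetry and unit diagonal are exact by construction, not within
  tolerance; positive semidefiniteness is a property of the Gaussian
  kernel and is spot-checked (smallest eigenvalue $\geq -10^{-10}$).
- Row sums of the transition matrix are exact to $10^{-12}$ and validated
  by the class's validity method.
- An all-zero adjacency has an undefined bandwidth (division by zero) and
  is a hard error; LOOCV never reaches it because at least one
  association always remains.
- Ties anywhere in ranking use midranks (the 0.5 convention of the
  Mann-Whitney statistic), so a constant score vector yields AUC exactly
  0.5.
- Test-suite and acceptance problem sizes — 10 × 40 fixtures with 103-200
  folds, 200-instance oracle sweeps over hypergraphs with ≤ 6 vertices —
  were chosen so every check reruns exhaustive oracles in seconds on one
  CPU while still exercising dangling vertices, empty hyperedges, ties and
  flagged folds.

## Worked example

```{r example}
x <- namedFixture("blocks-noisy")
x
scoreDisease(x, "d01")
g <- globalLoocv(x)
g
head(loocvFolds(g), 3)
```

## Limitations

- The model cannot score a disease with no known microbes (no seeds) or
  rank a microbe with no associations other than through the dangling
  fallback; both are inherent to propagation on known associations.
- Kernel and hypergraph are built entirely from the association table, so
  well-annotated diseases and microbes dominate the weights — rankings are
  biased toward the well-studied.
- Only microbe-side similarity is used; disease-side similarity (semantic
  or symptom-based) is deliberately out of scope.
- Hyperedge weights are uniform; differential disease weighting would
  require information the input table does not carry.
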