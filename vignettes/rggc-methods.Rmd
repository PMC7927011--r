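---
title: "Regularized Gaussian graphical clustering: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized Gaussian graphical clustering: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rggc)
```

## The model

Given a preprocessed expression matrix $X \in \mathbb{R}^{p \times n}$
(genes $\times$ cells, each cell standardized), the method assumes each
cell lies near a union of low-dimensional subspaces, so that every cell is
approximately a linear combination of the other cells. The
self-representation problem

$$\min_W \|X - XW\|_F^2 + \lambda \|W\|_F^2,
  \qquad \mathrm{diag}(W) = 0,\ \lambda > 0$$

decomposes into $n$ ridge regressions of each cell on all others. Rather
than solving those one by one, the unconstrained problem has the closed
form $W = (X^\top X + \lambda I)^{-1} X^\top X = I - \lambda S$ with
$S = (X^\top X + \lambda I)^{-1}$, and the zero-diagonal constraint is
enforced by dropping the diagonal: $w_{ij} = -\lambda s_{ij}$ for
$i \neq j$. One symmetric positive-definite factorization of an
$n \times n$ matrix therefore replaces $n$ separate solves.

`compute_W()` offers the raw scaling and two normalizations of $S$:
*column* ($w_{ij} = -s_{ij}/s_{jj}$) and *symmetric*
($w_{ij} = -s_{ij}/\sqrt{s_{ii} s_{jj}}$, the default). The symmetric form
is the standard map from an inverse covariance to partial correlations: it
is symmetric by construction, its entries lie in $(-1, 1)$, and
$w_{ij}$ is the association between cells $i$ and $j$ *after regressing
out all other cells* — a high-order partial correlation, in contrast to
the pairwise correlations most clustering pipelines use.

Because the penalty is an L2 norm, highly correlated cells receive nearly
equal coefficients (the grouping effect): for unit-norm columns the
per-column optimum satisfies
$|\bar w_{jk} - \bar w_{jl}| \le \tfrac{1}{\lambda}
\sqrt{2(1 - x_k^\top x_l)}$, and exact duplicates receive exactly equal
weights. Sparse (L1) self-representation lacks this property — it picks
one representative of a correlated group — which is why the L2 form suits
cluster discovery. The test suite checks the bound over all column
triples and the exact-duplicate case against a brute-force per-column
ridge solver (`ridge_oracle()`).

## Choosing lambda (or rather, not choosing it)

$\lambda$ is the model's only free quantity, and it does not need tuning:
the package defaults to $\lambda = \ln p$ (a BIC-style choice) with
$\lambda = 2$ (AIC-style) as the named alternative. Two facts make this
safe. First, after preprocessing, $\mathrm{diag}(X^\top X) = p$, so any
$\lambda$ in the $[0.01, 2\ln p]$ range perturbs the Gram matrix by well
under one percent and the *rank order* of the off-diagonal entries of $W$
is essentially frozen (the suite asserts Spearman $> 0.99$ across that
range). Second, the downstream community detection responds to relative,
not absolute, edge weights, so even $\lambda$ values approaching the Gram
scale (hundreds to 1000, where ranks do drift measurably) move the final
NMI by only a few hundredths — the acceptance suite bounds the spread at
0.08 across $\lambda \in \{0.01, \dots, 1000\}$. A strictly positive
$\lambda$ is also what guarantees the inverse exists when cells outnumber
genes; `compute_S()` refuses a singular $\lambda = 0$ system instead of
silently pseudo-inverting.

## Preprocessing

The fixed chain is `log2(x + 1)` → quantile normalization across cells →
per-cell z-score, recorded in the matrix's `provenance` attribute. Two
conventions needed pinning down:

* **Ties in quantile normalization.** Log-counts are mostly zeros, so a
  rank-interpolation dialect would depend on gene order. Every tied value
  receives the *mean of the reference distribution over its rank span*
  ($z$ zeros all map to `mean(ref[1:z])`), which is permutation-invariant.
  A consequence worth knowing: with ties, the output columns do not carry
  byte-identical sorted profiles (the span mean replaces a run of
  reference values by their average); the property holds exactly on
  tie-free data and the tests check both readings.
* **Variance convention.** The z-score uses the population standard
  deviation (divide by $p$). Either convention rescales $X^\top X$ by a
  constant that cancels in the normalized $W$; population is used so the
  chain's output is exactly what the grouping-effect algebra assumes up to
  the factor $\sqrt p$.
* **No gene filtering by default.** The method is designed to run on the
  raw matrix; an optional `min_cells` filter exists for user data only.
  Quantile normalization operates over all genes, including unexpressed
  ones — the simplest reading, and consistent with not filtering.

Zero-variance cells carry no signal; they are set to all-zero columns and
reported, rather than producing NaNs inside the Gram matrix.

## Community detection and the sign question

Louvain maximizes the modularity
$Q = \tfrac{1}{2m}\sum_{ij}\left[w_{ij} - \tfrac{k_i k_j}{2m}\right]
\delta(c_i, c_j)$; the number of clusters is emergent and the resolution
is fixed at 1, so the pipeline stays parameter-free. Louvain is
order-dependent, so `louvain_cluster()` runs `restarts = 10` independent
passes over shuffled node orders (seeded, hence reproducible) and keeps
the partition with the largest $Q$.

The partial-correlation adjacency genuinely contains negative entries,
and what to do with them was the one design question where the two
defensible answers disagree in practice. Clipping negatives to zero makes
the graph safe for standard Louvain, but on harder designs (unequal group
sizes plus dropout) the surviving noise-floor positive weights fragment
the weak groups. Retaining the signs and optimizing the standard
two-layer signed modularity

$$Q = \frac{2m^+}{2m^+ + 2m^-} Q^+ - \frac{2m^-}{2m^+ + 2m^-} Q^-$$

(each layer with its own total weight) keeps the repulsive information —
two cells with a negative partial correlation should *not* share a
cluster — and recovers those designs cleanly. Signed mode is therefore
the default; `mode = "standard"` plus clipping remains available.

Implementation-wise, nonnegative graphs go through igraph's classic
two-phase Louvain. The signed objective has no installed optimizer, so
the package ships its own: greedy single-node moves over the shuffled
order (gains tracked via running per-community degree totals in each
layer) alternating with whole-community merges on the aggregated
community graph, iterated until no move or merge improves $Q$ by more
than $10^{-12}$. Ties in the local moves go to the first-encountered best
community in the shuffled order. On nonnegative graphs the signed
objective reduces exactly to standard $Q$, which gives a direct
cross-check between the two optimizers; on small graphs (where exhaustive
enumeration over all set partitions is feasible) the suite verifies both
reach the global optimum in nearly all draws.

Degenerate inputs are explicit: an all-zero adjacency yields a single
cluster with a warning, an empty graph is an error for `modularity_q()`,
and negative weights under `mode = "standard"` are an error pointing at
the signed mode.

## The count simulator

`simulate_counts()` draws from a gamma-Poisson hierarchy with the same
skeleton as the splatter simulator: gamma baseline gene means, per-group
log-normal differential-expression factors (inverted with probability
1/2), multinomial group sizes, log-normal library sizes (each cell's
expected total count equals its library factor), gamma over-dispersion
parameterized by a biological coefficient of variation, Poisson counts,
and optional logistic dropout whose zeroing probability decreases with
expected expression (`1/(1 + exp(shape * (log(lambda + 1) - mid)))`).

The three stock designs (600 cells × 5000 genes) exercise increasing
difficulty: equal groups without dropout; unequal groups (0.35/0.4/0.15/
0.1) with dropout midpoint 2 — more than half the matrix zeroed; and five
unequal groups with dropout midpoint 1. The second design's DE
probabilities are not separately specified by its source description
("also generated … but with unequal abundances and dropout"), so it
carries the first design's 0.05/0.1/0.2/0.4. "Dropout of 2/1" is read as
the logistic midpoint — the one dropout knob splatter users commonly
vary — with slope 1.

Where the design descriptions are silent the simulator uses the
conventional splatter values, documented as emulation constants:
`mean_shape 0.6`, `mean_rate 0.3`, `de_fac_loc 0.1`, `de_fac_scale 0.4`,
`lib_loc 11`, `lib_scale 0.2`, `bcv 0.18`. The simulator emulates the
generative structure, not the byte stream: it omits splatter's outlier
genes, mean-trended BCV with its chi-square df correction, batch effects,
and trajectory paths. Passing recovery tests on these simulations shows
the pipeline handles group structure, depth variation, over-dispersion
and zero-inflation of this kind; it does not certify performance on real
data with, e.g., strong batch structure or continuous differentiation
gradients — the non-CI `scripts/benchmark_real.R` exists for the
published-data check.

## Visualization

`embed_cells()` embeds the *model's own similarity matrix*, not the
expression data: the symmetrized, clipped $W$ is min-max scaled and
converted to the dissimilarity $d_{ij} = 1 - \tilde w_{ij}$, on which an
exact $O(n^2)$ t-SNE with precomputed distances runs (per-point precision
calibrated to a perplexity of 30, capped at $(n-1)/3$; 500 iterations
with early exaggeration ×4 for the first 100 and momentum 0.5→0.8).
t-SNE preserves local neighborhoods only — inter-cluster distances in the
figure are not interpretable — and the embedding is strictly downstream
of clustering: nothing flows back. `heatmap_order()` orders cells by
cluster and within-cluster strength so a well-separated $W$ displays a
block-diagonal checkerboard.

## Problem sizes and numerical choices

The test suite runs the three full-size designs (600 × 5000) over five
seeds each for the recovery checks and one seed for the
$\lambda$-robustness grid; unit tests use 40–90 cells × 200–2000 genes so
the whole suite stays in the minutes range. Numerical floors: `diag(S)`
below $10^{-12}$ is an error (a non-PD $S$), cell variances below
$10^{-12}$ mark a degenerate cell, and restart selection treats $Q$
improvements under $10^{-12}$ as ties (first winner kept). All
stochastic stages — simulation, restart shuffles, embedding
initialization — take explicit seeds and are bit-reproducible.

## Known limitations

* Dense $n \times n$ and $p \times n$ algebra throughout: comfortable to
  a few thousand cells, not designed for $10^5$-cell atlases.
* The signed optimizer is a greedy move+merge heuristic, not a full
  two-phase aggregation; on small graphs it matches exhaustive optima,
  but no global-optimality guarantee exists (none does for Louvain
  either).
* Rank stability of $W$ — the mechanism behind $\lambda$-robustness —
  holds while $\lambda \ll p$; with $\lambda$ within an order of
  magnitude of $p$ the edge ranking drifts, and only the end-to-end
  accuracy remains flat.
* The simulator's realism boundaries are listed above; treat simulation
  results as necessary, not sufficient, evidence for real-data behavior.
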