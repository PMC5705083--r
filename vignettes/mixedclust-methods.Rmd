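---
title: "Clustering mixed-type data: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering mixed-type data: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixedclust)
```

Biomedical tables rarely live on one scale: gene expression is quantitative,
tumor grade is ordinal, molecular subtype is nominal, receptor status is
binary. `mixedclust` clusters both the samples and the variables of such
tables without forcing everything onto a common scale, and draws integrative
heatmaps from the resulting trees. This vignette explains the statistical
machinery, the tunable parameters, and the design decisions taken where more
than one reasonable construction exists.

## Data model

A dataset is an ordinary data frame (samples in rows) together with a type
specification, `mixed_spec()`: per variable a scale
(`quantitative` / `ordinal` / `nominal` / `binary`), the ordered level list
for ordinal variables, and a nonnegative weight (default 1) used by the
sample distance. Binary variables are stored as two-level factors; the
`binary` tag only routes coefficient selection in the association-measure
method. Undeclared nominal levels are taken in order of first appearance,
which keeps parsing deterministic without sorting assumptions. Missing cells
(`NA`, and the tokens `""`/`"NA"` in files) are first-class: every pairwise
computation below handles them explicitly.

## Distances between samples: Gower's coefficient

For samples $i, j$ the similarity is the weighted mean of per-variable
scores,

$$s(x_i, x_j) = \frac{\sum_k s_k(x_{ik}, x_{jk})\,\delta_k(x_{ik}, x_{jk})\,w_k}
                     {\sum_k \delta_k(x_{ik}, x_{jk})\,w_k},$$

where $\delta_k = 0$ whenever either value is missing, and

* qualitative: $s_k = 1$ if the samples agree, else 0;
* quantitative: $s_k = 1 - |x_{ik} - x_{jk}| / R_k$ with $R_k$ the observed
  range;
* ordinal (Podani's rank extension):
  $s_k = 1 - |r_k(x_{ik}) - r_k(x_{jk})| \,/\, (\max_m r_k(x_{mk}) - \min_m r_k(x_{mk}))$.

Distances are $d = 1 - s$. Three numerical choices:

* **Ties.** Ordinal ranks are midranks. The printed rank formula is silent on
  ties; midranks are the standard resolution and coincide with it when there
  are none.
* **Degenerate variables.** A zero-range quantitative variable (or an ordinal
  or qualitative variable with a single observed value) carries no
  information. It contributes $\delta_k = 0$ for *every* pair, with a
  warning, rather than a constant score of 1 — a constant score would inflate
  similarity with no evidence.
* **Incomparable pairs.** If a sample pair shares no observed variable, the
  distance is undefined and `gower_dist()` errors naming the pair rather than
  imputing.

With complete data and equal denominators, $1 - s$ is a convex combination of
per-variable metrics and hence itself a metric; with missing values the
pairwise denominators differ and the triangle inequality can fail. The
metric-property checks in the test suite therefore draw complete datasets.

## Distances between variables I: combined association measures

Each pair of variables gets the coefficient suited to its scale combination:

| pair | coefficient |
|---|---|
| quantitative–quantitative, quantitative–ordinal | absolute Spearman correlation |
| ordinal–ordinal, quantitative–binary, ordinal–binary | absolute Goodman–Kruskal $\gamma$ |
| quantitative/ordinal–nominal | category reordering + Spearman or $\gamma$ |
| nominal/binary–nominal/binary | cross-table diagonalization + $\gamma$ |

$\gamma = (n_c - n_d)/(n_c + n_d)$ counts concordant and discordant
observation pairs under the current category orders; a quantitative variable
enters through its observed value order, a binary variable as a two-level
ordinal.

**Category reordering.** There is no off-the-shelf coefficient between a
nominal factor and a rank-ordered variable. The trick is to *find* the
ordering: categories are sorted by the mean midrank of the partner variable
within each category, after which Spearman (quantitative partner) or
$\gamma$ (ordinal partner) applies. Because this reordering is optimistic
under independence, a Kruskal–Wallis pre-test gates it: only when
$p < \alpha$ (default 0.05) is the reordered coefficient used; otherwise the
coefficient is computed on the original, essentially random, order and lands
near zero. The same logic drives the nominal–nominal case, where both
category orders are chosen by diagonalizing the cross-table (concentrating
mass on the diagonal, maximizing $|\gamma|$) behind a chi-square gate.

The diagonalization search is a design choice — the goal (large diagonal
frequencies) does not pin down an algorithm. We permute the side with fewer
categories exhaustively (up to `max_exhaustive_categories = 6`; permutations
visited in lexicographic order, first maximizer kept, so results are
deterministic), order the other side by mean position of its observations,
and keep the arrangement with maximal $|\gamma|$. Beyond the cap, a
frequency-sorted start with two rounds of reciprocal reordering approximates
the search. Pre-tests use the asymptotic Kruskal–Wallis chi-square (with tie
correction) and Pearson chi-square without continuity correction, and are
deliberately not multiplicity-adjusted: they are per-pair heuristics, not
inference.

**Making the distances Euclidean.** Assembling these coefficients into a
similarity matrix $S$ does not guarantee positive semi-definiteness, and
$\sqrt{1-s}$ distances from an indefinite $S$ can violate triangle
inequalities. By Gower's theorem, if $S$ is PSD then $D = \sqrt{1-S}$ is
Euclidean. `nearest_psd()` therefore projects $S$ onto the nearest PSD
matrix in Frobenius norm (Higham's alternating projections as implemented in
`Matrix::nearPD`, unit weights, tolerance $10^{-7}$, at most 100 iterations,
diagonal re-pinned to 1), clamps entries to $[-1, 1]$, and leaves
already-PSD matrices untouched. `ama_dist()` returns $D = \sqrt{1 - S'}$.

All coefficients and pre-tests use pairwise-complete observations — the
analogue of Gower's $\delta$. A pair with fewer than three complete
observations yields similarity 0 with a warning.

## Distances between variables II: generalized distance correlation

The second construction measures dependence rather than monotone
association. Each variable induces a metric on the samples matched to its
scale: absolute differences (quantitative), absolute midrank differences
(ordinal), the discrete 0/1 metric (nominal/binary). For variables $k, l$
with distance matrices $d_k, d_l$, double-center
$A_{ij} = d_{ij} - \bar d_{i\cdot} - \bar d_{\cdot j} + \bar d$, form the
modified matrices

$$A^*_{ij} = \frac{n}{n-1}\Big(A_{ij} - \frac{d_{ij}}{n}\Big)\ (i \ne j),
\qquad
A^*_{ii} = \frac{n}{n-1}\Big(\bar d_{i\cdot} - \bar d\Big),$$

and the bias-corrected squared distance covariance

$$\tilde U_{kl} = \frac{n-3}{n}\Big(\sum_{i,j} A^*_{ij} B^*_{ij}
  - \frac{n}{n-2}\sum_i A^*_{ii} B^*_{ii}\Big),$$

which unlike its biased counterpart can be negative. The correlation is

$$\tilde R_{kl} = \tilde U_{kl} \,/\, \sqrt{\tilde U_{kk}\, \tilde U_{ll}},$$

and the dissimilarity is $d_{kl} = 1 - \tilde R_{kl}$.

The normalization deserves a note, because the displayed equation admits
more than one typographical reading (an alternative places a square root
over the covariance and fourth roots below). We use the form above — exactly
the Székely–Rizzo bias-corrected estimator of the squared distance
correlation when both variables are quantitative, which is the statistic the
construction is stated to reduce to in that case. The choice is not
cosmetic: the square-root variant is *not* centered under independence (the
null distribution of $\tilde U$ is right-skewed, and the square root turns
that into a positive bias of about +0.02 at $n = 200$), and it amplifies
floating-point cancellation for structurally-zero covariances. Under the
form above, $\tilde R_{kk} = 1$ for nonconstant variables, the statistic is
centered near 0 under independence, and for the bivariate normal it sits
below the absolute Pearson correlation.

Further conventions: the metric pair makes $\tilde R$ exactly
scale-invariant, so range-normalized metrics (the Gower summands) give
identical values — verified to $10^{-12}$ in the tests; constant variables
get $\tilde R = 0$ (distance 1) with a warning rather than a 0/0; negative
$\tilde R$ propagates, so $d_{kl}$ can marginally exceed 1 — we keep
$d = 1 - \tilde R$ as defined instead of truncating, and flag such pairs
with a message. The estimator needs $n \ge 4$ (the $n-2$, $n-3$ factors);
with missing data each pair uses its complete cases, with ordinal midranks
recomputed on the subset.

## Clustering and evaluation

Trees come from the Lance–Williams recurrences on the precomputed distances
(`stats::hclust`); "Ward" means `ward.D2`, the textbook Ward criterion for
distance-matrix input. Any of `ward`, `complete`, `average`, `single` can be
selected; trees export to Newick via `ape`. Two-group recovery is scored by
the misclassification rate $\mathrm{MCR} = (a_{12} + a_{21})/\sum a_{ij}$
and the balanced error rate
$\mathrm{BER} = \tfrac12\,(a_{12}/(a_{11}+a_{12}) + a_{21}/(a_{21}+a_{22}))$,
each minimized over the two cluster-to-class matchings since cluster labels
are arbitrary.

## What the simulation generators emulate

Two designs validate the measures, mirroring the conditions under which they
were developed.

**Correlated pairs.** `sim_correlated_pair()` draws a bivariate standard
normal with correlation $\rho$ and replaces either side by a quantile-cut
categorized version in "perfect agreement": a median cut for binary, cuts at
the $j/K$ quantiles for $K$ categories, so the categorized variable carries
the same association as its quantitative parent. Ordinal versions keep the
cut order; nominal versions get a seeded random level order so that the
original ordering carries no information. The reference grids are
$\rho \in \{0, 0.25, 0.5, 0.75, 0.95\}$ and $n \in \{40, 96, 200, 400\}$
(sizes divisible by 8 keep an 8-way categorization balanced). Under this
design the recovered similarity should increase with $\rho$ for every
data-type combination and sit near zero at $\rho = 0$.

**Two variable groups.** `sim_two_groups()` builds a $p$-variable
multivariate normal whose variables split into two equal groups. Within a
group of size $g$, correlations decay linearly with index distance from a
maximum $\rho \in \{0.25, 0.5, 0.75\}$ to 0 — the decay shape is our choice;
only "decreasing to 0" is prescribed. A fraction (0%, 20%, 40%) of
inter-group correlations is set to 0.5 (sampled symmetrically without
replacement), which can make the target indefinite; the target is then
repaired with a nearest-PSD projection before sampling. A fraction of the
variables is categorized in perfect agreement with $K \sim U\{2..8\}$ and an
ordinal/nominal coin flip, preserving the true grouping. Baselines for the
clustering comparison are the Euclidean distance on the pre-categorization
quantitative data and the simple matching distance on median-binarized data
(nominal variables collapse to most-frequent-versus-rest, ties by level
order). Reproducibility: replicate $r$ of a study uses child seed
$\texttt{seed} + r$, so studies are deterministic and partitionable.

What the generators do *not* emulate: heavy tails, outliers, non-monotone
dependence, unbalanced categories, informative missingness, and correlated
noise structure — passing these studies therefore demonstrates recovery
under clean Gaussian-copula-like conditions, not robustness to real-data
pathologies.

Problem sizes in the shipped checks were chosen to make the suite complete
in minutes on one core while keeping each property decisively testable:
equation-level oracle equivalence on 50 datasets ($n = 20$, $p = 4$);
monotone recovery with 200 replicates per $\rho$ at $n = 400$ for all ten
data-type combinations; clustering recovery with 20 replicates at
$n = 100$, $p = 100$, $\rho = 0.75$ and 25 replicates at $n = 50$,
$p = 100$, $\rho = 0.5$ with 20% noise.

## Visualization

The integrative heatmap (`plot_mixed_heatmap()`) shows variables as rows and
samples as columns, both ordered by their trees, with one color family per
scale: blue sequential for quantitative rows (min–max scaled per row — raw
values are not comparable across variables), green sequential for ordinal
rows by level order, red shades for nominal rows, white for missing cells.
The display caps at 200 variables; beyond that, summarize or select first.
`plot_similarity_heatmap()` renders a similarity matrix with a monotone blue
scale ordered by the tree, and `plot_similarity_scatter()` places every
variable at (similarity to a chosen predictor, similarity to a chosen
outcome) — anchors at $(s_{op}, 1)$ and $(1, s_{op})$ — to flag candidate
predictors, surrogates, collinear variables and confounders at a glance.

## Known limitations

* Whether certain scale combinations systematically yield larger or smaller
  distances than others (e.g. quantitative–quantitative versus
  quantitative–binary) is an open calibration question; no cross-type
  correction is applied.
* The association-measure method targets monotone, correlation-like
  structure; non-monotone dependence is the distance-correlation method's
  territory.
* Pre-test gates are per-pair heuristics at a fixed $\alpha$; with thousands
  of pairs, a small fraction of independent pairs will pass the gate by
  construction.
* Gower distances with missing data need not satisfy the triangle
  inequality (denominators differ across pairs).
* The asymmetric-binary variant of Gower's coefficient is not implemented;
  binary variables always use the symmetric match/mismatch score.
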