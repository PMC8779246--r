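---
title: "Estimating symptom networks from ordinal rating scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating symptom networks from ordinal rating scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bprsnet)
```

## The problem

Psychiatric rating scales such as the 18-item Brief Psychiatric Rating Scale
(BPRS) score each symptom on an ordinal scale — here 1 ("not present") to 7
("very severe"). The network view of psychopathology treats the symptoms
themselves, and the conditional dependencies among them, as the object of
study: a symptom that is strongly connected to many others ("central") is a
candidate driver of the syndrome, and groups of densely interconnected
symptoms form clinically interpretable clusters. `bprsnet` implements the
full estimation pipeline for this kind of analysis — from raw ordinal
responses to a regularized partial-correlation network with centrality
indices, community structure, resampling diagnostics, and a group-difference
permutation test — together with a synthetic-data generator that makes every
step testable against a known ground truth.

## The model, step by step

### Polychoric correlations

Ordinal item scores are modeled as discretizations of latent standard-normal
variables: item $i$ shows category $k$ when its latent variable falls
between thresholds $\tau_{i,k-1}$ and $\tau_{i,k}$. The package uses the
standard two-step estimator:

1. **Thresholds** from the marginals: $\hat\tau_{i,k} =
   \Phi^{-1}(\hat F_i(k))$, the normal quantile of the cumulative response
   proportion.
2. **Correlation** per pair by maximum likelihood with thresholds fixed:
   $\hat\rho_{ij}$ maximizes $\sum_{ab} n_{ab}\log \pi_{ab}(\rho)$, where
   $\pi_{ab}$ is the bivariate-normal rectangle probability of cell $(a,b)$.

The two-step form (rather than full joint ML) is the default of the
psychometric tooling ecosystem and decouples threshold estimation from
correlation estimation, which also makes each step testable on its own.
Rectangle probabilities come from a compiled bivariate-normal CDF
(Gauss–Legendre quadrature of the Drezner–Wesolowsky angular integral, with
the transformed-tail quadrature above $|\rho| = 0.925$), accurate to about
1e-14; the optimizer is bounded Brent search on $[-0.999, 0.999]$. Cell
probabilities are clamped at $10^{-12}$ before the log so sparse tables
cannot produce $-\infty$; no further continuity correction is applied —
empty cells simply contribute nothing to the likelihood. An empty *internal*
category would create a zero-width latent interval; it is merged into its
upper neighbour and the merge recorded. Pairwise assembly does not guarantee
a positive-definite matrix, so if the smallest eigenvalue falls below
$10^{-8}$ the matrix is projected to the nearest unit-diagonal PD matrix by
alternating projections (the projection clips eigenvalues an order of
magnitude above the floor so the diagonal-restoring step cannot push them
back under it) and the result is flagged `pd_adjusted`.

### Graphical lasso with EBIC selection

The network is the Gaussian graphical model estimated by penalized maximum
likelihood: $\hat\Theta$ maximizes
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\neq j}|\Theta_{ij}|$
with the diagonal unpenalized, solved by block coordinate descent with an
inner soft-thresholding lasso (so zeros are exact). The penalty is chosen on
a 100-point log-spaced path from $\lambda_{\max}$ (the largest off-diagonal
$|S|$, where the graph is empty) down to $0.01\,\lambda_{\max}$, minimizing
the extended BIC

$$\mathrm{EBIC}_\gamma = -2\,\ell(\hat\Theta) + E\log n + 4\gamma E\log p,$$

with $E$ the number of edges and $\gamma = 0.5$, the conservative
convention for psychometric networks. Exact EBIC ties are broken toward the
larger penalty (sparser model). Edges are reported as partial correlations
$w_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. The multivariate
normal constant is omitted from the likelihood throughout; selection is
invariant to it. Edge counting uses a $10^{-8}$ threshold purely as a guard
against float noise — coordinate descent itself returns exact zeros.

### Centrality

Three node statistics are computed on the weighted graph, with edge lengths
$1/|w_{ij}|$ for the path-based ones:

* **strength** $s_i = \sum_j |w_{ij}|$ — absolute values because
  regularized networks contain negative edges;
* **closeness** $(p-1)/\sum_j d(i,j)$, summed over the nodes reachable from
  $i$ (its connected component; unreachable nodes contribute nothing, so
  closeness is still defined when the graph is disconnected). A harmonic
  variant (mean of $1/d(i,j)$) is available behind a flag, since published
  analyses do not always state which convention their tooling used;
* **betweenness** by Brandes' path-counting algorithm, with equal-length
  shortest paths split fractionally and counts halved for undirectedness,
  reported as unnormalized pair counts (z-scores make reporting scale-free
  anyway).

The distance transform $1/|w|$ is the key non-printed convention and is
deliberately the one the field's standard tooling applies. All three
metrics carry z-standardized versions; a metric that is constant across
nodes gets z-scores of 0 with a warning.

### Spin-glass communities

Communities minimize the configuration-null Potts Hamiltonian

$$H(\sigma) = -\sum_{i<j}\left(a_{ij} -
  \gamma\,\frac{s_i s_j}{2m}\right)\delta(\sigma_i,\sigma_j),$$

on absolute weights $a_{ij} = |w_{ij}|$, by Metropolis simulated annealing:
$p \times \mathrm{spins}$ single-node proposals per temperature, acceptance
$\min(1, e^{-\Delta H/T})$, temperature multiplied by 0.99 from 1 down
to 0.01, at most 17 communities. Defaults mirror the parameterization
standard for 18-item scales. Running on $|w|$ is the positive-weight
variant of the algorithm; the signed extension is out of scope and the
choice is flagged here. Because annealing is stochastic, the optimizer keeps
the best state ever visited and runs 10 independent restarts by default
(cheap at $p = 18$); with a fixed seed the result is reproducible. On
6-node graphs the annealer provably reaches the exhaustive minimum in the
test suite.

### Stability and inference

* **Case-dropping bootstrap / CS-coefficient.** For each drop proportion
  $q$ in a grid, subsamples of size $(1-q)n$ are drawn without replacement
  and the whole pipeline re-run; the CS-coefficient of a centrality index is
  the largest $q$ at which at least 95% of subsample centrality vectors
  correlate at least 0.7 with the full-sample vector. CS > 0.25 is
  conventionally interpretable, CS > 0.5 preferred. The correlation is
  product-moment by default — the cited convention of the method — with a
  rank (Spearman) option, since verbal descriptions of the coefficient
  sometimes say "ranking correlation". The grid (0.10–0.75 in steps of
  0.05) and 100 subsamples per point are package defaults, not sacred
  values; both are arguments.
* **Nonparametric bootstrap.** $B = 1000$ case-resamples with replacement;
  2.5%/97.5% empirical quantiles for every edge and strength, and for all
  pairwise differences; a difference is "significant" exactly when its
  interval excludes zero.
* **Group permutation test.** Whether one item group (e.g. the 8 symptoms
  mapping onto DSM criteria) is more central than the other (10): the
  observed difference in group means is compared against reassignments of
  the per-node values to groups of the same sizes. With 18 nodes all
  $\binom{18}{8} = 43{,}758$ assignments are enumerated — exact and cheaper
  than the conventional 100,000 Monte-Carlo draws, which remain available
  (`mode = "monte-carlo"`, add-one estimator $(1+\#)/(1+R)$ so $p > 0$).
  Two-sided significance at $p < 0.05$ corresponds to the observed
  difference falling in the 2.5% tails of the null.

## The synthetic-data generator

`make_truth_network()` plants a sparse block-structured partial-correlation
network — by default three blocks of 10/3/5 items mirroring the
positive/negative/general symptom clusters of the BPRS, within-block edge
density 0.5 with weights 0.15–0.45, and 4 weak (0.1) cross-block bridges.
Each block is built connected (spanning tree first), so without bridges the
truth has exactly one component per block. The pattern is written into a
unit-diagonal precision matrix which is diagonally loaded until its smallest
eigenvalue reaches 0.05; the partial correlations implied *after* loading
(attenuated by the loading) are stored as the achieved truth — what was
actually generated is what recovery is measured against. `sample_ordinal()`
then draws latent Gaussians with the implied correlation and discretizes at
the normal quantiles of per-item category probabilities; the packaged
defaults are the empirical category frequencies of a published 1438-patient
cohort, so simulated items reproduce the heavy floor effects of real symptom
ratings (six items with more than two thirds of responses at "not
present").

This is exactly the data model the polychoric estimator assumes — which is
the point: failures downstream cannot be blamed on model misspecification.
By the same token, passing tests on these data say nothing about rater
effects, item-level non-normality of the latent scale, missingness, or
measurement non-invariance across sites; real cohort data differ in all of
those ways.

## What recovery can and cannot achieve

Two honest limitations of the estimation stack, measured with the
generator's own truth and documented rather than hidden:

* **Weak spurious edges are intrinsic to EBIC-glasso here.** With dense
  blocks and strong within-block weights, the L1 penalty cannot unshrink
  the true edges without freeing weak false ones (the irrepresentability
  condition fails), so the EBIC optimum keeps two or three dozen spurious
  edges an order of magnitude weaker than the recovered true edges — even
  when fed the exact latent correlation matrix. Sensitivity is high
  (typically 0.94–1.00 at $n = 1438$); specificity plateaus around 0.7–0.8.
  The test suite therefore asserts high sensitivity plus the qualitative
  signature (false edges systematically weaker than true ones) rather than
  a symmetric sensitivity/specificity bar.
* **Community recovery follows the estimated network, not the truth.** On
  seeds where spurious plus bridge edges tie the small negative-symptom
  block to a neighbour, the annealer's partition has a genuinely lower
  Hamiltonian than the planted one; merging is then the correct answer for
  its input. The planted partition is recovered exactly when the truth
  weights are given directly.

The polychoric step contributes estimation noise concentrated in the most
skewed item pairs (floor > 75%), whose effective cell counts are tiny; the
pairwise mean absolute error at $n = 1438$ is about 0.02, but the worst of
the 153 pairs can be off by 0.1 or more in any given sample.

## Numerical and design choices

* Missing-data policy on load: reject the file by default (the emulated
  study used complete forms only); `drop-row` available, dropped count
  reported.
* Table-style reporting (means, SDs, percentages) rounds half up to one
  decimal, matching clinical-table convention; SDs use the $n-1$
  denominator (both denominators agree at one decimal on the packaged
  reference table).
* The permutation test's discreteness matters at small $p$: with 8 nodes
  and a 3/5 split the exact size of the test at the 0.05 level is
  $2/56 = 3.57\%$, which is what the type-I simulation in the acceptance
  suite is expected to produce — not 5% exactly.
* All randomized components (generator, annealer, layout, bootstraps,
  Monte-Carlo permutation, pipeline) take explicit seeds, record them in
  their outputs, and rerun byte-identically.
* Resampling problem sizes in the test suite and acceptance script are
  scaled down (stability grid 0.1–0.7 in steps of 0.1 with 10–25 subsamples
  per point, 20–40 penalty points) — sizes chosen so the whole validation
  runs comfortably at a desk; the statistical conventions are unchanged and
  full-scale defaults remain the package defaults.

## A complete run

```{r, eval = FALSE}
library(bprsnet)

spec <- make_truth_network(seed = 1)          # planted 3-cluster truth
ds <- sample_ordinal(spec, 1438, seed = 42)   # 1438 x 18 ordinal matrix

report <- run_pipeline(ds$data, bprs_catalog(),
                       output_dir = "results", seed = 1)
report$n_edges            # edges in the selected model
report$edge_fraction_pct  # percentage of the 153 possible edges
report$communities        # spin-glass partition
report$permutation$strength$p_value
```

`run_pipeline()` writes the edge list, centrality table, partition, layout
and a JSON report whose every number is recomputable from the stored inputs
and seeds; `scripts/acceptance.R` in the repository recomputes the
package's headline quantities from scratch the same way.
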