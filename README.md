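# bprsnet

Regularized partial-correlation networks for ordinal symptom ratings.

`bprsnet` implements the complete estimation pipeline used in psychometric
network analysis of clinical rating scales such as the 18-item Brief
Psychiatric Rating Scale (BPRS, items scored 1–7): subjects × items ordinal
data in, a sparse symptom network with centrality, community structure,
stability diagnostics and group-difference inference out. It is aimed at
researchers who want the whole chain — including the numerically delicate
parts — as plain, tested, seedable R code.

The pipeline:

1. **Polychoric correlations** — two-step maximum likelihood: latent-normal
   thresholds from the marginals, then each pairwise correlation ρ̂
   maximizing the bivariate-normal contingency likelihood
   Σ n_ab log π_ab(ρ), with a nearest-PD projection when pairwise assembly
   produces an indefinite matrix.
2. **Graphical lasso + EBIC** — penalized precision estimation maximizing
   log det Θ − tr(SΘ) − λΣ|Θ_ij| over a 100-point λ path; the extended BIC
   −2ℓ(Θ̂) + E log n + 4γE log p (γ = 0.5) selects the model; edges are
   partial correlations w_ij = −Θ_ij/√(Θ_ii Θ_jj).
3. **Centrality** — strength Σ|w_ij|, closeness and betweenness on
   distances 1/|w_ij|, raw and z-standardized.
4. **Spin-glass communities** — simulated annealing of the
   configuration-null Potts Hamiltonian
   H(σ) = −Σ_{i<j}(a_ij − γ s_i s_j / 2m) δ(σ_i, σ_j)
   (gamma = 0.5, spins = 17, T: 1 → 0.01, cooling 0.99).
5. **Resampling** — case-dropping bootstrap with the CS-coefficient
   (largest drop proportion keeping 95% of subsample centralities correlated
   ≥ 0.7 with the original), nonparametric bootstrap CIs (B = 1000), and an
   exact/Monte-Carlo permutation test for DSM vs non-DSM centrality
   differences (all C(18,8) = 43,758 reassignments enumerated by default).
6. **Synthetic data** — a latent-Gaussian copula generator with a planted
   block-structured partial-correlation network and per-item marginals
   matched to a published 1438-patient cohort, so the whole pipeline is
   testable with no external data.

## Worked example

```r
library(bprsnet)

spec <- make_truth_network(seed = 1)          # planted 10/3/5 block truth
ds   <- sample_ordinal(spec, 1438, seed = 42) # 1438 x 18 ordinal responses

pc  <- polychoric_matrix(ds$data)
net <- estimate_network(pc, n = 1438)
net
#> Partial-correlation network: 18 nodes, 70 / 153 edges
#>   selected lambda = 0.03731 (EBIC gamma = 0.5, n = 1438)

head(edge_list(net), 3)
#>   node_i node_j    weight
#> 1    GUI    DEP 0.2823742
#> 2    HAL    DIS 0.2615136
#> 3    MAN    GRA 0.2604381

spinglass_partition(net, seed = 2016)
#> Spin-glass partition: 3 communities, H = -4.2247
#>   [1] SOM ANX GUI TEN DEP
#>   [2] EMO MOT BLU
#>   [3] CON MAN GRA HOS SUS HAL UNC THO EXC DIS

cent <- centrality_table(net)
perm <- group_centrality_permutation(setNames(cent$strength, cent$node),
                                     bprs_catalog())
perm
#> Group-centrality permutation test (exhaustive, 43758 assignments)
#>   observed difference (DSM - other) = -0.0236, p = 0.8918
```

The selected model keeps 70 of the 153 possible edges; the strongest edges
are within-cluster partial correlations around 0.23–0.28; the annealer
recovers the three planted symptom clusters exactly; and the permutation
test finds no evidence that DSM-criterion symptoms are more central than
the rest (p = 0.89) — with the planted truth, none was built in.

`run_pipeline()` wraps the chain end to end and writes an edge-list TSV,
centrality CSV, partition CSV, layout TSV and a seeded, fully reproducible
`report.json`; `inst/cli/bprsnet` exposes the same steps as shell verbs
(`simulate`, `estimate`, `centrality`, `communities`, `stability`,
`permtest`, `report`).

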