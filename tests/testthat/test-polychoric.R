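# 1-D reduction of the bivariate-normal CDF: an oracle independent of the
# compiled quadrature
bvn_cdf_oracle <- function(h, k, r) {
  integrate(function(x) dnorm(x) * pnorm((k - r * x) / sqrt(1 - r^2)),
            -9, h, rel.tol = 1e-12, abs.tol = 1e-14,
            subdivisions = 2000L)$value
}

test_that("bivariate normal CDF matches numerical integration", {
  hs <- c(-2.5, -1, 0, 0.2125, 1, 2.3)
  rs <- c(-0.999, -0.95, -0.6, 0.001, 0.5, 0.8, 0.924, 0.926, 0.999)
  for (r in rs) for (h in hs) for (k in c(-1.3, 0.4, 2)) {
    expect_equal(bvn_cdf(h, k, r), bvn_cdf_oracle(h, k, r),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_equal(as.numeric(bvn_cdf(Inf, 0.3, 0.5)), pnorm(0.3))
  expect_equal(as.numeric(bvn_cdf(-Inf, 0.3, 0.5)), 0)
  expect_equal(as.numeric(bvn_cdf(Inf, Inf, -0.2)), 1)
})

test_that("thresholds are normal quantiles of cumulative proportions", {
  # median split: single threshold at 0
  th <- estimate_thresholds(rep(1:2, each = 50))
  expect_equal(th$cuts, c(-Inf, 0, Inf))

  # heavily skewed item: first threshold at qnorm(840/1438) ~ 0.2125
  v <- rep(1:7, times = c(840, 258, 199, 87, 37, 13, 4))
  th2 <- estimate_thresholds(v)
  expect_equal(th2$cuts[2], 0.2125, tolerance = 5e-4)
  expect_equal(th2$cuts[2], qnorm(840 / 1438))
  expect_true(all(diff(th2$cuts) > 0))

  # uniform over 7 categories converges on qnorm(k/7)
  u <- rep(1:7, each = 2000)
  expect_equal(estimate_thresholds(u)$cuts[2:7], qnorm((1:6) / 7),
               tolerance = 1e-12)
})

test_that("empty internal categories merge into their upper neighbour", {
  v <- rep(c(1L, 3L, 5L), times = c(30, 40, 30))
  th <- estimate_thresholds(v)
  expect_equal(length(th$cuts), 4)          # 3 occupied cells
  expect_equal(th$merge_map, c(1L, 2L, 2L, 3L, 3L))
  expect_error(estimate_thresholds(rep(2L, 50)), "constant")
})

test_that("pair estimate maximizes the contingency likelihood", {
  # perfect concordance pushes the estimate to the boundary
  set.seed(1)
  x <- sample(1:5, 400, TRUE)
  expect_gte(as.numeric(estimate_pair_rho(x, x)), 0.99)

  # independence: estimate near zero
  set.seed(2)
  xi <- sample(1:7, 5000, TRUE)
  xj <- sample(1:7, 5000, TRUE)
  expect_lt(abs(as.numeric(estimate_pair_rho(xi, xj))), 0.05)

  # true rho 0.5 under median splits: close to truth, and the continuous
  # optimum agrees with a grid search over the same likelihood computed
  # from integration-oracle cell probabilities
  set.seed(3)
  Z <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, .5, .5, 1), 2))
  xi <- (Z[, 1] > 0) + 1L
  xj <- (Z[, 2] > 0) + 1L
  rho <- as.numeric(estimate_pair_rho(xi, xj))
  expect_gte(rho, 0.45)
  expect_lte(rho, 0.55)
  tab <- table(xi, xj)
  cut_i <- estimate_thresholds(xi)$cuts[2]
  cut_j <- estimate_thresholds(xj)$cuts[2]
  grid <- seq(-0.99, 0.99, by = 0.01)
  nll <- vapply(grid, function(r) {
    Fhk <- bvn_cdf_oracle(cut_i, cut_j, r)
    pr <- matrix(c(Fhk, pnorm(cut_i) - Fhk, pnorm(cut_j) - Fhk,
                   1 - pnorm(cut_i) - pnorm(cut_j) + Fhk), 2, byrow = TRUE)
    -sum(tab * log(pmax(pr, 1e-12)))
  }, numeric(1))
  expect_lte(abs(rho - grid[which.min(nll)]), 0.01)
})

test_that("pair estimate is invariant to subject order and score shifts", {
  set.seed(4)
  Z <- MASS::mvrnorm(800, c(0, 0), matrix(c(1, .4, .4, 1), 2))
  xi <- findInterval(Z[, 1], c(-0.5, 0.4, 1.1)) + 1L
  xj <- findInterval(Z[, 2], c(0, 0.9)) + 1L
  base <- as.numeric(estimate_pair_rho(xi, xj))
  perm <- sample(length(xi))
  expect_equal(as.numeric(estimate_pair_rho(xi[perm], xj[perm])), base)
  expect_equal(as.numeric(estimate_pair_rho(xi + 2L, xj + 2L)), base)
})

test_that("pairwise recovery error stays small under skewed marginals", {
  marg <- packaged_bprs_marginals()
  cuts_a <- qnorm(cumsum(marg["SOM", ])[-7])
  cuts_b <- qnorm(cumsum(marg["HAL", ])[-7])
  errs <- c()
  for (s in 1:20) {
    for (rho in c(-0.8, -0.4, 0, 0.4, 0.8)) {
      set.seed(s * 1000 + round(rho * 10))
      Z <- MASS::mvrnorm(1438, c(0, 0), matrix(c(1, rho, rho, 1), 2))
      xi <- findInterval(Z[, 1], cuts_a) + 1L
      xj <- findInterval(Z[, 2], cuts_b) + 1L
      errs <- c(errs, abs(as.numeric(estimate_pair_rho(xi, xj)) - rho))
    }
  }
  expect_lt(mean(errs), 0.05)
})

test_that("polychoric matrix is symmetric, unit-diagonal and consistent", {
  set.seed(5)
  Z <- MASS::mvrnorm(600, rep(0, 2), matrix(c(1, .3, .3, 1), 2))
  x <- ordinal_matrix(cbind(A = findInterval(Z[, 1], c(-1, 0, 1)) + 1L,
                            B = findInterval(Z[, 2], c(-0.5, 0.7)) + 1L),
                      K = 7)
  pc <- polychoric_matrix(x)
  expect_equal(diag(pc$correlation), c(A = 1, B = 1))
  expect_equal(pc$correlation[1, 2],
               as.numeric(estimate_pair_rho(x[, 1], x[, 2])))
  expect_true(isSymmetric(pc$correlation))
})

test_that("matrix estimates track the generating latent correlation", {
  spec <- make_truth_network(seed = 1)
  ds <- sample_ordinal(spec, 1438, seed = 101)
  pc <- polychoric_matrix(ds$data)
  devs <- abs(pc$correlation - spec$latent_correlation)
  expect_lt(mean(devs[upper.tri(devs)]), 0.04)   # average estimation error
  expect_lt(max(devs), 0.2)                      # worst pair stays bounded
  expect_true(all(abs(pc$correlation) <= 1))
  expect_gte(min(eigen(pc$correlation, symmetric = TRUE,
                       only.values = TRUE)$values), 1e-8)
})

test_that("indefinite matrices project to the nearest PD correlation", {
  R <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_lt(min(eigen(R, only.values = TRUE)$values), 0)
  P <- nearest_pd_correlation(R)
  expect_equal(diag(P), rep(1, 3))
  expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
             1e-8 - 1e-12)
  expect_true(isSymmetric(P))
  # projection leaves an already-PD matrix essentially unchanged
  R2 <- matrix(c(1, .3, .3, 1), 2)
  expect_equal(nearest_pd_correlation(R2), R2, tolerance = 1e-8)
})

test_that("correlation TSV round trips", {
  spec <- make_truth_network(blocks = c(3, 3), seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_correlation_tsv(spec$latent_correlation, f)
  back <- read_correlation_tsv(f)
  expect_equal(back, spec$latent_correlation, tolerance = 1e-12)
})
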