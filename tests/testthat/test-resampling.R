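test_that("near-zero case dropping leaves centrality essentially intact", {
  spec <- make_truth_network(blocks = c(3, 3), seed = 1, bridge_count = 1)
  ds <- sample_ordinal(spec, 400, seed = 11)
  st <- case_drop_stability(ds$data, pipeline_config(n_lambda = 25),
                            grid = c(0.02, 0.05), B_per = 8, seed = 2)
  cors <- st$correlations$strength
  expect_true(all(cors[!is.na(cors)] > 0.7))
  expect_equal(unname(st$cs["strength"]), 0.05)  # max grid value
  expect_true(all(unlist(st$correlations) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("CS-coefficient is nonincreasing in the required correlation", {
  spec <- make_truth_network(blocks = c(3, 3), seed = 2, bridge_count = 1)
  ds <- sample_ordinal(spec, 300, seed = 12)
  st <- case_drop_stability(ds$data, pipeline_config(n_lambda = 25),
                            grid = c(0.1, 0.3, 0.5), B_per = 10, seed = 3)
  cs_prev <- Inf
  for (thr in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    cs_now <- cs_from_correlations(st, cor_threshold = thr)
    expect_true(all(cs_now <= cs_prev + 1e-12))
    cs_prev <- cs_now
  }
  expect_identical(names(st$cs), c("strength", "closeness", "betweenness"))
  expect_identical(unname(st$interpretable), unname(st$cs > 0.25))
  expect_identical(unname(st$preferred), unname(st$cs > 0.5))
})

test_that("strength is the most case-drop-stable index on generated cohorts", {
  wins <- 0
  for (s in 1:5) {
    spec <- make_truth_network(seed = s)
    ds <- sample_ordinal(spec, 1438, seed = s + 200)
    st <- case_drop_stability(ds$data, pipeline_config(n_lambda = 30),
                              grid = seq(0.1, 0.7, 0.1), B_per = 10,
                              seed = s)
    wins <- wins + (st$cs["strength"] >= st$cs["betweenness"])
  }
  expect_gte(wins, 4)
})

test_that("bootstrap reruns are identical given the seed and bounds are ordered", {
  spec <- make_truth_network(blocks = c(3, 3), seed = 3, bridge_count = 1)
  ds <- sample_ordinal(spec, 250, seed = 13)
  b1 <- nonparametric_bootstrap(ds$data, pipeline_config(n_lambda = 20),
                                B = 2, seed = 7)
  b2 <- nonparametric_bootstrap(ds$data, pipeline_config(n_lambda = 20),
                                B = 2, seed = 7)
  expect_identical(b1$edge_samples, b2$edge_samples)
  expect_identical(b1$edge_ci, b2$edge_ci)
  b3 <- nonparametric_bootstrap(ds$data, pipeline_config(n_lambda = 20),
                                B = 25, seed = 8)
  expect_true(all(b3$edge_ci$lower <= b3$edge_ci$upper))
  expect_true(all(b3$strength_ci$lower <= b3$strength_ci$upper))
  expect_true(all(b3$edge_diff$lower <= b3$edge_diff$upper))
  # a significant difference is exactly an interval excluding zero
  expect_identical(b3$strength_diff$significant,
                   b3$strength_diff$lower > 0 | b3$strength_diff$upper < 0)
})

test_that("true-zero edges are covered by their bootstrap intervals", {
  spec <- make_truth_network(blocks = c(3, 3), seed = 5, bridge_count = 0)
  expect_equal(spec$partial[1, 4], 0)
  cover <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    ds <- sample_ordinal(spec, 150, seed = 3000 + r)
    bt <- nonparametric_bootstrap(ds$data, pipeline_config(n_lambda = 30),
                                  B = 40, seed = r, diff_pairs = FALSE)
    ci <- bt$edge_ci[bt$edge_ci$node_i == spec$item_codes[1] &
                       bt$edge_ci$node_j == spec$item_codes[4], ]
    cover <- cover + (ci$lower <= 0 && ci$upper >= 0)
  }
  expect_gte(cover / reps, 0.85)  # ~95% nominal, within Monte-Carlo error
})

test_that("permutation test handles degenerate and extreme inputs exactly", {
  cat18 <- bprs_catalog()
  flat <- setNames(rep(2.5, 18), cat18$code)
  expect_equal(group_centrality_permutation(flat, cat18)$p_value, 1)

  # separation case: only one of the 43,758 assignments reaches |diff| = 10
  x <- setNames(numeric(18), cat18$code)
  x[cat18$code[cat18$group == "DSM"]] <- 10
  res <- group_centrality_permutation(x, cat18)
  expect_identical(res$mode, "exhaustive")
  expect_identical(res$R_used, choose(18, 8))
  expect_equal(res$observed, 10)
  expect_equal(res$p_value, 1 / 43758)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration", {
  cat18 <- bprs_catalog()
  set.seed(21)
  x <- setNames(rnorm(18, sd = 0.3) + (bprs_catalog()$group == "DSM") * 0.2,
                cat18$code)
  ex <- group_centrality_permutation(x, cat18, mode = "exhaustive")
  R <- 20000
  mc <- group_centrality_permutation(x, cat18, R = R, mode = "monte-carlo",
                                     seed = 5)
  tol <- 3 * sqrt(ex$p_value * (1 - ex$p_value) / R)
  expect_lt(abs(mc$p_value - ex$p_value), tol + 2 / R)
  expect_gt(mc$p_value, 0)   # add-one estimator never returns 0
  expect_lte(mc$p_value, 1)
  # identical reruns under the same seed
  mc2 <- group_centrality_permutation(x, cat18, R = R, mode = "monte-carlo",
                                      seed = 5)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("permutation test validates its inputs", {
  cat18 <- bprs_catalog()
  bad <- setNames(rnorm(18), paste0("X", 1:18))
  expect_error(group_centrality_permutation(bad, cat18), "do not match")
})

test_that("stability and permutation JSON writers emit their documented fields", {
  spec <- make_truth_network(blocks = c(3, 3), seed = 4, bridge_count = 1)
  ds <- sample_ordinal(spec, 250, seed = 14)
  st <- case_drop_stability(ds$data, pipeline_config(n_lambda = 20),
                            grid = c(0.1, 0.2), B_per = 5, seed = 1)
  f <- tempfile(fileext = ".json")
  write_stability_json(st, f)
  js <- jsonlite::fromJSON(f)
  expect_equal(js$grid, c(0.1, 0.2))
  expect_equal(js$cs$strength, unname(st$cs["strength"]))
  expect_equal(js$seed, 1)

  perm <- group_centrality_permutation(
    setNames(rnorm(6), spec$item_codes), make_test_catalog(6, 3, spec$item_codes))
  fp <- tempfile(fileext = ".json")
  write_permutation_json(perm, fp)
  jp <- jsonlite::fromJSON(fp)
  expect_equal(jp$p_value, perm$p_value)
  expect_equal(jp$mode, "exhaustive")
})
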