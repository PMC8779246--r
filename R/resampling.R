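#' Pipeline configuration
#'
#' Bundles the tuning parameters shared by the estimation pipeline and every
#' resampling routine that re-runs it.
#'
#' @param gamma_ebic EBIC hyperparameter
#' @param n_lambda penalties on the graphical-lasso path
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#' @param closeness_variant closeness formula, see [shortest_path_metrics()]
#' @return a list of class \code{pipeline_config}
#' @export
pipeline_config <- function(gamma_ebic = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01,
                            closeness_variant = "reciprocal") {
  structure(list(gamma_ebic = gamma_ebic, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 closeness_variant = closeness_variant),
            class = "pipeline_config")
}

#' Estimate the network from raw ordinal data
#'
#' Polychoric correlation matrix followed by EBIC-selected graphical lasso;
#' the single step every resampling routine repeats.
#'
#' @param data an \code{ordinal_matrix}
#' @param config a [pipeline_config()]
#' @return a \code{sym_network}
#' @export
network_from_data <- function(data, config = pipeline_config()) {
  pc <- polychoric_matrix(data)
  estimate_network(pc, n = nrow(data), gamma_ebic = config$gamma_ebic,
                   n_lambda = config$n_lambda,
                   lambda_min_ratio = config$lambda_min_ratio)
}

centrality_matrix <- function(data, config) {
  net <- network_from_data(data, config)
  tab <- suppressWarnings(centrality_table(net, config$closeness_variant))
  cbind(strength = tab$strength, closeness = tab$closeness,
        betweenness = tab$betweenness)
}

#' Case-dropping bootstrap stability and the CS-coefficient
#'
#' For each drop proportion q in \code{grid}, draws \code{B_per} subsamples
#' of size \code{round((1 - q) n)} without replacement, re-runs the full
#' pipeline (polychoric, EBIC graphical lasso, centrality) on each, and
#' records the correlation between the subsample and full-sample centrality
#' vectors. The CS-coefficient of an index is the largest q at which at
#' least 95\% of subsample correlations stay at or above 0.7; CS above 0.25
#' is conventionally "interpretable", above 0.5 "preferred". Subsamples on
#' which the pipeline fails are skipped and counted.
#'
#' @param data an \code{ordinal_matrix}
#' @param config a [pipeline_config()]
#' @param grid drop proportions
#' @param B_per subsamples per proportion
#' @param cor_method correlation between centrality vectors:
#'   product-moment \code{"pearson"} (default) or rank \code{"spearman"}
#' @param seed RNG seed
#' @return a list of class \code{stability_result}: \code{grid},
#'   \code{correlations} (per index, a grid x B matrix), \code{cs} (named
#'   CS-coefficients), \code{interpretable}, \code{preferred},
#'   \code{failures}, \code{cor_threshold}, \code{seed}
#' @export
case_drop_stability <- function(data, config = pipeline_config(),
                                grid = seq(0.10, 0.75, by = 0.05),
                                B_per = 100,
                                cor_method = c("pearson", "spearman"),
                                seed = 1) {
  cor_method <- match.arg(cor_method)
  n <- nrow(data)
  p <- ncol(data)
  stopifnot(all(grid > 0), all(grid < 1))
  if (round((1 - max(grid)) * n) < p + 1) {
    stop("largest drop proportion leaves fewer than p + 1 cases")
  }
  full <- centrality_matrix(data, config)
  indices <- colnames(full)
  cors <- lapply(indices, function(i) {
    matrix(NA_real_, length(grid), B_per,
           dimnames = list(format(grid), NULL))
  })
  names(cors) <- indices
  failures <- 0L
  set.seed(seed)
  for (g in seq_along(grid)) {
    m <- round((1 - grid[g]) * n)
    for (b in seq_len(B_per)) {
      idx <- sample.int(n, m)
      sub <- tryCatch(
        centrality_matrix(ordinal_matrix(unclass(data)[idx, , drop = FALSE],
                                         colnames(data), attr(data, "K")),
                          config),
        error = function(e) NULL)
      if (is.null(sub)) {
        failures <- failures + 1L
        next
      }
      for (i in indices) {
        cors[[i]][g, b] <- suppressWarnings(
          cor(full[, i], sub[, i], method = cor_method))
      }
    }
  }
  out <- structure(list(grid = grid, correlations = cors, failures = failures,
                        cor_threshold = 0.7, prob = 0.95,
                        cor_method = cor_method, B_per = B_per, seed = seed),
                   class = "stability_result")
  out$cs <- cs_from_correlations(out)
  out$interpretable <- out$cs > 0.25
  out$preferred <- out$cs > 0.5
  out
}

#' CS-coefficient from stored subsample correlations
#'
#' Recomputes the CS-coefficient of each centrality index from an existing
#' [case_drop_stability()] result, optionally at a different correlation
#' threshold. Constant centrality vectors yield undefined correlations;
#' such draws are treated as stable (correlation 1) would be wrong, so they
#' are simply excluded from the fraction.
#'
#' @param stab a \code{stability_result}
#' @param cor_threshold required correlation (default the stored 0.7)
#' @param prob required probability (default 0.95)
#' @return named vector of CS values (0 when no grid point qualifies)
#' @export
cs_from_correlations <- function(stab, cor_threshold = NULL, prob = NULL) {
  thr <- cor_threshold %||% stab$cor_threshold
  pr <- prob %||% stab$prob
  vapply(stab$correlations, function(m) {
    frac <- apply(m, 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) return(0)
      mean(r >= thr)
    })
    ok <- stab$grid[frac >= pr]
    if (length(ok)) max(ok) else 0
  }, numeric(1))
}

#' Nonparametric bootstrap of edge weights and centralities
#'
#' Draws B case-resamples with replacement, re-runs the pipeline, and stores
#' 2.5\%/97.5\% empirical quantiles for every edge weight and node strength,
#' and for all pairwise differences (edge minus edge, strength minus
#' strength). A difference is flagged significant when its interval excludes
#' zero. Deterministic given \code{seed}.
#'
#' @param data an \code{ordinal_matrix}
#' @param config a [pipeline_config()]
#' @param B bootstrap samples
#' @param seed RNG seed
#' @param diff_pairs also compute pairwise-difference intervals (can be
#'   large: choose(p(p-1)/2, 2) edge pairs)
#' @return a list of class \code{bootstrap_result}: \code{edge_ci},
#'   \code{strength_ci} (data frames with point estimate and bounds),
#'   \code{edge_diff}, \code{strength_diff} (difference intervals with a
#'   \code{significant} flag), \code{failures}, \code{B}, \code{seed}
#' @export
nonparametric_bootstrap <- function(data, config = pipeline_config(),
                                    B = 1000, seed = 1, diff_pairs = TRUE) {
  n <- nrow(data)
  p <- ncol(data)
  codes <- colnames(data)
  full_net <- network_from_data(data, config)
  idx_ut <- upper_tri_pairs(p)
  n_e <- nrow(idx_ut)
  edge_s <- matrix(NA_real_, B, n_e)
  str_s <- matrix(NA_real_, B, p)
  failures <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    net <- tryCatch(
      network_from_data(ordinal_matrix(unclass(data)[rows, , drop = FALSE],
                                       codes, attr(data, "K")), config),
      error = function(e) NULL)
    if (is.null(net)) {
      failures <- failures + 1L
      next
    }
    edge_s[b, ] <- net$weights[idx_ut]
    str_s[b, ] <- strength(net)
  }
  ok <- !is.na(edge_s[, 1])
  qs <- function(m) t(apply(m[ok, , drop = FALSE], 2, quantile,
                            probs = c(0.025, 0.975), names = FALSE))
  eq <- qs(edge_s)
  sq <- qs(str_s)
  edge_ci <- data.frame(node_i = codes[idx_ut[, 1]],
                        node_j = codes[idx_ut[, 2]],
                        estimate = full_net$weights[idx_ut],
                        lower = eq[, 1], upper = eq[, 2],
                        stringsAsFactors = FALSE)
  strength_ci <- data.frame(node = codes, estimate = strength(full_net),
                            lower = sq[, 1], upper = sq[, 2],
                            row.names = NULL, stringsAsFactors = FALSE)
  diff_ci <- function(samples, labels) {
    np <- ncol(samples)
    pr <- upper_tri_pairs(np)
    d <- samples[ok, pr[, 1], drop = FALSE] -
      samples[ok, pr[, 2], drop = FALSE]
    dq <- t(apply(d, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
    data.frame(a = labels[pr[, 1]], b = labels[pr[, 2]],
               lower = dq[, 1], upper = dq[, 2],
               significant = dq[, 1] > 0 | dq[, 2] < 0,
               stringsAsFactors = FALSE)
  }
  edge_diff <- strength_diff <- NULL
  if (diff_pairs) {
    elab <- paste(codes[idx_ut[, 1]], codes[idx_ut[, 2]], sep = "--")
    edge_diff <- diff_ci(edge_s, elab)
    strength_diff <- diff_ci(str_s, codes)
  }
  structure(list(edge_ci = edge_ci, strength_ci = strength_ci,
                 edge_diff = edge_diff, strength_diff = strength_diff,
                 edge_samples = edge_s, strength_samples = str_s,
                 failures = failures, B = B, seed = seed),
            class = "bootstrap_result")
}

#' Permutation test for group differences in centrality
#'
#' Tests whether the mean centrality of one item group (e.g. the DSM
#' symptoms) differs from the other by reassigning the observed per-node
#' centralities to groups of the same sizes. With 8 of 18 nodes in group
#' one there are choose(18, 8) = 43,758 assignments, so exhaustive
#' enumeration is exact and cheaper than Monte-Carlo; \code{mode = "auto"}
#' enumerates whenever that count does not exceed \code{R}. The two-sided
#' p-value is the tail fraction \eqn{\#\{|null| \ge |obs|\}} over all
#' assignments (exhaustive) or the add-one estimator
#' \eqn{(1 + \#)/(1 + R)} (Monte-Carlo).
#'
#' @param centrality named per-node values; names must match catalog codes
#' @param catalog an \code{item_catalog}; its \code{group} column defines
#'   the two groups
#' @param R Monte-Carlo reassignments
#' @param mode \code{"auto"}, \code{"exhaustive"} or \code{"monte-carlo"}
#' @param seed RNG seed (Monte-Carlo mode)
#' @return a list of class \code{perm_test_result}: \code{observed} (mean
#'   group 1 minus mean group 2), \code{p_value}, \code{mode}, \code{R_used},
#'   \code{group_sizes}, \code{null} (the null-distribution sample),
#'   \code{seed}
#' @export
group_centrality_permutation <- function(centrality, catalog,
                                         R = 100000,
                                         mode = c("auto", "exhaustive",
                                                  "monte-carlo"),
                                         seed = 1) {
  mode <- match.arg(mode)
  codes <- catalog$code
  if (!setequal(names(centrality), codes)) {
    stop("centrality names do not match catalog item codes")
  }
  x <- as.numeric(centrality[codes])
  groups <- catalog$group
  g1 <- unique(groups)[1]
  if ("DSM" %in% groups) g1 <- "DSM"
  in1 <- groups == g1
  n1 <- sum(in1)
  n2 <- sum(!in1)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  p <- length(x)
  observed <- mean(x[in1]) - mean(x[!in1])
  n_exh <- choose(p, n1)
  if (mode == "auto") {
    mode <- if (n_exh <= R) "exhaustive" else "monte-carlo"
  }
  tol <- 1e-12
  total <- sum(x)
  if (mode == "exhaustive") {
    cmb <- combn(p, n1)
    s1 <- colSums(matrix(x[cmb], nrow = n1))
    nulls <- s1 / n1 - (total - s1) / n2
    p_value <- mean(abs(nulls) >= abs(observed) - tol)
    R_used <- n_exh
  } else {
    set.seed(seed)
    nulls <- vapply(seq_len(R), function(b) {
      pick <- sample.int(p, n1)
      s1 <- sum(x[pick])
      s1 / n1 - (total - s1) / n2
    }, numeric(1))
    p_value <- (1 + sum(abs(nulls) >= abs(observed) - tol)) / (1 + R)
    R_used <- R
  }
  structure(list(observed = observed, p_value = p_value, mode = mode,
                 R_used = R_used, group_sizes = c(n1, n2), group1 = g1,
                 null = nulls, seed = seed),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "Group-centrality permutation test (%s, %d assignments)\n  observed difference (%s - other) = %.4f, p = %.4g\n",
    x$mode, x$R_used, x$group1, x$observed, x$p_value))
  invisible(x)
}

#' Stability-result JSON writer
#'
#' @param stab a \code{stability_result}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_stability_json <- function(stab, path) {
  summ <- lapply(stab$correlations, function(m) {
    list(mean = unname(rowMeans(m, na.rm = TRUE)),
         frac_ge_threshold = unname(apply(m, 1, function(r) {
           mean(r[!is.na(r)] >= stab$cor_threshold)
         })))
  })
  jsonlite::write_json(
    list(grid = stab$grid, cs = as.list(stab$cs),
         interpretable = as.list(stab$interpretable),
         preferred = as.list(stab$preferred),
         cor_threshold = stab$cor_threshold, cor_method = stab$cor_method,
         B_per = stab$B_per, failures = stab$failures, seed = stab$seed,
         summary = summ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Permutation-result JSON writer
#' @param perm a \code{perm_test_result}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_permutation_json <- function(perm, path) {
  jsonlite::write_json(
    list(observed = perm$observed, p_value = perm$p_value, mode = perm$mode,
         R = perm$R_used, group_sizes = perm$group_sizes,
         group1 = perm$group1, seed = perm$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
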