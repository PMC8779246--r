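#' Graphical lasso fit at one penalty
#'
#' Maximizes \eqn{\log\det\Theta - tr(S\Theta) - \lambda\sum_{i\ne j}|\Theta_{ij}|}
#' by block coordinate descent with an inner soft-thresholding lasso per
#' column; the diagonal is unpenalized. Soft-thresholding yields exact zeros
#' in the precision matrix.
#'
#' @param S symmetric positive-definite correlation (or covariance) matrix
#' @param lam nonnegative L1 penalty
#' @param tol outer convergence tolerance (max elementwise change)
#' @param maxit maximum number of outer sweeps
#' @return the estimated precision matrix, with attributes \code{sweeps} and
#'   \code{W} (the implied covariance)
#' @export
glasso_fit <- function(S, lam, tol = 1e-6, maxit = 500) {
  S <- as.matrix(S)
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("S must be symmetric")
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("S must be positive definite (min eigenvalue ", ev, ")")
  fit <- glasso_cpp(S, lam, tol, maxit)
  if (!fit$converged) {
    stop(sprintf("graphical lasso did not converge in %d sweeps (lam = %g)",
                 maxit, lam))
  }
  Theta <- fit$Theta
  dimnames(Theta) <- dimnames(S)
  structure(Theta, sweeps = fit$sweeps, W = fit$W)
}

#' Extended Bayesian Information Criterion of a precision matrix
#'
#' \deqn{-2\,(n/2)(\log\det\Theta - tr(S\Theta)) + E\log n + 4\gamma E\log p}
#' where E counts nonzero upper-triangle off-diagonal entries
#' (\code{|Theta_ij| > edge_tol}). The multivariate-normal constant is
#' omitted consistently; model selection is invariant to it.
#'
#' @param Theta precision matrix (positive definite)
#' @param S sample correlation matrix
#' @param n sample size
#' @param gamma_ebic EBIC hyperparameter (0 recovers ordinary BIC)
#' @param edge_tol threshold below which an entry counts as zero
#' @return the EBIC value, with attributes \code{E} and \code{loglik}
#' @export
ebic <- function(Theta, S, n, gamma_ebic = 0.5, edge_tol = 1e-8) {
  p <- nrow(Theta)
  ll <- (n / 2) * (determinant(Theta, logarithm = TRUE)$modulus[1] -
                     sum(S * Theta))
  E <- sum(abs(Theta[upper.tri(Theta)]) > edge_tol)
  val <- -2 * ll + E * log(n) + 4 * gamma_ebic * E * log(p)
  structure(val, E = E, loglik = ll)
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along a descending log-spaced penalty path from
#' \eqn{\lambda_{max}} (the largest absolute off-diagonal of S, at which the
#' graph is empty) down to \eqn{\lambda_{max}\cdot} \code{lambda_min_ratio},
#' selects the penalty minimizing the EBIC (ties broken toward larger
#' penalties, i.e. sparser models), and converts the selected precision
#' matrix to partial-correlation edge weights
#' \eqn{w_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}}.
#'
#' @param S correlation matrix or a \code{polychoric_result}
#' @param n number of subjects behind S
#' @param gamma_ebic EBIC hyperparameter (default 0.5, the conservative
#'   convention for psychometric networks)
#' @param n_lambda number of penalties on the path
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#' @param item_codes node names (defaults to the row names of S)
#' @return a list of class \code{sym_network}: \code{weights} (symmetric,
#'   zero diagonal), \code{Theta}, \code{lambda}, \code{gamma_ebic},
#'   \code{n}, \code{n_edges}, \code{path} (a data frame with one row per
#'   penalty: lambda, loglik, n_edges, ebic)
#' @export
estimate_network <- function(S, n, gamma_ebic = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, item_codes = NULL) {
  if (inherits(S, "polychoric_result")) S <- S$correlation
  S <- as.matrix(S)
  p <- nrow(S)
  item_codes <- item_codes %||% rownames(S) %||% paste0("V", seq_len(p))
  if (n <= p) {
    warning("sample size n <= number of items p; estimates may be unstable")
  }
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max < 1e-12) {
    W <- matrix(0, p, p, dimnames = list(item_codes, item_codes))
    return(new_sym_network(W, diag(p), NA_real_, gamma_ebic, n, item_codes,
                           path = NULL))
  }
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  fits <- vector("list", n_lambda)
  path <- data.frame(lambda = lambdas, loglik = NA_real_,
                     n_edges = NA_integer_, ebic = NA_real_)
  for (k in seq_len(n_lambda)) {
    Theta <- glasso_fit(S, lambdas[k])
    eb <- ebic(Theta, S, n, gamma_ebic)
    fits[[k]] <- Theta
    path$loglik[k] <- attr(eb, "loglik")
    path$n_edges[k] <- attr(eb, "E")
    path$ebic[k] <- as.numeric(eb)
  }
  best <- which.min(path$ebic)  # first minimum = largest lambda on ties
  Theta <- fits[[best]]
  d <- sqrt(diag(Theta))
  W <- -Theta / outer(d, d)
  diag(W) <- 0
  W[abs(Theta) <= 1e-8 & row(W) != col(W)] <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- list(item_codes, item_codes)
  new_sym_network(W, Theta, lambdas[best], gamma_ebic, n, item_codes, path)
}

new_sym_network <- function(W, Theta, lambda, gamma_ebic, n, item_codes,
                            path) {
  structure(list(weights = W, Theta = Theta, lambda = lambda,
                 gamma_ebic = gamma_ebic, n = n, item_codes = item_codes,
                 n_edges = sum(W[upper.tri(W)] != 0), path = path),
            class = "sym_network")
}

#' Wrap a weight matrix as a network object
#'
#' Convenience constructor used by the generators and in tests: takes a
#' symmetric partial-correlation weight matrix directly.
#'
#' @param W symmetric matrix with zero diagonal, entries in (-1, 1)
#' @param item_codes node names
#' @return a \code{sym_network}
#' @export
as_sym_network <- function(W, item_codes = NULL) {
  W <- as.matrix(W)
  item_codes <- item_codes %||% rownames(W) %||% paste0("V", seq_len(nrow(W)))
  if (!isSymmetric(unname(W), tol = 1e-10)) stop("W must be symmetric")
  if (any(abs(W) >= 1)) stop("partial-correlation weights must lie in (-1, 1)")
  diag(W) <- 0
  dimnames(W) <- list(item_codes, item_codes)
  new_sym_network(W, Theta = NULL, lambda = NA_real_, gamma_ebic = NA_real_,
                  n = NA_integer_, item_codes = item_codes, path = NULL)
}

#' @export
print.sym_network <- function(x, ...) {
  p <- length(x$item_codes)
  cat(sprintf("Partial-correlation network: %d nodes, %d / %d edges\n",
              p, x$n_edges, p * (p - 1) / 2))
  if (!is.na(x$lambda)) {
    cat(sprintf("  selected lambda = %.4g (EBIC gamma = %g, n = %d)\n",
                x$lambda, x$gamma_ebic, x$n))
  }
  invisible(x)
}

#' Edge list of a network
#'
#' @param net a \code{sym_network}
#' @param nonzero_only drop zero-weight pairs (default TRUE)
#' @return data frame \code{node_i}, \code{node_j}, \code{weight}, sorted by
#'   absolute weight descending
#' @export
edge_list <- function(net, nonzero_only = TRUE) {
  W <- net$weights
  idx <- upper_tri_pairs(nrow(W))
  df <- data.frame(node_i = net$item_codes[idx[, 1]],
                   node_j = net$item_codes[idx[, 2]],
                   weight = W[idx], stringsAsFactors = FALSE)
  if (nonzero_only) df <- df[df$weight != 0, , drop = FALSE]
  df <- df[order(-abs(df$weight)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Network writers
#'
#' \code{write_edge_list()} writes the |weight|-sorted edge list as TSV;
#' \code{write_weight_matrix()} the square weight matrix as TSV;
#' \code{write_graphml()} a minimal GraphML file with a \code{weight} edge
#' attribute.
#'
#' @param net a \code{sym_network}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(edge_list(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_weight_matrix <- function(net, path) {
  write_correlation_tsv(net$weights, path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  el <- edge_list(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '<graph edgedefault="undirected">'), con)
  writeLines(sprintf('<node id="%s"/>', net$item_codes), con)
  writeLines(sprintf(
    '<edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
    el$node_i, el$node_j, el$weight), con)
  writeLines(c('</graph>', '</graphml>'), con)
  invisible(path)
}
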