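#' Estimate latent-normal thresholds from ordinal marginals
#'
#' Step one of the two-step polychoric estimator: for each item the k-th
#' threshold is the standard-normal quantile of the cumulative proportion of
#' responses in categories up to k. Empty categories at the margins simply
#' yield no interior threshold there; an empty internal category would create
#' a zero-width latent interval, so it is merged into its upper neighbour and
#' the merge recorded in \code{merge_map}.
#'
#' @param x an \code{ordinal_matrix}, or a single integer vector
#' @return for a matrix, a list of class \code{threshold_set} (one element
#'   per item); for a vector, a single threshold element. Each element has
#'   \code{cuts} (cell boundaries including the \code{-Inf}/\code{Inf}
#'   sentinels), \code{merge_map} (observed category -> cell index) and
#'   \code{props} (cell proportions).
#' @export
estimate_thresholds <- function(x) {
  if (is.matrix(x)) {
    out <- lapply(seq_len(ncol(x)), function(j) {
      thresholds_one(x[, j], colnames(x)[j])
    })
    names(out) <- colnames(x)
    class(out) <- "threshold_set"
    return(out)
  }
  thresholds_one(x, deparse(substitute(x)))
}

thresholds_one <- function(v, label = "item") {
  lev <- sort(unique(v))
  if (length(lev) < 2) {
    stop(sprintf("item %s is constant: no correlation estimable", label))
  }
  counts <- as.numeric(table(factor(v, levels = lev)))
  props <- counts / sum(counts)
  cuts <- c(-Inf, qnorm(cumsum(props)[-length(props)]), Inf)
  # map every possible category value onto its cell: an empty internal
  # category merges into its upper neighbour (leading empties join cell 1)
  K <- max(lev)
  merge_map <- vapply(seq_len(K), function(ct) {
    hit <- which(lev >= ct)
    if (length(hit)) hit[1] else length(lev)
  }, integer(1))
  list(cuts = cuts, merge_map = merge_map, props = props, levels = lev)
}

#' Maximum-likelihood polychoric correlation of one item pair
#'
#' Step two of the two-step estimator: with thresholds fixed at their
#' marginal estimates, the latent correlation maximizes the multinomial
#' log-likelihood of the observed cross-tabulation, where each cell
#' probability is the bivariate-normal rectangle probability between the
#' cell's thresholds. One-dimensional bounded optimization over
#' \eqn{[-0.999, 0.999]}; empty cells contribute nothing and cell
#' probabilities are clamped at 1e-12 before the log.
#'
#' @param xi,xj equal-length integer vectors
#' @param ti,tj threshold elements from [estimate_thresholds()]; estimated
#'   from \code{xi}, \code{xj} when omitted
#' @return the estimated correlation, with the maximized log-likelihood in
#'   attribute \code{loglik}
#' @export
estimate_pair_rho <- function(xi, xj, ti = NULL, tj = NULL) {
  stopifnot(length(xi) == length(xj))
  ti <- ti %||% thresholds_one(xi, "i")
  tj <- tj %||% thresholds_one(xj, "j")
  bi <- factor(ti$merge_map[xi], levels = seq_along(ti$props))
  bj <- factor(tj$merge_map[xj], levels = seq_along(tj$props))
  tab <- table(bi, bj)
  counts <- matrix(as.numeric(tab), nrow = nrow(tab))
  opt <- optimize(function(r) pair_negloglik_cpp(r, counts, ti$cuts, tj$cuts),
                  interval = c(-0.999, 0.999), tol = 1e-7)
  structure(opt$minimum, loglik = -opt$objective)
}

#' Polychoric correlation matrix
#'
#' Assembles all pairwise two-step estimates into a symmetric matrix with
#' unit diagonal. Pairwise estimation does not guarantee positive
#' definiteness; if the smallest eigenvalue falls below \code{1e-8} the
#' matrix is projected to the nearest positive-definite correlation matrix
#' (alternating projections, unit diagonal preserved) and flagged.
#'
#' @param x an \code{ordinal_matrix}
#' @return a list of class \code{polychoric_result}: \code{correlation}
#'   (p x p), \code{thresholds}, \code{pd_adjusted}, \code{min_eigenvalue}
#'   (before any adjustment)
#' @export
polychoric_matrix <- function(x) {
  p <- ncol(x)
  if (p < 2) stop("need at least two items")
  th <- estimate_thresholds(x)
  R <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      R[i, j] <- R[j, i] <-
        as.numeric(estimate_pair_rho(x[, i], x[, j], th[[i]], th[[j]]))
    }
  }
  dimnames(R) <- list(colnames(x), colnames(x))
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  pd_adjusted <- FALSE
  if (ev_min < 1e-8) {
    R <- nearest_pd_correlation(R)
    pd_adjusted <- TRUE
  }
  structure(list(correlation = R, thresholds = th,
                 pd_adjusted = pd_adjusted, min_eigenvalue = ev_min),
            class = "polychoric_result")
}

#' Nearest positive-definite correlation matrix
#'
#' Alternating projections (with Dykstra's correction) between the cone of
#' matrices with smallest eigenvalue at least \code{eig_floor} and the set of
#' unit-diagonal symmetric matrices.
#'
#' @param R symmetric matrix
#' @param eig_floor smallest admissible eigenvalue
#' @param tol convergence tolerance on the iterate change
#' @param maxit iteration cap
#' @return unit-diagonal symmetric matrix with min eigenvalue >= eig_floor
#' @export
nearest_pd_correlation <- function(R, eig_floor = 1e-8, tol = 1e-10,
                                   maxit = 500) {
  Y <- R
  D <- matrix(0, nrow(R), ncol(R))
  # clip slightly above the floor so the unit-diagonal step cannot push the
  # smallest eigenvalue back under it at convergence tolerance
  clip <- eig_floor * 10
  for (it in seq_len(maxit)) {
    Rk <- Y - D
    e <- eigen(Rk, symmetric = TRUE)
    X <- e$vectors %*% (pmax(e$values, clip) * t(e$vectors))
    X <- (X + t(X)) / 2
    D <- X - Rk
    Ynew <- X
    diag(Ynew) <- 1
    if (max(abs(Ynew - Y)) < tol) {
      Y <- Ynew
      break
    }
    Y <- Ynew
  }
  dimnames(Y) <- dimnames(R)
  Y
}

#' Write / read a square correlation matrix as TSV
#'
#' Header row and first column carry the item codes.
#'
#' @param R matrix (or \code{polychoric_result})
#' @param path file path
#' @return \code{path} (write) or the matrix (read)
#' @export
write_correlation_tsv <- function(R, path) {
  if (inherits(R, "polychoric_result")) R <- R$correlation
  df <- data.frame(item = rownames(R), R, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_tsv
#' @export
read_correlation_tsv <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
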