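#' Packaged BPRS marginal category probabilities
#'
#' Per-item probabilities of the 7 response categories, obtained from the
#' packaged reference-cohort frequency counts ([bprs_reference_counts()])
#' divided by the cohort size (1438). These are the default marginals of the
#' synthetic generator, so simulated data reproduce the heavy skew toward
#' "not present" typical of symptom ratings.
#'
#' @return 18 x 7 matrix of probabilities; every row sums to 1
#' @export
packaged_bprs_marginals <- function() {
  counts <- bprs_reference_counts()
  counts / rowSums(counts)
}

#' Construct a ground-truth sparse partial-correlation network
#'
#' Builds the generating model for synthetic ordinal data: a block-structured
#' partial-correlation pattern (three symptom clusters by default, sizes
#' 10/3/5) with a stated within-block edge density and weight range, plus a
#' few weak cross-block bridge edges. Each block is kept internally connected
#' (random spanning tree first, then extra edges up to the density target),
#' so absent bridges the truth has exactly as many connected components as
#' blocks. The pattern is written into a unit-diagonal precision matrix
#' (\eqn{\Theta_{ij} = -w_{ij}}), which is then diagonally loaded until its
#' smallest eigenvalue reaches 0.05; the partial correlations implied
#' after loading are re-derived and stored as the achieved truth that
#' recovery tests compare against.
#'
#' @param blocks block sizes (must sum to p)
#' @param within_density fraction of within-block pairs carrying an edge
#'   (a connected spanning tree is a floor when density > 0)
#' @param within_weight_range range of within-block partial correlations
#' @param bridge_count number of cross-block edges
#' @param bridge_weight partial correlation of bridge edges
#' @param seed RNG seed
#' @param item_codes node names; for p = 18 defaults to the BPRS codes with
#'   blocks matching the positive/negative/general symptom clusters
#' @param marginals per-item category probability matrix (rows recycled from
#'   the packaged BPRS marginals by default)
#' @param loading_cap maximum admissible diagonal loading
#' @return a list of class \code{synthetic_spec}: \code{p}, \code{blocks},
#'   \code{membership}, \code{precision}, \code{partial} (achieved truth),
#'   \code{target_partial}, \code{latent_correlation}, \code{item_codes},
#'   \code{marginals}, \code{loading}, \code{seed}
#' @export
make_truth_network <- function(blocks = c(10, 3, 5), within_density = 0.5,
                               within_weight_range = c(0.15, 0.45),
                               bridge_count = 4, bridge_weight = 0.1,
                               seed = 1, item_codes = NULL, marginals = NULL,
                               loading_cap = 10) {
  p <- sum(blocks)
  stopifnot(within_density >= 0, within_density <= 1, bridge_count >= 0)
  set.seed(seed)

  if (is.null(item_codes) && p == 18 && identical(blocks, c(10, 3, 5))) {
    # mirror the three clinical symptom clusters of the 18-item scale
    members <- list(
      c("CON", "MAN", "GRA", "HOS", "SUS", "HAL", "UNC", "THO", "EXC", "DIS"),
      c("EMO", "MOT", "BLU"),
      c("SOM", "ANX", "GUI", "TEN", "DEP"))
    codes <- bprs_catalog()$code
    membership <- integer(p)
    names(membership) <- codes
    for (b in seq_along(members)) membership[members[[b]]] <- b
  } else {
    codes <- item_codes %||% paste0("V", seq_len(p))
    membership <- setNames(rep(seq_along(blocks), blocks), codes)
  }

  P <- matrix(0, p, p, dimnames = list(codes, codes))
  for (b in seq_along(blocks)) {
    idx <- which(membership == b)
    nb <- length(idx)
    if (nb < 2 || within_density == 0) next
    pairs <- t(combn(idx, 2))
    target <- max(nb - 1, round(within_density * nrow(pairs)))
    target <- min(target, nrow(pairs))
    # random spanning tree keeps the block connected
    perm <- sample(idx)
    tree <- cbind(perm[-1], vapply(2:nb, function(k) {
      perm[sample.int(k - 1, 1)]
    }, numeric(1)))
    tree <- t(apply(tree, 1, sort))
    key <- function(m) paste(m[, 1], m[, 2])
    rest <- pairs[!(key(pairs) %in% key(tree)), , drop = FALSE]
    extra <- target - nrow(tree)
    if (extra > 0 && nrow(rest) > 0) {
      rest <- rest[sample(nrow(rest), min(extra, nrow(rest))), ,
                   drop = FALSE]
      edges <- rbind(tree, rest)
    } else {
      edges <- tree
    }
    w <- runif(nrow(edges), within_weight_range[1], within_weight_range[2])
    for (e in seq_len(nrow(edges))) {
      P[edges[e, 1], edges[e, 2]] <- P[edges[e, 2], edges[e, 1]] <- w[e]
    }
  }
  if (bridge_count > 0 && length(blocks) > 1) {
    cross <- t(combn(seq_len(p), 2))
    cross <- cross[membership[cross[, 1]] != membership[cross[, 2]], ,
                   drop = FALSE]
    pick <- cross[sample(nrow(cross), min(bridge_count, nrow(cross))), ,
                  drop = FALSE]
    for (e in seq_len(nrow(pick))) {
      P[pick[e, 1], pick[e, 2]] <- P[pick[e, 2], pick[e, 1]] <- bridge_weight
    }
  }

  Theta <- diag(p) - P  # unit diagonal, Theta_ij = -w_ij
  ev_min <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
  loading <- max(0, 0.05 - ev_min)
  if (loading > loading_cap) {
    stop(sprintf(
      "weights infeasible: diagonal loading %.2f exceeds cap %.2f",
      loading, loading_cap))
  }
  Theta <- Theta + diag(loading, p)
  d <- sqrt(diag(Theta))
  achieved <- -Theta / outer(d, d)
  diag(achieved) <- 0
  latent <- stats::cov2cor(solve(Theta))
  dimnames(latent) <- dimnames(P)

  marg <- marginals %||%
    packaged_bprs_marginals()[rep_len(seq_len(18), p), , drop = FALSE]
  marg <- as.matrix(marg)
  rownames(marg) <- codes
  if (any(abs(rowSums(marg) - 1) > 1e-8)) {
    stop("each row of marginals must sum to 1")
  }

  structure(list(p = p, blocks = blocks, membership = membership,
                 precision = Theta, partial = achieved, target_partial = P,
                 latent_correlation = latent, item_codes = codes,
                 marginals = marg, loading = loading, seed = seed),
            class = "synthetic_spec")
}

#' Sample ordinal data from a synthetic specification
#'
#' Draws latent vectors from the zero-mean Gaussian with the specification's
#' latent correlation matrix and discretizes item i at the standard-normal
#' quantiles of its cumulative category probabilities -- exactly the data
#' model the polychoric estimator assumes. Deterministic given
#' \code{(spec, seed)}.
#'
#' @param spec a \code{synthetic_spec}
#' @param n number of subjects
#' @param seed RNG seed
#' @return a list of class \code{synthetic_dataset}: \code{data} (an
#'   \code{ordinal_matrix}), \code{spec}, \code{seed}
#' @export
sample_ordinal <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, spec$p), Sigma = spec$latent_correlation)
  K <- ncol(spec$marginals)
  X <- matrix(1L, n, spec$p, dimnames = list(NULL, spec$item_codes))
  for (j in seq_len(spec$p)) {
    cuts <- qnorm(cumsum(spec$marginals[j, ])[-K])
    X[, j] <- as.integer(findInterval(Z[, j], cuts) + 1L)
  }
  structure(list(data = ordinal_matrix(X, spec$item_codes, K),
                 spec = spec, seed = seed),
            class = "synthetic_dataset")
}

#' Synthetic-data writers
#'
#' The dataset is written in the same CSV dialect [load_responses()] reads;
#' the ground truth (achieved partial-correlation weights and block labels)
#' as JSON for test harnesses.
#'
#' @param ds a \code{synthetic_dataset}
#' @param spec a \code{synthetic_spec}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_synthetic_csv <- function(ds, path) {
  write.csv(as.data.frame(unclass(ds$data)), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_synthetic_csv
#' @export
write_truth_json <- function(spec, path) {
  jsonlite::write_json(
    list(item_codes = spec$item_codes,
         membership = unname(spec$membership),
         partial = apply(spec$partial, 1, as.numeric, simplify = FALSE),
         loading = spec$loading, seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
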