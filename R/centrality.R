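#' Node strength
#'
#' Sum of absolute edge weights at each node. Absolute values are used
#' because regularized partial-correlation networks contain negative edges.
#'
#' @param net a \code{sym_network} (or weight matrix)
#' @return named numeric vector
#' @export
strength <- function(net) {
  W <- if (inherits(net, "sym_network")) net$weights else as.matrix(net)
  rowSums(abs(W))
}

#' Closeness and betweenness on the weighted network
#'
#' Edges are given lengths \eqn{1/|w_{ij}|}; shortest paths are computed by
#' Dijkstra's algorithm. Closeness of node i is \eqn{(p-1)/\sum_j d(i,j)}
#' over the nodes reachable from i (its connected component; unreachable
#' nodes contribute nothing); the \code{"harmonic"} variant averages
#' \eqn{1/d(i,j)} instead. Betweenness is the Brandes path-counting
#' accumulation over all source-target pairs, with equal-length ties split
#' fractionally, halved for undirectedness and reported as unnormalized pair
#' counts. Isolated nodes score 0 on both.
#'
#' @param net a \code{sym_network} or weight matrix
#' @param closeness_variant \code{"reciprocal"} (default) or
#'   \code{"harmonic"}
#' @return list with \code{closeness}, \code{betweenness} (named vectors)
#'   and \code{component} (component id per node)
#' @export
shortest_path_metrics <- function(net,
                                  closeness_variant = c("reciprocal",
                                                        "harmonic")) {
  closeness_variant <- match.arg(closeness_variant)
  W <- if (inherits(net, "sym_network")) net$weights else as.matrix(net)
  p <- nrow(W)
  codes <- rownames(W) %||% paste0("V", seq_len(p))
  len <- ifelse(W != 0, 1 / abs(W), Inf)
  diag(len) <- Inf
  tol <- 1e-12

  closeness <- numeric(p)
  betweenness <- numeric(p)
  D <- matrix(Inf, p, p)

  for (s in seq_len(p)) {
    dist <- rep(Inf, p)
    dist[s] <- 0
    sigma <- numeric(p)
    sigma[s] <- 1
    preds <- vector("list", p)
    settled <- integer(0)
    visited <- rep(FALSE, p)
    repeat {
      cand <- which(!visited & is.finite(dist))
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      visited[v] <- TRUE
      settled <- c(settled, v)
      nb <- which(is.finite(len[v, ]))
      for (w in nb) {
        if (visited[w]) next
        alt <- dist[v] + len[v, w]
        if (alt < dist[w] - tol) {
          dist[w] <- alt
          sigma[w] <- sigma[v]
          preds[[w]] <- v
        } else if (abs(alt - dist[w]) <= tol) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    D[s, ] <- dist
    delta <- numeric(p)
    for (w in rev(settled)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
    }
    delta[s] <- 0
    betweenness <- betweenness + delta
  }
  betweenness <- betweenness / 2

  comp <- component_labels(is.finite(D))
  for (i in seq_len(p)) {
    reach <- which(is.finite(D[i, ]) & seq_len(p) != i)
    if (!length(reach)) {
      closeness[i] <- 0
    } else if (closeness_variant == "reciprocal") {
      closeness[i] <- (p - 1) / sum(D[i, reach])
    } else {
      closeness[i] <- sum(1 / D[i, reach]) / (p - 1)
    }
  }
  names(closeness) <- names(betweenness) <- codes
  list(closeness = closeness, betweenness = betweenness,
       component = setNames(comp, codes))
}

component_labels <- function(reachable) {
  p <- nrow(reachable)
  lab <- integer(p)
  nxt <- 1L
  for (i in seq_len(p)) {
    if (lab[i] == 0L) {
      lab[reachable[i, ]] <- nxt
      lab[i] <- nxt
      nxt <- nxt + 1L
    }
  }
  lab
}

#' Centrality table
#'
#' Assembles strength, closeness and betweenness with their z-standardized
#' versions ((x - mean)/SD over nodes) and the strength ranking. If a metric
#' is constant across nodes its z-scores are set to 0 with a warning.
#'
#' @param net a \code{sym_network}
#' @param closeness_variant passed to [shortest_path_metrics()]
#' @return data frame of class \code{centrality_table} with columns
#'   \code{node}, \code{strength}, \code{closeness}, \code{betweenness},
#'   \code{z_strength}, \code{z_closeness}, \code{z_betweenness},
#'   \code{rank_strength}
#' @export
centrality_table <- function(net, closeness_variant = "reciprocal") {
  s <- strength(net)
  sp <- shortest_path_metrics(net, closeness_variant)
  zscore <- function(x, label) {
    sdx <- sd(x)
    if (!is.finite(sdx) || sdx == 0) {
      warning(sprintf("%s is constant across nodes; z-scores set to 0",
                      label))
      return(rep(0, length(x)))
    }
    (x - mean(x)) / sdx
  }
  out <- data.frame(
    node = names(s),
    strength = unname(s),
    closeness = unname(sp$closeness),
    betweenness = unname(sp$betweenness),
    z_strength = zscore(unname(s), "strength"),
    z_closeness = zscore(unname(sp$closeness), "closeness"),
    z_betweenness = zscore(unname(sp$betweenness), "betweenness"),
    stringsAsFactors = FALSE
  )
  out$rank_strength <- rank(-out$strength, ties.method = "min")
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Write a centrality table as CSV
#' @param tab a \code{centrality_table}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_centrality_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
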