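# Independent oracles and fixture builders shared across the suite.

# random symmetric weight matrix with zero diagonal; weights in +/-[0.2, 0.8]
rand_weight_graph <- function(p, density = 0.5, seed = 1, negative = TRUE) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < density]
  w <- runif(length(on), 0.2, 0.8)
  if (negative) w <- w * sample(c(-1, 1), length(on), replace = TRUE)
  W[on] <- w
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  dimnames(W) <- list(paste0("V", 1:p), paste0("V", 1:p))
  W
}

# exhaustive shortest-path metrics by enumerating every simple path
brute_path_metrics <- function(W) {
  p <- nrow(W)
  len <- ifelse(W != 0, 1 / abs(W), Inf)
  diag(len) <- Inf
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, total) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- list(path = path, len = total)
        return()
      }
      for (w in which(is.finite(len[v, ]))) {
        if (!(w %in% path)) walk(c(path, w), total + len[v, w])
      }
    }
    walk(s, 0)
    out
  }
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  btw <- numeric(p)
  for (s in 1:(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths_between(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      D[s, t] <- D[t, s] <- dmin
      short <- ps[abs(lens - dmin) <= 1e-9]
      for (sp in short) {
        inner <- setdiff(sp$path, c(s, t))
        for (v in inner) btw[v] <- btw[v] + 1 / length(short)
      }
    }
  }
  clo <- vapply(1:p, function(i) {
    reach <- which(is.finite(D[i, ]) & seq_len(p) != i)
    if (!length(reach)) 0 else (p - 1) / sum(D[i, reach])
  }, numeric(1))
  list(closeness = clo, betweenness = btw, D = D)
}

# Potts Hamiltonian computed directly from its definition
brute_hamiltonian <- function(W, labels, gamma) {
  A <- abs(W)
  diag(A) <- 0
  s <- rowSums(A)
  m <- sum(A) / 2
  H <- 0
  p <- nrow(A)
  for (i in 1:(p - 1)) {
    for (j in (i + 1):p) {
      if (labels[i] == labels[j]) H <- H - (A[i, j] - gamma * s[i] * s[j] / (2 * m))
    }
  }
  unname(H)
}

# exhaustive Hamiltonian minimum over all labellings into at most q groups
brute_min_hamiltonian <- function(W, gamma, q) {
  p <- nrow(W)
  grid <- as.matrix(expand.grid(rep(list(seq_len(q)), p)))
  min(apply(grid, 1, function(lab) brute_hamiltonian(W, lab, gamma)))
}

# penalized graphical-lasso objective maximized by a generic optimizer over
# the free entries of a symmetric Theta (PD enforced by barrier)
brute_glasso <- function(S, lam, n_starts = 8, seed = 1) {
  p <- nrow(S)
  ut <- which(upper.tri(S))
  unpack <- function(par) {
    Th <- diag(par[seq_len(p)])
    Th[ut] <- par[-seq_len(p)]
    Th[lower.tri(Th)] <- t(Th)[lower.tri(Th)]
    Th
  }
  negobj <- function(par) {
    Th <- unpack(par)
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) return(1e10)
    -(sum(log(ev)) - sum(S * Th) - lam * 2 * sum(abs(Th[ut])))
  }
  set.seed(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    init <- if (k == 1) solve(S) else if (k == 2) diag(p) else {
      solve(S) + matrix(rnorm(p * p, sd = 0.05), p, p)
    }
    init <- (init + t(init)) / 2
    par0 <- c(diag(init), init[ut])
    for (rep in 1:4) {
      o <- optim(par0, negobj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
      par0 <- o$par
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  unpack(best$par)
}

# minimal two-group catalog for arbitrary p
make_test_catalog <- function(p, n1 = floor(p / 2), codes = paste0("V", 1:p)) {
  cat <- data.frame(code = codes, name = codes,
                    group = rep(c("DSM", "non-DSM"), c(n1, p - n1)),
                    stringsAsFactors = FALSE)
  class(cat) <- c("item_catalog", "data.frame")
  cat
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
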