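#' Spin-glass community detection
#'
#' Partitions the nodes by minimizing the configuration-null Potts
#' Hamiltonian
#' \deqn{H(\sigma) = -\sum_{i<j}\left(a_{ij} -
#'   \gamma\,\frac{s_i s_j}{2m}\right)\,\delta(\sigma_i,\sigma_j)}
#' on the absolute edge weights \eqn{a_{ij} = |w_{ij}|}, via Metropolis
#' simulated annealing: at each temperature \code{p * spins} single-node
#' label changes are proposed and accepted with probability
#' \eqn{\min(1, e^{-\Delta H/T})}; the temperature is multiplied by
#' \code{cooling} until it falls below \code{t_stop}. The best state visited
#' across \code{n_restart} independent restarts is returned, so the reported
#' Hamiltonian never exceeds that of any visited partition. Deterministic
#' given \code{seed}.
#'
#' @param net a \code{sym_network} (or weight matrix); must have at least
#'   one edge
#' @param gamma_spin resolution parameter of the null-model term
#' @param spins maximum number of communities
#' @param t_start,t_stop,cooling annealing schedule
#' @param seed RNG seed
#' @param n_restart independent annealing restarts (best Hamiltonian kept)
#' @return a list of class \code{community_partition}: \code{labels}
#'   (named, contiguous from 1), \code{n_communities}, \code{hamiltonian},
#'   \code{sizes}, \code{members}, plus the parameters
#' @export
spinglass_partition <- function(net, gamma_spin = 0.5, spins = 17L,
                                t_start = 1, t_stop = 0.01, cooling = 0.99,
                                seed = 2016L, n_restart = 10L) {
  W <- if (inherits(net, "sym_network")) net$weights else as.matrix(net)
  codes <- rownames(W) %||% paste0("V", seq_len(nrow(W)))
  A <- abs(W)
  diag(A) <- 0
  if (all(A == 0)) stop("no community structure estimable: network has no edges")
  stopifnot(cooling > 0, cooling < 1, t_stop < t_start, spins >= 1)
  set.seed(seed)
  res <- spinglass_anneal_cpp(A, gamma_spin, as.integer(spins), t_start,
                              t_stop, cooling, as.integer(n_restart))
  raw <- res$labels
  labels <- match(raw, unique(raw))  # contiguous, in order of appearance
  names(labels) <- codes
  members <- split(codes, labels)
  structure(list(labels = labels, n_communities = length(members),
                 hamiltonian = res$H, sizes = lengths(members),
                 members = members, gamma_spin = gamma_spin, spins = spins,
                 t_start = t_start, t_stop = t_stop, cooling = cooling,
                 seed = seed, n_restart = n_restart),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Spin-glass partition: %d communities, H = %.4f\n",
              x$n_communities, x$hamiltonian))
  for (k in seq_along(x$members)) {
    cat(sprintf("  [%d] %s\n", k, paste(x$members[[k]], collapse = " ")))
  }
  invisible(x)
}

#' Potts Hamiltonian of a labelling
#'
#' Public scoring function for the objective minimized by
#' [spinglass_partition()] (same absolute-weight convention).
#'
#' @param net a \code{sym_network} or weight matrix
#' @param labels integer community label per node
#' @param gamma_spin resolution parameter
#' @return the Hamiltonian value
#' @export
hamiltonian <- function(net, labels, gamma_spin = 0.5) {
  W <- if (inherits(net, "sym_network")) net$weights else as.matrix(net)
  A <- abs(W)
  diag(A) <- 0
  stopifnot(length(labels) == nrow(A))
  spinglass_hamiltonian_cpp(A, as.integer(labels), gamma_spin)
}

#' Partition writers
#'
#' CSV with columns \code{node}, \code{community}; JSON summary with sizes,
#' member codes and the final Hamiltonian.
#'
#' @param part a \code{community_partition}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_partition_csv <- function(part, path) {
  write.csv(data.frame(node = names(part$labels),
                       community = unname(part$labels)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
write_partition_json <- function(part, path) {
  jsonlite::write_json(
    list(n_communities = part$n_communities,
         sizes = unname(part$sizes),
         members = unname(part$members),
         hamiltonian = part$hamiltonian,
         gamma_spin = part$gamma_spin, seed = part$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
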