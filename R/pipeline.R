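#' Fruchterman-Reingold layout for a weighted network
#'
#' Force-directed placement: every node pair repels with force
#' \eqn{k^2/d}, every edge attracts with force \eqn{d^2/k} scaled by
#' \eqn{|w_{ij}|}, so strongly connected nodes end up closer together.
#' Displacements are capped by a temperature annealed linearly to zero over
#' the iterations. Final coordinates are rescaled to the unit square.
#' Deterministic given \code{seed}.
#'
#' @param net a \code{sym_network} or weight matrix
#' @param iterations number of iterations
#' @param seed RNG seed for the initial placement
#' @return a list of class \code{layout_result}: \code{coords} (p x 2, rows
#'   named by node), \code{iterations}, \code{seed}
#' @export
fr_layout <- function(net, iterations = 500, seed = 1) {
  W <- if (inherits(net, "sym_network")) net$weights else as.matrix(net)
  p <- nrow(W)
  codes <- rownames(W) %||% paste0("V", seq_len(p))
  if (p == 1) {
    coords <- matrix(0.5, 1, 2, dimnames = list(codes, c("x", "y")))
    return(structure(list(coords = coords, iterations = 0L, seed = seed),
                     class = "layout_result"))
  }
  set.seed(seed)
  pos <- matrix(runif(2 * p), p, 2)
  A <- abs(W)
  k <- sqrt(1 / p)
  for (it in seq_len(iterations)) {
    temp <- 0.1 * (iterations - it + 1) / iterations
    disp <- matrix(0, p, 2)
    for (i in seq_len(p)) {
      d <- sweep(pos, 2, pos[i, ])          # vectors from i to others
      dist <- sqrt(rowSums(d^2))
      dist[i] <- Inf
      dist <- pmax(dist, 1e-9)
      u <- d / dist
      # repulsion from all nodes, attraction along edges
      f <- -k^2 / dist + A[i, ] * dist^2 / k
      f[i] <- 0
      disp[i, ] <- colSums(u * f)
    }
    mag <- pmax(sqrt(rowSums(disp^2)), 1e-12)
    step <- pmin(mag, temp)
    pos <- pos + disp / mag * step
  }
  rng <- apply(pos, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  coords <- sweep(sweep(pos, 2, rng[1, ]), 2, span, "/")
  dimnames(coords) <- list(codes, c("x", "y"))
  structure(list(coords = coords, iterations = iterations, seed = seed),
            class = "layout_result")
}

#' Run the full symptom-network pipeline
#'
#' Orchestrates data loading, polychoric correlation, EBIC graphical lasso,
#' centrality, spin-glass communities, layout, and (optionally) stability,
#' bootstrap and the group-centrality permutation test, producing a
#' machine-readable run report and, when \code{output_dir} is given, the
#' artifact files (edge list TSV, centrality CSV, partition CSV, layout TSV,
#' report JSON). A failure aborts with the stage name and removes partial
#' artifacts. Reruns with identical config and seeds reproduce the report
#' exactly (the \code{timings} field aside).
#'
#' @param input CSV path or an \code{ordinal_matrix}
#' @param catalog an \code{item_catalog}
#' @param config a [pipeline_config()]
#' @param output_dir directory for artifacts (created if needed); NULL
#'   writes nothing
#' @param stability run [case_drop_stability()] (with \code{grid},
#'   \code{B_per} below)
#' @param bootstrap run [nonparametric_bootstrap()] with \code{B} samples
#' @param permutation run the group permutation test on strength,
#'   closeness and betweenness
#' @param grid,B_per,B resampling sizes
#' @param seed master seed; stage seeds are derived from it
#' @param top_k edges listed in the report
#' @return a list of class \code{run_report}
#' @export
run_pipeline <- function(input, catalog = bprs_catalog(),
                         config = pipeline_config(), output_dir = NULL,
                         stability = FALSE, bootstrap = FALSE,
                         permutation = TRUE,
                         grid = seq(0.10, 0.75, by = 0.05), B_per = 100,
                         B = 1000, seed = 1, top_k = 10) {
  timings <- list()
  written <- character(0)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      unlink(written)
      stop_stage(stage, conditionMessage(e))
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("stage %-12s %8.2fs", stage, timings[[stage]]))
    res
  }

  data <- tick("load", {
    if (inherits(input, "ordinal_matrix")) input
    else load_responses(input, catalog)
  })
  p <- ncol(data)
  pc <- tick("polychoric", polychoric_matrix(data))
  net <- tick("network", estimate_network(
    pc, n = nrow(data), gamma_ebic = config$gamma_ebic,
    n_lambda = config$n_lambda,
    lambda_min_ratio = config$lambda_min_ratio))
  cent <- tick("centrality", centrality_table(net, config$closeness_variant))
  part <- tick("communities", spinglass_partition(net, seed = seed + 1))
  lay <- tick("layout", fr_layout(net, seed = seed + 2))

  stab <- boot <- perm <- NULL
  if (stability) {
    stab <- tick("stability", case_drop_stability(
      data, config, grid = grid, B_per = B_per, seed = seed + 3))
  }
  if (bootstrap) {
    boot <- tick("bootstrap", nonparametric_bootstrap(
      data, config, B = B, seed = seed + 4, diff_pairs = FALSE))
  }
  if (permutation) {
    perm <- tick("permutation", {
      lapply(setNames(c("strength", "closeness", "betweenness"),
                      c("strength", "closeness", "betweenness")),
             function(idx) {
               group_centrality_permutation(
                 setNames(cent[[idx]], cent$node), catalog, seed = seed + 5)
             })
    })
  }

  possible <- p * (p - 1) / 2
  el <- edge_list(net)
  report <- list(
    package_version = as.character(packageVersion("bprsnet")),
    config = c(unclass(config), list(seed = seed, K = attr(data, "K"))),
    n_subjects = nrow(data), n_items = p,
    possible_edges = possible, n_edges = net$n_edges,
    edge_fraction_pct = round_half_up(100 * net$n_edges / possible, 1),
    selected_lambda = net$lambda,
    top_edges = utils::head(el, top_k),
    centrality = as.data.frame(cent),
    communities = list(labels = as.list(part$labels),
                       sizes = unname(part$sizes),
                       hamiltonian = part$hamiltonian),
    permutation = if (!is.null(perm)) {
      lapply(perm, function(x) {
        list(observed = x$observed, p_value = x$p_value, mode = x$mode)
      })
    },
    stability = if (!is.null(stab)) {
      list(cs = as.list(stab$cs), interpretable = as.list(stab$interpretable))
    },
    bootstrap = if (!is.null(boot)) {
      list(B = boot$B, failures = boot$failures)
    }
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(output_dir, f)
    written <- c(write_edge_list(net, fp("edges.tsv")),
                 write_centrality_csv(cent, fp("centrality.csv")),
                 write_partition_csv(part, fp("partition.csv")))
    lt <- data.frame(node = rownames(lay$coords), lay$coords)
    utils::write.table(lt, fp("layout.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, fp("layout.tsv"))
    if (!is.null(stab)) written <- c(written,
                                     write_stability_json(stab, fp("stability.json")))
    jsonlite::write_json(c(report, list(timings = timings)),
                         fp("report.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    written <- c(written, fp("report.json"))
  }

  structure(c(report, list(network = net, partition = part, layout = lay,
                           stability_result = stab, bootstrap_result = boot,
                           permutation_result = perm, timings = timings)),
            class = "run_report")
}

#' Validate a run report against the shipped schema
#'
#' The schema (inst/schema/report_schema.json) lists the required top-level
#' fields and their JSON types; this checks a report list or report.json
#' file against it.
#'
#' @param report a \code{run_report}, a list parsed from report.json, or a
#'   path to one
#' @return TRUE invisibly; errors describe the first violation
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::fromJSON(report)
  schema <- jsonlite::fromJSON(system.file("schema", "report_schema.json",
                                           package = "bprsnet"))
  for (field in schema$required) {
    if (is.null(report[[field]])) stop("report missing field: ", field)
  }
  num_fields <- c("n_subjects", "n_items", "possible_edges", "n_edges",
                  "edge_fraction_pct")
  for (field in num_fields) {
    if (!is.numeric(report[[field]])) {
      stop("report field not numeric: ", field)
    }
  }
  invisible(TRUE)
}

#' Plot a symptom network
#'
#' Best-effort figure: nodes at a Fruchterman-Reingold layout, positive
#' edges green, negative edges red, line width proportional to
#' \eqn{|w_{ij}|}.
#'
#' @param x a \code{sym_network}
#' @param layout a \code{layout_result} (computed if missing)
#' @param ... passed to \code{plot.default}
#' @return the layout, invisibly
#' @export
plot.sym_network <- function(x, layout = NULL, ...) {
  lay <- layout %||% fr_layout(x)
  xy <- lay$coords
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-0.08, 1.08), ylim = c(-0.08, 1.08), asp = 1, ...)
  el <- edge_list(x)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      graphics::segments(xy[el$node_i[e], 1], xy[el$node_i[e], 2],
                         xy[el$node_j[e], 1], xy[el$node_j[e], 2],
                         col = if (el$weight[e] > 0) "forestgreen" else "firebrick",
                         lwd = 6 * abs(el$weight[e]))
    }
  }
  graphics::points(xy, pch = 21, bg = "grey90", cex = 3)
  graphics::text(xy, labels = rownames(xy), cex = 0.6)
  invisible(lay)
}
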