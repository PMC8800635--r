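# Random walk with restart on the confidence-weighted protein network.

#' Random-walk-with-restart parameters
#'
#' @param restart_prob Restart probability r in (0, 1]; default 0.75.
#' @param tolerance L1 convergence tolerance of the iterative solver
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @param solver `"iterative"` (power iteration) or `"direct"` (dense linear
#'   solve).
#' @return List of class `rwr_params`.
#' @export
rwr_params <- function(restart_prob = 0.75, tolerance = 1e-10,
                       max_iter = 10000L, solver = c("iterative", "direct")) {
  restart_prob <- assert_real(restart_prob, "restart_prob")
  if (restart_prob <= 0 || restart_prob > 1)
    hp_stop("'restart_prob' must lie in (0, 1]")
  structure(list(restart_prob = restart_prob,
                 tolerance = assert_real(tolerance, "tolerance", lo = 0),
                 max_iter = assert_count(max_iter, "max_iter"),
                 solver = match.arg(solver)),
            class = "rwr_params")
}

# Column-normalized confidence-weighted adjacency over `nodes`.
# Zero-degree columns become absorbing self-loops so that probability mass is
# conserved for isolated seed nodes.
transition_matrix <- function(net, nodes) {
  n <- length(nodes)
  e <- net$edges[net$edges$protein_a %in% nodes &
                   net$edges$protein_b %in% nodes, , drop = FALSE]
  ia <- match(e$protein_a, nodes); ib <- match(e$protein_b, nodes)
  a <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = c(e$confidence, e$confidence),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  deg <- Matrix::colSums(a)
  isolated <- which(deg == 0)
  if (length(isolated) > 0L) {
    a <- a + Matrix::sparseMatrix(i = isolated, j = isolated,
                                  x = rep(1, length(isolated)),
                                  dims = c(n, n))
    deg[isolated] <- 1
  }
  a %*% Matrix::Diagonal(n, 1 / deg)
}

#' Propagate seed probability over the network by random walk with restart
#'
#' Solves the stationary equation `p = (1 - r) W p + r q`, where `W` is the
#' column-normalized confidence-weighted adjacency of the connected
#' component(s) containing seeds and `q` is uniform over the seeds present in
#' the network. Nodes outside seed-containing components receive probability
#' 0, so the returned vector sums to 1 (within tolerance).
#'
#' @param net A [ppin()].
#' @param seeds Character vector of seed gene symbols; at least one must be a
#'   network node.
#' @param params An [rwr_params()] object.
#' @return Named numeric vector of stable probabilities over all network
#'   nodes.
#' @export
rwr_propagate <- function(net, seeds, params = rwr_params()) {
  stopifnot(inherits(net, "ppin"))
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, net$nodes)
  if (length(present) == 0L)
    hp_stop("none of the %d seed(s) are network nodes", length(seeds))
  # restrict to connected components that contain a seed
  g <- igraph::graph_from_data_frame(net$edges[, c("protein_a", "protein_b")],
                                     directed = FALSE, vertices = net$nodes)
  comp <- igraph::components(g)$membership
  keep_comp <- unique(comp[present])
  nodes <- names(comp)[comp %in% keep_comp]
  isolated_seeds <- present[igraph::degree(g)[present] == 0]
  if (length(isolated_seeds) > 0L)
    message(sprintf("rwr_propagate: %d isolated seed node(s) act as absorbing states",
                    length(isolated_seeds)))
  w <- transition_matrix(net, nodes)
  r <- params$restart_prob
  q <- stats::setNames(numeric(length(nodes)), nodes)
  q[present] <- 1 / length(present)
  p <- if (params$solver == "direct") {
    m <- diag(length(nodes)) - (1 - r) * as.matrix(w)
    as.numeric(solve(m, r * q))
  } else {
    p0 <- q
    converged <- FALSE
    for (i in seq_len(params$max_iter)) {
      p1 <- as.numeric((1 - r) * (w %*% p0)) + r * q
      if (sum(abs(p1 - p0)) < params$tolerance) { converged <- TRUE; p0 <- p1; break }
      p0 <- p1
    }
    if (!converged)
      hp_stop("rwr_propagate did not converge in %d iterations (L1 change %.3g)",
              params$max_iter, sum(abs(p1 - p0)))
    p0
  }
  out <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  out[nodes] <- p
  out
}

#' Pair-level RWR proximity of herb targets to disease genes
#'
#' Propagates from the disease genes (uniform seeds) and sums the stable
#' probabilities over the union of the two herbs' targets that exist in the
#' network; absent targets contribute 0.
#'
#' @param net A [ppin()].
#' @param disease A [disease_context()].
#' @param profile_a,profile_b [herb_profile()] objects for the two herbs.
#' @param params An [rwr_params()].
#' @param propagated Optional precomputed result of [rwr_propagate()] for the
#'   disease seeds (used by [featurize_pairs()] to avoid recomputation).
#' @return The summed stable probability, in `[0, 1]`.
#' @export
rwr_pair_score <- function(net, disease, profile_a, profile_b,
                           params = rwr_params(), propagated = NULL) {
  if (is.null(propagated))
    propagated <- rwr_propagate(net, disease$disease_genes, params)
  targets <- union(profile_a$targets, profile_b$targets)
  sum(propagated[intersect(targets, names(propagated))])
}
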