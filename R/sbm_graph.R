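#' Multigraph container for stochastic block modelling
#'
#' An undirected multigraph on `n` nodes, optionally edge-weighted and
#' partitioned into layers.  Parallel edges are allowed (a directed graph is
#' encoded by giving each orientation its own parallel edge); self-loops are
#' not.  This is the input type of [description_length()] and [fit_sbm()].
#'
#' @param n Number of nodes.
#' @param edges Two-column integer matrix of endpoints (1-based).
#' @param weights Optional numeric edge weights (length = edge count).
#' @param layers Optional integer layer label per edge in `1..n_layers`.
#' @param n_layers Number of layers (default 1).
#' @param layer_names Optional character names for the layers.
#' @param binom_trials Number of trials K when weights are binomial shared
#'   counts (integer weights in `0..K`).
#' @param node_names Optional node names.
#' @return Object of class `sbm_graph`.
#' @export
sbm_graph <- function(n, edges, weights = NULL, layers = NULL,
                      n_layers = 1L, layer_names = NULL,
                      binom_trials = NULL, node_names = NULL) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  m <- nrow(edges)
  if (m > 0) {
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not supported")
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != m) stop("weights length must equal edge count")
  }
  if (is.null(layers)) {
    layers <- rep(1L, m)
  } else {
    layers <- as.integer(layers)
    if (length(layers) != m) stop("layers length must equal edge count")
    if (m > 0 && (any(layers < 1L) || any(layers > n_layers))) {
      stop("layer label outside 1..n_layers")
    }
  }
  if (!is.null(node_names) && length(node_names) != n) {
    stop("node_names length must equal n")
  }
  structure(list(n = as.integer(n), edges = edges, weights = weights,
                 layers = layers, n_layers = as.integer(n_layers),
                 layer_names = layer_names, binom_trials = binom_trials,
                 node_names = node_names),
            class = "sbm_graph")
}

#' Coerce to an `sbm_graph`
#'
#' @param x An `igraph` object (undirected; edge attribute `weight` kept)
#'   or a 2/3-column edge-list data.frame/matrix (`from`, `to`, optional
#'   `weight`).
#' @param ... Passed to [sbm_graph()].
#' @return An `sbm_graph`.
#' @export
as_sbm_graph <- function(x, ...) {
  if (inherits(x, "sbm_graph")) return(x)
  if (inherits(x, "igraph")) {
    el <- igraph::as_edgelist(x, names = FALSE)
    w <- if ("weight" %in% igraph::edge_attr_names(x)) {
      igraph::E(x)$weight
    } else NULL
    return(sbm_graph(igraph::vcount(x), el, weights = w,
                     node_names = if ("name" %in% igraph::vertex_attr_names(x))
                       igraph::V(x)$name else NULL, ...))
  }
  x <- as.matrix(x)
  w <- if (ncol(x) >= 3) as.numeric(x[, 3]) else NULL
  sbm_graph(max(x[, 1:2]), x[, 1:2, drop = FALSE], weights = w, ...)
}

#' @export
print.sbm_graph <- function(x, ...) {
  cat("sbm_graph:", x$n, "nodes,", nrow(x$edges), "edges,",
      x$n_layers, "layer(s),",
      if (is.null(x$weights)) "unweighted" else "weighted", "\n")
  invisible(x)
}

#' Sample a planted-partition (assortative) graph
#'
#' Simple undirected graph: nodes split evenly into `B` planted blocks,
#' within-block pairs connected with probability `p_in`, between-block
#' pairs with `p_out`.
#'
#' @param n Nodes.
#' @param B Planted blocks.
#' @param p_in,p_out Within/between connection probabilities.
#' @param seed RNG seed.
#' @return List with `graph` (an `sbm_graph`) and `truth` (block labels).
#' @export
sample_ppm <- function(n, B, p_in, p_out, seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  truth <- sort(rep(seq_len(B), length.out = n))
  pr <- utils::combn(n, 2)
  same <- truth[pr[1, ]] == truth[pr[2, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pr)) < p
  list(graph = sbm_graph(n, t(pr[, keep, drop = FALSE])),
       truth = truth)
}

#' Sample a planted two-layer graph
#'
#' Shared planted bipartition; layer 1 holds assortative (within-block)
#' edges, layer 2 disassortative (between-block) edges, so the layer labels
#' carry real structure that a layered block model can exploit and a
#' layer-shuffled null cannot.
#'
#' @param n Nodes (even).
#' @param p_in Within-block probability for layer 1.
#' @param p_out Between-block probability for layer 2.
#' @param seed RNG seed.
#' @return List with `graph` (2-layer `sbm_graph`) and `truth`.
#' @export
sample_layered_planted <- function(n, p_in = 0.5, p_out = 0.5, seed = 1) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  truth <- rep(1:2, each = n / 2)
  pr <- utils::combn(n, 2)
  same <- truth[pr[1, ]] == truth[pr[2, ]]
  k1 <- same & stats::runif(ncol(pr)) < p_in
  k2 <- !same & stats::runif(ncol(pr)) < p_out
  edges <- rbind(t(pr[, k1, drop = FALSE]), t(pr[, k2, drop = FALSE]))
  list(graph = sbm_graph(n, edges,
                         layers = c(rep(1L, sum(k1)), rep(2L, sum(k2))),
                         n_layers = 2L),
       truth = truth)
}
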