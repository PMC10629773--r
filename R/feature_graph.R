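#' Directed conditional-probability graph of genetic features
#'
#' For features a, b the directed weight is the Bayes-rule conditional
#' probability W\[a,b\] = P(a present | b present), estimated pairwise-
#' complete: counts are restricted to patients in whom both features were
#' assayed.  The sampling layer S\[a,b\] is the fraction of patients with
#' both domains assayed, and I\[a,b\] = P(a and b) the intersection
#' probability on the same denominator.  With N nodes the number of
#' possible directed edges is 2*choose(N,2), both orientations of each pair.
#'
#' The Bayes identity W\[a,b\] p(b) = W\[b,a\] p(a) = I\[a,b\] holds exactly
#' on the counts (p(.) the marginal presence probability among co-assayed
#' patients).  Pairs whose denominator is zero (the conditioning feature
#' never present among co-assayed patients) get weight 0 and are flagged in
#' `zero_denominator`, keeping the node set fixed for block modelling.
#'
#' @param barcode A `feature_barcode` from [fractionate_features()].
#' @return Object of class `conditional_graph`: list with `nodes`,
#'   `domains`, matrices `W` (directed conditional), `S` (co-assay
#'   fraction), `I` (intersection), `C` (co-assayed counts), `J` (joint
#'   presence counts), `zero_denominator`, and `n_patients`.  Diagonals are
#'   zeroed (no self-loops).
#' @export
conditional_probability_graph <- function(barcode) {
  stopifnot(inherits(barcode, "feature_barcode"))
  X <- barcode$X
  if (nrow(X) < 1) stop("empty barcode")
  M <- !is.na(X)                      # assayed mask
  A <- X; A[!M] <- 0L                 # presence among assayed
  storage.mode(A) <- "double"; storage.mode(M) <- "double"
  C <- crossprod(M)                   # co-assayed counts
  J <- crossprod(A)                   # both present
  D <- crossprod(M, A)                # D[a,b] = # (a assayed, b present)
  W <- ifelse(D > 0, J / D, 0)
  I <- ifelse(C > 0, J / C, 0)
  S <- C / nrow(X)
  zd <- D == 0
  diag(W) <- 0; diag(S) <- 0; diag(I) <- 0; diag(zd) <- FALSE
  structure(list(nodes = barcode$features, domains = barcode$domains,
                 W = W, S = S, I = I, C = C, J = J,
                 zero_denominator = zd, n_patients = nrow(X)),
            class = "conditional_graph")
}

#' Histogram and variance of nonzero edge weights
#'
#' Used to compare the spread of conditional-probability weights against
#' intersection weights: conditional weights carry far greater variance,
#' which motivates using them for the directed graph.
#'
#' @param graph A `conditional_graph`.
#' @param which `"conditional"` (directed W, off-diagonal) or
#'   `"intersection"` (upper triangle of I).
#' @param breaks Passed to [graphics::hist()] binning via [base::cut()];
#'   default 20 equal bins on \[0,1\].
#' @return List with `weights` (nonzero), `counts` (binned), `mids`,
#'   and `variance`.
#' @export
edge_weight_histogram <- function(graph, which = c("conditional",
                                                   "intersection"),
                                  breaks = seq(0, 1, length.out = 21)) {
  which <- match.arg(which)
  stopifnot(inherits(graph, "conditional_graph"))
  M <- if (which == "conditional") graph$W else graph$I
  w <- if (which == "conditional") {
    M[row(M) != col(M) & M > 0]
  } else {
    M[upper.tri(M) & M > 0]
  }
  cuts <- cut(w, breaks = breaks, include.lowest = TRUE)
  list(weights = w, counts = as.integer(table(cuts)),
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       # population variance: the two-point set {0.2, 0.8} has variance 0.09
       variance = if (length(w)) mean((w - mean(w))^2) else 0)
}

#' Min-max rescale weights into \[0, 1\]
#'
#' Affine map sending the minimum to 0 and the maximum to 1; a constant
#' vector maps to all zeros with a warning (the stated convention).
#'
#' @param values Nonempty numeric vector.
#' @return Rescaled vector.
#' @export
rescale_weights <- function(values) {
  if (!length(values)) stop("empty weight vector")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("constant weights rescaled to 0")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Weighted centralities of the directed conditional graph
#'
#' Eigenvector, hub and authority centralities are computed on the directed
#' weighted adjacency by power iteration (tolerance 1e-10, at most 10000
#' iterations, uniform start vector); pagerank and betweenness via igraph.
#' Betweenness uses the distance transform d = -log(w) floored at 1e-12 so
#' that higher conditional probability means a shorter path.  On a
#' disconnected graph the path-based measures are computed per component
#' (igraph's convention) and the spectral ones on the full matrix.
#'
#' @param graph A `conditional_graph`, or a plain weighted adjacency matrix.
#' @return data.frame: node, eigenvector, hub, authority, betweenness,
#'   pagerank.
#' @export
weighted_centralities <- function(graph) {
  W <- if (inherits(graph, "conditional_graph")) graph$W else as.matrix(graph)
  if (nrow(W) < 2) stop("need at least 2 nodes")
  nodes <- rownames(W)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(W)))
  mode <- if (isSymmetric(unname(W))) "undirected" else "directed"
  ig <- igraph::graph_from_adjacency_matrix(W, mode = mode,
                                            weighted = TRUE, diag = FALSE)
  dist_w <- pmax(-log(igraph::E(ig)$weight), 1e-12)
  # shortest paths are invariant under positive scaling; normalizing by the
  # minimum keeps the floored distances away from igraph's epsilon
  dist_w <- dist_w / min(dist_w)
  data.frame(
    node = nodes,
    eigenvector = power_iteration(W + t(W)),
    hub = power_iteration(W %*% t(W)),
    authority = power_iteration(t(W) %*% W),
    betweenness = igraph::betweenness(ig, weights = dist_w),
    pagerank = igraph::page_rank(ig, weights = igraph::E(ig)$weight)$vector,
    row.names = NULL, stringsAsFactors = FALSE)
}

# Leading-eigenvector scores of a nonnegative matrix by power iteration;
# uniform start, max-norm normalization, deterministic.
power_iteration <- function(M, tol = 1e-10, max_iter = 10000) {
  n <- nrow(M)
  v <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(M %*% v)
    m <- max(abs(v2))
    if (m == 0) return(rep(0, n))
    v2 <- v2 / m
    if (max(abs(v2 - v)) < tol) {
      v <- v2
      break
    }
    v <- v2
  }
  v / max(v)
}

#' One-way ANOVA of a node metric across coarse genetic domains
#'
#' @param values Numeric per-node metric.
#' @param groups Factor/character of the node's coarse domain.
#' @return List with `F`, `p`, `df` and the full `anova` table.
#' @export
group_anova <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  tab <- table(groups)
  if (any(tab == 0)) {
    warning("dropping empty groups")
    keep <- groups %in% names(tab)[tab > 0]
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2 || length(values) < 2) {
    stop("need >= 2 groups and >= 2 observations")
  }
  # Identical values everywhere: no between-group signal by definition;
  # report F = 0, p = 1 rather than the 0/0 the ANOVA table would produce.
  if (max(abs(values - values[1])) <= 1e-12 * (1 + abs(values[1]))) {
    k <- length(unique(groups))
    return(list(F = 0, p = 1, df = c(k - 1, length(values) - k),
                anova = NULL))
  }
  fit <- stats::aov(values ~ factor(groups))
  an <- stats::anova(fit)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], df = an$Df,
       anova = an)
}

#' Raw structural diagnostics of a weighted graph
#'
#' Diameter of the unweighted topology (longest shortest path over nonzero
#' edges, largest component, undirected) and the random-walk mixing time
#' tau = 1/(1 - lambda_2) from the spectral gap of the transition matrix
#' P = D^-1 W on the symmetrized weights.  These are the raw statistics; no
#' z-scoring against an external network corpus is performed.
#'
#' @param graph A `conditional_graph` or adjacency matrix.
#' @return List with `diameter` and `mixing_time`.
#' @export
graph_diagnostics <- function(graph) {
  W <- if (inherits(graph, "conditional_graph")) graph$W else as.matrix(graph)
  Wsym <- (W + t(W)) / 2
  ig <- igraph::graph_from_adjacency_matrix(Wsym > 0, mode = "undirected")
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  diam <- igraph::diameter(igraph::induced_subgraph(ig, keep),
                           weights = NA)
  Ws <- Wsym[keep, keep, drop = FALSE]
  d <- rowSums(Ws)
  d[d == 0] <- 1
  # P = D^-1 W is similar to the symmetric D^-1/2 W D^-1/2: real spectrum.
  Sm <- diag(1 / sqrt(d)) %*% Ws %*% diag(1 / sqrt(d))
  ev <- sort(eigen(Sm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  lambda2 <- if (length(ev) > 1) ev[2] else 0
  list(diameter = diam,
       mixing_time = if (lambda2 < 1) 1 / (1 - lambda2) else Inf)
}

#' Assemble the two-layer feature multigraph for block modelling
#'
#' Layer 1 ("conditional") carries one undirected parallel edge per ordered
#' feature pair with nonzero conditional weight (so each unordered pair can
#' contribute two edges, one per orientation); layer 2 ("sampling") one edge
#' per unordered pair with nonzero co-assay frequency.  Both layers' weights
#' are min-max rescaled into \[0, 1\] so their distributions are comparable
#' for model fitting.
#'
#' @param graph A `conditional_graph`.
#' @return An [sbm_graph()] with `n_layers = 2` and layer labels
#'   `c("conditional", "sampling")`.
#' @export
feature_layered_graph <- function(graph) {
  stopifnot(inherits(graph, "conditional_graph"))
  W <- graph$W; S <- graph$S
  idx <- which(W > 0, arr.ind = TRUE)           # ordered pairs a|b
  e1 <- cbind(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]))
  w1 <- W[idx]
  iu <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  e2 <- cbind(iu[, 1], iu[, 2])
  w2 <- S[iu]
  sbm_graph(n = length(graph$nodes),
            edges = rbind(e1, e2),
            weights = c(rescale_weights(w1), rescale_weights(w2)),
            layers = c(rep(1L, nrow(e1)), rep(2L, nrow(e2))),
            n_layers = 2L,
            layer_names = c("conditional", "sampling"),
            node_names = graph$nodes)
}

#' Export a conditional graph as a weighted edge list (TSV)
#'
#' Columns: src, dst, conditional_w, sampling_w; one row per directed edge
#' with nonzero conditional weight.
#'
#' @param graph A `conditional_graph`.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "conditional_graph"))
  idx <- which(graph$W > 0, arr.ind = TRUE)
  df <- data.frame(src = graph$nodes[idx[, 1]],
                   dst = graph$nodes[idx[, 2]],
                   conditional_w = graph$W[idx],
                   sampling_w = graph$S[idx],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a conditional graph as GraphML
#' @param graph A `conditional_graph`.
#' @param path Output path.
#' @export
write_feature_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "conditional_graph"))
  ig <- igraph::graph_from_adjacency_matrix(graph$W, mode = "directed",
                                            weighted = TRUE, diag = FALSE)
  igraph::V(ig)$name <- graph$nodes
  igraph::V(ig)$domain <- graph$domains
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
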