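#' Description length of a microcanonical stochastic block model
#'
#' Computes the description length Sigma = -ln P(data, partition) in nats of
#' an undirected multigraph under the nonparametric microcanonical
#' stochastic block model, for flat or nested hierarchies, with or without
#' degree correction, with independent layers, and with optional edge
#' covariates under conjugate marginal likelihoods.  Every term below is
#' implemented in a dedicated internal function and unit-tested against
#' hand evaluation.
#'
#' With `N` nodes, blocks `b` (sizes `n_r`, count `B`), inter-block edge
#' counts `e_rs` (diagonal counted twice) and degree sequence `k`, the terms
#' are, per layer:
#'
#' * adjacency (plain):
#'   `-sum_{r<s} ln e_rs! - sum_r ln e_rr!! + sum_r e_r ln n_r + sum_{i<j} ln A_ij!`
#'   with `(2m)!! = 2^m m!` and `e_r = sum_s e_rs`;
#' * adjacency (degree-corrected):
#'   `-sum_{r<s} ln e_rs! - sum_r ln e_rr!! + sum_r ln e_r! - sum_i ln k_i! + sum_{i<j} ln A_ij!`
#'   plus the uniform degree prior `sum_r ln multiset(n_r, e_r)`, where
#'   `multiset(n, m) = choose(n + m - 1, m)`;
#' * edge covariates, summed over block pairs `r <= s` with `m` edges and
#'   weight sums `Sx`, `Sx2`: the negative log marginal likelihood under
#'   - exponential: rate with Gamma(1, 1) prior,
#'     `-ln Gamma(m + 1) + (m + 1) ln(1 + Sx)`;
#'   - normal: unknown mean/variance with normal-inverse-gamma prior
#'     (mu0 = 0, kappa0 = 1, alpha0 = 1, beta0 = 1);
#'   - binomial (K trials): success probability with Beta(1, 1) prior,
#'     `-sum_e ln C(K, x_e) - ln B(Sx + 1, mK - Sx + 1) + ln(mK + 1)`
#'     written via log-gammas.
#'
#' Each level `l >= 1` of the hierarchy prices the previous level's block
#' multigraph uniformly given its own grouping (sizes `m_R`, aggregated
#' counts `E_RS`):
#' `sum_{R<S} ln multiset(m_R m_S, E_RS) + sum_R ln multiset(m_R (m_R+1)/2, E_RR / 2)`,
#' and every level adds the partition prior
#' `ln N_l + ln choose(N_l - 1, B_l - 1) + ln N_l! - sum_r ln n_r!`.
#' The top level always has a single block.  A layered graph contributes
#' one adjacency/degree/covariate/multigraph term per layer (partitions are
#' shared across layers) plus a uniform composition prior
#' `ln choose(E + C - 1, C - 1)` over the split of the `E` edges among the
#' `C` layers.
#'
#' @param graph An [sbm_graph()] (or anything [as_sbm_graph()] accepts).
#' @param levels Hierarchy memberships: either a single integer membership
#'   vector (a flat model; the forced single-block top level is appended
#'   automatically) or a list of membership vectors from level 0 upwards,
#'   the last of which must assign everything to one block.
#' @param degree_corrected Condition on the observed degree sequence.
#' @param weight_model One of `"none"`, `"normal"`, `"exponential"`,
#'   `"binomial"`.
#' @param binom_trials Trials K for the binomial model (defaults to the
#'   graph's `binom_trials`).
#' @param parts Return the named term breakdown instead of the total.
#' @return Sigma in nats (or a named numeric of terms when `parts = TRUE`).
#' @export
description_length <- function(graph, levels, degree_corrected = FALSE,
                               weight_model = c("none", "normal",
                                                "exponential", "binomial"),
                               binom_trials = NULL, parts = FALSE) {
  graph <- as_sbm_graph(graph)
  weight_model <- match.arg(weight_model)
  if (is.null(binom_trials)) binom_trials <- graph$binom_trials
  levels <- normalize_levels(levels, graph$n)
  check_weight_model(graph, weight_model, binom_trials)

  b0 <- levels[[1]]
  B0 <- max(b0)
  nr <- tabulate(b0, B0)
  out <- c(partition_dl(b0))
  names(out)[length(out)] <- "partition_L0"

  E_list <- vector("list", graph$n_layers)
  for (l in seq_len(graph$n_layers)) {
    idx <- which(graph$layers == l)
    E <- block_edge_matrix(graph$edges[idx, , drop = FALSE], b0, B0)
    E_list[[l]] <- E
    k <- node_degrees(graph, l)
    out[paste0("adjacency_layer", l)] <-
      adjacency_dl(E, nr, k, degree_corrected) +
      multiplicity_const(graph$edges[idx, , drop = FALSE])
    if (degree_corrected) {
      out[paste0("degree_prior_layer", l)] <- degree_prior_dl(E, nr)
    }
    if (weight_model != "none") {
      st <- weight_stats(graph, l, b0, B0)
      wdl <- weight_dl(st$m, st$s1, st$s2, weight_model, binom_trials)
      if (weight_model == "binomial" && length(idx)) {
        wdl <- wdl - sum(lchoose(binom_trials, graph$weights[idx]))
      }
      out[paste0("weights_layer", l)] <- wdl
    }
  }
  if (graph$n_layers > 1) {
    out["layer_composition"] <-
      lchoose(nrow(graph$edges) + graph$n_layers - 1, graph$n_layers - 1)
  }
  for (h in seq_along(levels)[-1]) {
    c_h <- levels[[h]]
    out[paste0("partition_L", h - 1)] <- partition_dl(c_h)
    tot <- 0
    for (l in seq_len(graph$n_layers)) {
      res <- multigraph_dl(E_list[[l]], c_h)
      tot <- tot + res$dl
      E_list[[l]] <- res$E
    }
    out[paste0("multigraph_L", h - 1)] <- tot
  }
  if (parts) out else sum(out)
}

# --- hierarchy plumbing -----------------------------------------------------

normalize_levels <- function(levels, n) {
  if (!is.list(levels)) levels <- list(as.integer(levels))
  levels <- lapply(levels, as.integer)
  if (length(levels[[1]]) != n) {
    stop("level-0 membership must have one entry per node")
  }
  for (h in seq_along(levels)) {
    b <- levels[[h]]
    B <- max(b)
    if (any(b < 1L) || !all(seq_len(B) %in% b)) {
      stop("memberships must be surjective onto 1..B (level ", h - 1, ")")
    }
    if (h > 1 && length(b) != max(levels[[h - 1]])) {
      stop("level ", h - 1, " must partition the blocks of the level below")
    }
  }
  top_B <- max(levels[[length(levels)]])
  if (top_B != 1L) {
    levels <- c(levels, list(rep(1L, top_B)))
  }
  levels
}

# Block-pair edge count matrix with the diagonal counted twice.
block_edge_matrix <- function(edges, b, B) {
  if (!nrow(edges)) return(matrix(0, B, B))
  r <- b[edges[, 1]]; s <- b[edges[, 2]]
  matrix(tabulate(c((r - 1) * B + s, (s - 1) * B + r), nbins = B * B), B, B)
}

node_degrees <- function(graph, layer) {
  idx <- which(graph$layers == layer)
  tabulate(c(graph$edges[idx, 1], graph$edges[idx, 2]), graph$n)
}

# sum_{i<j} ln A_ij! for parallel edges (0 for simple graphs).
multiplicity_const <- function(edges) {
  if (!nrow(edges)) return(0)
  key <- paste(edges[, 1], edges[, 2])
  sum(lgamma(table(key) + 1))
}

# Per-block-pair weight sufficient statistics (m, sum, sum of squares),
# matrices with the diagonal doubled like block_edge_matrix.
weight_stats <- function(graph, layer, b, B) {
  idx <- which(graph$layers == layer)
  m <- matrix(0, B, B); s1 <- matrix(0, B, B); s2 <- matrix(0, B, B)
  if (length(idx)) {
    r <- b[graph$edges[idx, 1]]; s <- b[graph$edges[idx, 2]]
    w <- graph$weights[idx]
    key <- c((r - 1) * B + s, (s - 1) * B + r)
    m <- matrix(tabulate(key, nbins = B * B), B, B)
    acc1 <- rowsum(c(w, w), key)
    acc2 <- rowsum(c(w^2, w^2), key)
    s1[as.integer(rownames(acc1))] <- acc1
    s2[as.integer(rownames(acc2))] <- acc2
  }
  list(m = m, s1 = s1, s2 = s2)
}

# --- description-length terms ----------------------------------------------

ln_multiset <- function(n, m) lchoose(n + m - 1, m)

# -ln P(b): uniform over B, then compositions, then labelled partitions.
partition_dl <- function(b) {
  N <- length(b)
  B <- max(b)
  nr <- tabulate(b, B)
  log(N) + lchoose(N - 1, B - 1) + lgamma(N + 1) - sum(lgamma(nr + 1))
}

# -ln P(A | e, b) (+ degree terms when degree-corrected), excluding the
# parallel-edge multiplicity constant.
adjacency_dl <- function(E, nr, k, degree_corrected) {
  er <- rowSums(E)
  diag_half <- diag(E) / 2
  s <- -(sum(lgamma(E[upper.tri(E)] + 1)) +
           sum(diag_half * log(2) + lgamma(diag_half + 1)))
  if (degree_corrected) {
    s + sum(lgamma(er + 1)) - sum(lgamma(k + 1))
  } else {
    s + sum(er * log(nr))
  }
}

# Uniform prior on the degree sequence within each block.
degree_prior_dl <- function(E, nr) {
  sum(ln_multiset(nr, rowSums(E)))
}

# One nested level: uniform multigraphs given the coarser grouping.
multigraph_dl <- function(E_prev, c_h) {
  B <- max(c_h)
  mR <- tabulate(c_h, B)
  G <- rowsum(t(rowsum(E_prev, c_h, reorder = TRUE)), c_h, reorder = TRUE)
  dl <- sum(ln_multiset(outer(mR, mR)[upper.tri(G)], G[upper.tri(G)])) +
    sum(ln_multiset(mR * (mR + 1) / 2, diag(G) / 2))
  list(dl = dl, E = G)
}

# Negative log marginal likelihoods of the edge-covariate models, from the
# per-pair sufficient statistics (matrices with doubled diagonal).
weight_dl <- function(m, s1, s2, model, K = NULL) {
  up <- upper.tri(m)
  mm <- c(m[up], diag(m) / 2)
  ss1 <- c(s1[up], diag(s1) / 2)
  ss2 <- c(s2[up], diag(s2) / 2)
  sum(neg_ln_ml(mm, ss1, ss2, model, K))
}

neg_ln_ml <- function(m, s1, s2, model, K = NULL) {
  out <- numeric(length(m))
  pos <- m > 0
  if (!any(pos)) return(out)
  m <- m[pos]; s1 <- s1[pos]; s2 <- s2[pos]
  out[pos] <- switch(
    model,
    exponential = -lgamma(m + 1) + (m + 1) * log1p(s1),
    normal = {
      k0 <- 1; a0 <- 1; b0 <- 1
      xbar <- s1 / m
      kn <- k0 + m
      an <- a0 + m / 2
      bn <- b0 + pmax(s2 - m * xbar^2, 0) / 2 + k0 * m * xbar^2 / (2 * kn)
      -(-(m / 2) * log(2 * pi) + 0.5 * log(k0 / kn) +
          lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn))
    },
    binomial = {
      if (is.null(K)) stop("binomial weight model needs binom_trials")
      -(lgamma(s1 + 1) + lgamma(m * K - s1 + 1) - lgamma(m * K + 2))
    },
    stop("unknown weight model"))
  out
}

check_weight_model <- function(graph, weight_model, binom_trials) {
  if (weight_model == "none") return(invisible(TRUE))
  if (is.null(graph$weights)) {
    stop("weight model '", weight_model, "' requested but graph has no weights")
  }
  if (weight_model == "exponential" && any(graph$weights < 0)) {
    stop("exponential weight model requires nonnegative weights")
  }
  if (weight_model == "binomial") {
    if (is.null(binom_trials)) stop("binomial weight model needs binom_trials")
    w <- graph$weights
    if (any(w != round(w)) || any(w < 0) || any(w > binom_trials)) {
      stop("binomial weights must be integers in 0..K")
    }
  }
  invisible(TRUE)
}
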