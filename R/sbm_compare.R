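#' Posterior odds between two fitted hypotheses
#'
#' Given description lengths `sigma_a` and `sigma_b` of hypotheses H_a and
#' H_b (for example a layer-respecting model versus a layer-shuffled null),
#' the posterior odds ratio is `Lambda = exp(-(sigma_a - sigma_b)) *
#' P(H_a)/P(H_b)`.  Reported in log space: the odds themselves routinely
#' overflow double precision.
#'
#' @param sigma_a,sigma_b Description lengths in nats (finite).
#' @param prior_a,prior_b Prior hypothesis probabilities (default equal).
#' @return List with `delta` (sigma_a - sigma_b), `log_odds` (natural log
#'   of Lambda) and `odds` (exp of it; may overflow to Inf).
#' @export
posterior_odds <- function(sigma_a, sigma_b, prior_a = 0.5, prior_b = 0.5) {
  stopifnot(is.finite(sigma_a), is.finite(sigma_b),
            prior_a > 0, prior_b > 0)
  delta <- sigma_a - sigma_b
  log_odds <- -delta + log(prior_a) - log(prior_b)
  list(delta = delta, log_odds = log_odds, odds = exp(log_odds))
}

#' Permutation nulls of a (layered) weighted graph
#'
#' `mode = "edge_weights"` shuffles the weight vector across edges within
#' each layer, keeping the topology and layer structure; the weight
#' multiset per layer is conserved.  `mode = "layer_membership"` permutes
#' the layer labels across edges, so edges are randomly interspersed across
#' layers while per-layer edge totals are conserved exactly.
#'
#' @param graph An [sbm_graph()].
#' @param mode Which feature to permute.
#' @param seed RNG seed.
#' @return A permuted `sbm_graph`.
#' @export
permute_null <- function(graph, mode = c("edge_weights",
                                         "layer_membership"),
                         seed = 1) {
  graph <- as_sbm_graph(graph)
  mode <- match.arg(mode)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  m <- nrow(graph$edges)
  if (mode == "edge_weights") {
    if (is.null(graph$weights)) stop("graph has no weights to permute")
    if (m <= 1) {
      warning("fewer than two edges: weight permutation is the identity")
      return(graph)
    }
    w <- graph$weights
    for (l in seq_len(graph$n_layers)) {
      idx <- which(graph$layers == l)
      if (length(idx) > 1) w[idx] <- sample(w[idx])
    }
    graph$weights <- w
  } else {
    if (graph$n_layers < 2) stop("layer shuffle needs a layered graph")
    graph$layers <- graph$layers[sample.int(m)]
  }
  graph
}

#' Model selection over SBM variants by description length
#'
#' Fits every combination of the requested degree-correction, nesting and
#' weight-model choices with a shared seed schedule and returns the
#' candidate attaining the minimum description length together with the
#' full Sigma table.
#'
#' @param graph An [sbm_graph()].
#' @param degree_corrected Candidate settings (logical vector).
#' @param nested Candidate settings (logical vector).
#' @param weight_models Candidate weight models.
#' @param seed Shared base seed.
#' @param ... Passed to [fit_sbm()].
#' @return List with `best` (a `block_hierarchy`), `best_options` and
#'   `table` (data.frame of candidates and sigmas).
#' @export
select_model <- function(graph, degree_corrected = c(FALSE, TRUE),
                         nested = c(FALSE, TRUE),
                         weight_models = "none", seed = 1, ...) {
  graph <- as_sbm_graph(graph)
  grid <- expand.grid(dc = degree_corrected, nested = nested,
                      wm = weight_models, stringsAsFactors = FALSE)
  if (nrow(grid) < 1) stop("empty candidate grid")
  fits <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fits[[g]] <- fit_sbm(graph, degree_corrected = grid$dc[g],
                         nested = grid$nested[g],
                         weight_model = grid$wm[g], seed = seed, ...)
  }
  sig <- vapply(fits, function(f) f$sigma, numeric(1))
  tab <- data.frame(degree_corrected = grid$dc, nested = grid$nested,
                    weight_model = grid$wm, sigma = sig,
                    stringsAsFactors = FALSE)
  best <- which.min(sig)
  list(best = fits[[best]],
       best_options = as.list(grid[best, , drop = FALSE]),
       table = tab)
}

#' Exhaustive description-length minimum over all flat partitions
#'
#' Enumerates every partition of the node set (restricted growth strings;
#' Bell(8) = 4140 for eight nodes) and evaluates the flat-model description
#' length of each, providing the global-optimum oracle against which the
#' MCMC search is validated on small graphs.
#'
#' @param graph An [sbm_graph()] with at most `max_n` nodes.
#' @param degree_corrected,weight_model,binom_trials As in
#'   [description_length()].
#' @param max_n Safety cap on the exhaustive enumeration (default 10).
#' @return List with `sigma` (the minimum), `membership` (an argmin,
#'   ties broken toward fewer blocks) and `n_partitions`.
#' @export
exhaustive_minimum_dl <- function(graph, degree_corrected = FALSE,
                                  weight_model = "none",
                                  binom_trials = NULL, max_n = 10) {
  graph <- as_sbm_graph(graph)
  n <- graph$n
  if (n > max_n) stop("exhaustive enumeration capped at ", max_n, " nodes")
  parts <- enumerate_partitions(n)
  best_sigma <- Inf
  best_b <- NULL
  best_B <- Inf
  count <- 0L
  for (b in parts) {
    count <- count + 1L
    s <- description_length(graph, b, degree_corrected = degree_corrected,
                            weight_model = weight_model,
                            binom_trials = binom_trials)
    B <- max(b)
    if (s < best_sigma - 1e-12 ||
        (abs(s - best_sigma) <= 1e-12 && B < best_B)) {
      best_sigma <- s
      best_b <- b
      best_B <- B
    }
  }
  list(sigma = best_sigma, membership = best_b, n_partitions = count)
}

#' Enumerate all set partitions of n items
#'
#' Partitions are produced as restricted growth strings: membership vectors
#' `b` with `b[1] = 1` and `b[i] <= max(b[1..i-1]) + 1`.
#'
#' @param n Number of items (Bell numbers grow fast; keep n small).
#' @return List of integer membership vectors.
#' @export
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(b, i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- b
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) {
      b[i] <- v
      rec(b, i + 1L, max(mx, v))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}
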