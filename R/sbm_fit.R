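#' Fit a stochastic block model by MCMC description-length minimization
#'
#' Minimizes the microcanonical description length (see
#' [description_length()]) over node partitions with single-node
#' Metropolis-Hastings moves.  The chain is initialized from singletons
#' collapsed by greedy agglomerative sweeps (merging nodes into
#' neighbouring blocks while the description length falls), then proceeds
#' with stochastic sweeps: each sweep proposes one move per node in a
#' seeded random order, drawing the target block from a random neighbour's
#' block mixed with a uniform block (including a fresh block) at rate
#' `eps = 0.1`, and accepting with probability `min(1, exp(-delta Sigma))`.
#' No burn-in is used: the chain starts from the state the initialization
#' itself generates, and the best (record) state seen is returned.  The
#' chain stops once `patience` sweeps pass without a new record (a
#' record-breaking stopping rule).
#'
#' With `nested = TRUE` the hierarchy is grown greedily: after the flat
#' fit, the block multigraph is recursively partitioned (same machinery,
#' multigraph likelihood) while the total description length falls, the top
#' level is forced to a single block, and a bounded refinement pass revisits
#' the node-level memberships under the full hierarchy.
#'
#' @param graph An [sbm_graph()] (layered graphs fit all layers with shared
#'   partitions) or anything [as_sbm_graph()] accepts.
#' @param degree_corrected Condition on observed degrees.
#' @param weight_model Edge-covariate model (see [description_length()]).
#' @param nested Grow a hierarchy of levels above the node partition.
#' @param binom_trials Trials K for the binomial weight model.
#' @param seed Integer seed controlling all randomness.
#' @param patience Sweeps without a new minimum before stopping (default
#'   100).
#' @param max_sweeps Hard cap on sweeps per level (safety bound).
#' @param eps Uniform-proposal mixing rate.
#' @return Object of class `block_hierarchy`: `levels` (memberships from
#'   the node level upward, ending in a single block), `B` (block counts),
#'   `sigma` (description length, nats), `options`, `trace` (record sigma
#'   per sweep) and `n`.
#' @export
fit_sbm <- function(graph, degree_corrected = FALSE,
                    weight_model = c("none", "normal", "exponential",
                                     "binomial"),
                    nested = FALSE, binom_trials = NULL, seed = 1,
                    patience = 100, max_sweeps = 3000, eps = 0.1) {
  graph <- as_sbm_graph(graph)
  weight_model <- match.arg(weight_model)
  if (is.null(binom_trials)) binom_trials <- graph$binom_trials
  check_weight_model(graph, weight_model, binom_trials)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  cache <- sbm_cache(graph, seq_len(graph$n), degree_corrected,
                     weight_model, binom_trials)
  greedy_sweeps(cache)
  merge_down(cache)
  trace <- mcmc_sweeps(cache, patience = patience, max_sweeps = max_sweeps,
                       eps = eps)
  greedy_merge_pass(cache)
  restore_best(cache)
  levels <- list(compact_membership(cache$best_b))

  if (nested) {
    levels <- grow_hierarchy(cache, levels, graph)
    refine_base_level(cache, levels, patience = max(10, patience %/% 2))
    levels[[1]] <- compact_membership(cache$best_b)
  }
  finalize_hierarchy(graph, levels, degree_corrected, weight_model,
                     binom_trials, nested, trace)
}

#' Fit a layered stochastic block model
#'
#' Thin wrapper over [fit_sbm()] asserting a genuinely layered input
#' (at least two layers over one shared node set).  Per-layer edge-count
#' matrices enter the description length; partitions are shared.
#'
#' @inheritParams fit_sbm
#' @param layered A layered [sbm_graph()] (`n_layers >= 2`).
#' @return A `block_hierarchy`.
#' @export
fit_layered_sbm <- function(layered, degree_corrected = FALSE,
                            weight_model = c("none", "normal",
                                             "exponential", "binomial"),
                            nested = FALSE, binom_trials = NULL, seed = 1,
                            patience = 100, max_sweeps = 3000, eps = 0.1) {
  layered <- as_sbm_graph(layered)
  if (layered$n_layers < 2) stop("layered fit needs >= 2 layers")
  fit_sbm(layered, degree_corrected = degree_corrected,
          weight_model = weight_model, nested = nested,
          binom_trials = binom_trials, seed = seed, patience = patience,
          max_sweeps = max_sweeps, eps = eps)
}

#' Composed node membership at a hierarchy level
#'
#' Level 1 is the first grouping of nodes; level `l` composes the first `l`
#' membership vectors, assigning each node its block at that level.
#'
#' @param hierarchy A `block_hierarchy`.
#' @param level Level index (1-based; up to `length(hierarchy$levels)`).
#' @return Integer membership vector over the nodes.
#' @export
hierarchy_membership <- function(hierarchy, level = 1) {
  stopifnot(inherits(hierarchy, "block_hierarchy"),
            level >= 1, level <= length(hierarchy$levels))
  b <- hierarchy$levels[[1]]
  for (h in seq_len(level)[-1]) b <- hierarchy$levels[[h]][b]
  b
}

#' @export
print.block_hierarchy <- function(x, ...) {
  cat("block_hierarchy:", x$n, "nodes; block counts",
      paste(x$B, collapse = " -> "), "\n")
  cat("  sigma =", format(x$sigma, digits = 10), "nats;",
      if (x$options$degree_corrected) "degree-corrected;" else "plain;",
      "weights:", x$options$weight_model,
      if (x$options$nested) "; nested" else "", "\n")
  invisible(x)
}

#' Serialize a hierarchy to JSON
#' @param hierarchy A `block_hierarchy`.
#' @param path Output path.
#' @export
write_hierarchy_json <- function(hierarchy, path) {
  jsonlite::write_json(
    list(levels = hierarchy$levels, B = hierarchy$B,
         sigma = hierarchy$sigma, options = hierarchy$options,
         n = hierarchy$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- internal state ---------------------------------------------------------

# Mutable fitting state held in an environment.  Matrices follow the
# doubled-diagonal convention of sbm_dl.R; `upper` optionally holds fixed
# upper-level memberships during refinement.
sbm_cache <- function(graph, b, degree_corrected, weight_model,
                      binom_trials) {
  env <- new.env(parent = emptyenv())
  env$graph <- graph
  env$dc <- degree_corrected
  env$wm <- weight_model
  env$K <- binom_trials
  env$b <- as.integer(b)
  env$B <- max(env$b)
  env$nr <- tabulate(env$b, env$B)
  env$upper <- NULL
  L <- graph$n_layers
  env$E <- vector("list", L)
  env$S1 <- vector("list", L)
  env$S2 <- vector("list", L)
  env$k <- vector("list", L)
  env$const <- 0
  for (l in seq_len(L)) {
    idx <- which(graph$layers == l)
    ed <- graph$edges[idx, , drop = FALSE]
    env$E[[l]] <- block_edge_matrix(ed, env$b, env$B)
    env$k[[l]] <- node_degrees(graph, l)
    env$const <- env$const + multiplicity_const(ed)
    if (weight_model != "none") {
      st <- weight_stats(graph, l, env$b, env$B)
      env$S1[[l]] <- st$s1
      env$S2[[l]] <- st$s2
      if (weight_model == "binomial" && length(idx)) {
        env$const <- env$const - sum(lchoose(binom_trials,
                                             graph$weights[idx]))
      }
    }
    if (degree_corrected) {
      env$const <- env$const - sum(lgamma(env$k[[l]] + 1))
    }
  }
  if (L > 1) {
    env$const <- env$const + lchoose(nrow(graph$edges) + L - 1, L - 1)
  }
  # adjacency lists: per node, the incident edge endpoints/layers/weights
  m <- nrow(graph$edges)
  nbr <- c(graph$edges[, 2], graph$edges[, 1])
  own <- c(graph$edges[, 1], graph$edges[, 2])
  lay <- c(graph$layers, graph$layers)
  wts <- if (is.null(graph$weights)) rep(1, 2 * m) else
    c(graph$weights, graph$weights)
  ord <- order(own)
  env$adj_nbr <- nbr[ord]
  env$adj_lay <- lay[ord]
  env$adj_w <- wts[ord]
  cnt <- tabulate(own, graph$n)
  env$adj_ptr <- c(0L, cumsum(cnt))  # node i: (ptr[i]+1):ptr[i+1]
  env$sigma <- cache_sigma(env)
  env$best_sigma <- env$sigma
  env$best_b <- env$b
  env
}

node_neighbours <- function(cache, i) {
  lo <- cache$adj_ptr[i] + 1L
  hi <- cache$adj_ptr[i + 1L]
  if (lo > hi) return(NULL)
  list(nbr = cache$adj_nbr[lo:hi], lay = cache$adj_lay[lo:hi],
       w = cache$adj_w[lo:hi])
}

# Full description length from the cached block-level statistics; identical
# term functions to description_length(), so fit sigma is self-consistent.
cache_sigma <- function(cache) {
  # evaluate on the compacted partition: a transiently empty block must not
  # contribute to the priors
  nz <- which(cache$nr > 0L)
  sub <- function(M) if (length(nz) == nrow(M)) M else
    M[nz, nz, drop = FALSE]
  sigma_from_stats(
    N = length(cache$b), nr = cache$nr[nz],
    E_list = lapply(cache$E, sub),
    S1_list = if (cache$wm == "none") NULL else lapply(cache$S1, sub),
    S2_list = if (cache$wm == "none") NULL else lapply(cache$S2, sub),
    dc = cache$dc, wm = cache$wm, K = cache$K, const = cache$const,
    upper = cache$upper)
}

# Description length from block-level sufficient statistics alone.
sigma_from_stats <- function(N, nr, E_list, S1_list, S2_list, dc, wm, K,
                             const, upper = NULL) {
  s <- partition_dl_sizes(N, nr) + const
  for (l in seq_along(E_list)) {
    E <- E_list[[l]]
    er <- rowSums(E)
    dh <- diag(E) / 2
    s <- s - (sum(lgamma(E[upper.tri(E)] + 1)) +
                sum(dh * log(2) + lgamma(dh + 1)))
    if (dc) {
      s <- s + sum(lgamma(er + 1)) + sum(ln_multiset(nr, er))
    } else {
      s <- s + sum(er * log(nr))
    }
    if (wm != "none") {
      s <- s + weight_dl(E, S1_list[[l]], S2_list[[l]], wm, K)
    }
  }
  if (is.null(upper)) upper <- list(rep(1L, length(nr)))
  for (c_h in upper) {
    s <- s + partition_dl(c_h)
    for (l in seq_along(E_list)) {
      res <- multigraph_dl(E_list[[l]], c_h)
      s <- s + res$dl
      E_list[[l]] <- res$E
    }
  }
  s
}

# Sigma of the partition obtained by merging block r into block s, computed
# by folding the cached block-level matrices (no per-edge work).
merge_sigma <- function(cache, r, s) {
  fold <- function(M) {
    M[s, ] <- M[s, ] + M[r, ]
    M[, s] <- M[, s] + M[, r]
    M[-r, -r, drop = FALSE]
  }
  nr <- cache$nr
  nr[s] <- nr[s] + nr[r]
  sigma_from_stats(
    N = length(cache$b), nr = nr[-r],
    E_list = lapply(cache$E, fold),
    S1_list = if (cache$wm == "none") NULL else lapply(cache$S1, fold),
    S2_list = if (cache$wm == "none") NULL else lapply(cache$S2, fold),
    dc = cache$dc, wm = cache$wm, K = cache$K, const = cache$const,
    upper = NULL)
}

apply_merge <- function(cache, r, s, new_sigma) {
  fold <- function(M) {
    M[s, ] <- M[s, ] + M[r, ]
    M[, s] <- M[, s] + M[, r]
    M[-r, -r, drop = FALSE]
  }
  cache$nr[s] <- cache$nr[s] + cache$nr[r]
  cache$nr <- cache$nr[-r]
  for (l in seq_along(cache$E)) {
    cache$E[[l]] <- fold(cache$E[[l]])
    if (cache$wm != "none") {
      cache$S1[[l]] <- fold(cache$S1[[l]])
      cache$S2[[l]] <- fold(cache$S2[[l]])
    }
  }
  b <- cache$b
  b[b == r] <- s
  b[b > r] <- b[b > r] - 1L
  cache$b <- b
  cache$B <- cache$B - 1L
  cache$sigma <- new_sigma
  if (new_sigma < cache$best_sigma - 1e-12) {
    cache$best_sigma <- new_sigma
    cache$best_b <- cache$b
  }
  invisible(cache)
}

# Candidate merge pairs: all when B is small, otherwise connected pairs.
merge_candidates <- function(cache, max_pairs = 600) {
  B <- cache$B
  if (B * (B - 1) / 2 <= max_pairs) {
    pr <- which(upper.tri(matrix(0, B, B)), arr.ind = TRUE)
  } else {
    Esum <- Reduce(`+`, cache$E)
    pr <- which(upper.tri(Esum) & Esum > 0, arr.ind = TRUE)
    if (nrow(pr) > max_pairs) pr <- pr[sample.int(nrow(pr), max_pairs), ]
  }
  pr
}

# Agglomerative exploration: repeatedly apply the best available merge all
# the way to a single block, recording every state passed; the best state
# seen is restored afterwards.  Escapes the over-split local minima that
# single-node moves cannot leave.
merge_down <- function(cache) {
  while (cache$B > 1L) {
    pr <- merge_candidates(cache)
    if (!nrow(pr)) break
    sig <- vapply(seq_len(nrow(pr)), function(x) {
      merge_sigma(cache, pr[x, 2], pr[x, 1])
    }, numeric(1))
    j <- which.min(sig)
    apply_merge(cache, pr[j, 2], pr[j, 1], sig[j])
  }
  restore_best(cache)
}

# Final polish: apply improving merges only, until none exists.
greedy_merge_pass <- function(cache) {
  repeat {
    if (cache$B <= 1L) break
    pr <- merge_candidates(cache)
    if (!nrow(pr)) break
    sig <- vapply(seq_len(nrow(pr)), function(x) {
      merge_sigma(cache, pr[x, 2], pr[x, 1])
    }, numeric(1))
    j <- which.min(sig)
    if (sig[j] < cache$sigma - 1e-12) {
      apply_merge(cache, pr[j, 2], pr[j, 1], sig[j])
    } else break
  }
  invisible(cache)
}

partition_dl_sizes <- function(N, nr) {
  B <- length(nr)
  log(N) + lchoose(N - 1, B - 1) + lgamma(N + 1) - sum(lgamma(nr + 1))
}

# Move node i to block s (possibly B+1 for a fresh block); mutates cache and
# returns the assignments needed to revert.
apply_move <- function(cache, i, s) {
  r <- cache$b[i]
  if (s == cache$B + 1L) {
    cache$B <- cache$B + 1L
    cache$nr <- c(cache$nr, 0L)
    for (l in seq_along(cache$E)) {
      cache$E[[l]] <- rbind(cbind(cache$E[[l]], 0), 0)
      if (cache$wm != "none") {
        cache$S1[[l]] <- rbind(cbind(cache$S1[[l]], 0), 0)
        cache$S2[[l]] <- rbind(cbind(cache$S2[[l]], 0), 0)
      }
    }
  }
  nb <- node_neighbours(cache, i)
  if (!is.null(nb)) {
    B <- cache$B
    for (l in unique(nb$lay)) {
      sel <- nb$lay == l
      q <- cache$b[nb$nbr[sel]]
      t_cnt <- tabulate(q, B)
      E <- cache$E[[l]]
      E[r, ] <- E[r, ] - t_cnt; E[, r] <- E[, r] - t_cnt
      E[s, ] <- E[s, ] + t_cnt; E[, s] <- E[, s] + t_cnt
      cache$E[[l]] <- E
      if (cache$wm != "none") {
        w <- nb$w[sel]
        tw1 <- numeric(B); tw2 <- numeric(B)
        acc <- rowsum(w, q)
        tw1[as.integer(rownames(acc))] <- acc
        acc2 <- rowsum(w^2, q)
        tw2[as.integer(rownames(acc2))] <- acc2
        S1 <- cache$S1[[l]]
        S1[r, ] <- S1[r, ] - tw1; S1[, r] <- S1[, r] - tw1
        S1[s, ] <- S1[s, ] + tw1; S1[, s] <- S1[, s] + tw1
        cache$S1[[l]] <- S1
        S2 <- cache$S2[[l]]
        S2[r, ] <- S2[r, ] - tw2; S2[, r] <- S2[, r] - tw2
        S2[s, ] <- S2[s, ] + tw2; S2[, s] <- S2[, s] + tw2
        cache$S2[[l]] <- S2
      }
    }
  }
  cache$b[i] <- s
  cache$nr[r] <- cache$nr[r] - 1L
  cache$nr[s] <- cache$nr[s] + 1L
  r
}

# Drop empty blocks by swapping them with the last label.
compact_cache <- function(cache) {
  while (any(cache$nr == 0L)) {
    r <- which(cache$nr == 0L)[1]
    B <- cache$B
    if (r != B) {
      cache$b[cache$b == B] <- r
      cache$nr[r] <- cache$nr[B]
      for (l in seq_along(cache$E)) {
        cache$E[[l]][c(r, B), ] <- cache$E[[l]][c(B, r), ]
        cache$E[[l]][, c(r, B)] <- cache$E[[l]][, c(B, r)]
        if (cache$wm != "none") {
          cache$S1[[l]][c(r, B), ] <- cache$S1[[l]][c(B, r), ]
          cache$S1[[l]][, c(r, B)] <- cache$S1[[l]][, c(B, r)]
          cache$S2[[l]][c(r, B), ] <- cache$S2[[l]][c(B, r), ]
          cache$S2[[l]][, c(r, B)] <- cache$S2[[l]][, c(B, r)]
        }
      }
    }
    cache$nr <- cache$nr[-B]
    for (l in seq_along(cache$E)) {
      cache$E[[l]] <- cache$E[[l]][-B, -B, drop = FALSE]
      if (cache$wm != "none") {
        cache$S1[[l]] <- cache$S1[[l]][-B, -B, drop = FALSE]
        cache$S2[[l]] <- cache$S2[[l]][-B, -B, drop = FALSE]
      }
    }
    cache$B <- B - 1L
  }
  invisible(cache)
}

# Try moving node i to block s; keep it when `keep(delta)` says so.
# Returns the delta actually realized (0 if reverted).
try_move <- function(cache, i, s, keep) {
  r <- cache$b[i]
  if (s == r) return(0)
  if (!is.null(cache$upper) && (cache$nr[r] == 1L || s > cache$B)) {
    return(0)  # block counts frozen while upper levels are fixed
  }
  apply_move(cache, i, s)
  new_sigma <- cache_sigma(cache)
  delta <- new_sigma - cache$sigma
  if (keep(delta)) {
    cache$sigma <- new_sigma
    if (cache$nr[r] == 0L) compact_cache(cache)
    if (new_sigma < cache$best_sigma - 1e-12) {
      cache$best_sigma <- new_sigma
      cache$best_b <- cache$b
    }
    delta
  } else {
    apply_move(cache, i, s <- r)  # revert
    if (cache$nr[cache$B] == 0L) compact_cache(cache)
    0
  }
}

# Greedy agglomerative collapse from the current state: each node is moved
# to the best of (a sample of) its neighbours' blocks whenever that lowers
# sigma; repeated until no move improves.
greedy_sweeps <- function(cache, max_pass = 25, n_cand = 10) {
  n <- length(cache$b)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in sample.int(n)) {
      nb <- node_neighbours(cache, i)
      if (is.null(nb)) next
      cand <- unique(cache$b[nb$nbr])
      cand <- setdiff(cand, cache$b[i])
      if (length(cand) > n_cand) {
        wsum <- rowsum(abs(nb$w) + 1e-9, cache$b[nb$nbr])
        pool <- as.integer(rownames(wsum))
        keep <- pool != cache$b[i]
        cand <- sample(pool[keep], n_cand, prob = wsum[keep])
      }
      if (!length(cand)) next
      best_s <- 0L; best_d <- 0
      for (s in cand) {
        d <- peek_move(cache, i, s)
        if (d < best_d - 1e-12) { best_d <- d; best_s <- s }
      }
      if (best_s > 0L) {
        try_move(cache, i, best_s, function(delta) TRUE)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  invisible(cache)
}

# Delta sigma of a candidate move without keeping it.
peek_move <- function(cache, i, s) {
  r <- cache$b[i]
  if (s == r || s > cache$B) return(0)
  apply_move(cache, i, s)
  d <- cache_sigma(cache) - cache$sigma
  apply_move(cache, i, r)
  d
}

# Metropolis-Hastings sweeps with record-breaking stopping.
mcmc_sweeps <- function(cache, patience = 100, max_sweeps = 3000,
                        eps = 0.1) {
  n <- length(cache$b)
  since_record <- 0L
  trace <- numeric(0)
  metropolis <- function(delta) delta < 0 || stats::runif(1) < exp(-delta)
  for (sweep in seq_len(max_sweeps)) {
    record_before <- cache$best_sigma
    for (i in sample.int(n)) {
      if (stats::runif(1) < eps) {
        s <- sample.int(min(cache$B + 1L, n), 1L)
      } else {
        nb <- node_neighbours(cache, i)
        if (is.null(nb)) {
          s <- sample.int(cache$B, 1L)
        } else {
          j <- if (length(nb$nbr) == 1L) nb$nbr else
            sample(nb$nbr, 1L, prob = abs(nb$w) + 1e-9)
          s <- cache$b[j]
        }
      }
      try_move(cache, i, s, metropolis)
    }
    trace <- c(trace, cache$best_sigma)
    if (cache$best_sigma < record_before - 1e-12) {
      since_record <- 0L
    } else {
      since_record <- since_record + 1L
    }
    if (since_record >= patience) break
  }
  # leave the cache on the best state seen
  restore_best(cache)
  data.frame(sweep = seq_along(trace), sigma_best = trace)
}

restore_best <- function(cache) {
  if (!identical(cache$b, cache$best_b)) {
    reset_cache_membership(cache, cache$best_b)
  }
  invisible(cache)
}

reset_cache_membership <- function(cache, b) {
  b <- as.integer(b)
  cache$b <- b
  cache$B <- max(b)
  cache$nr <- tabulate(b, cache$B)
  for (l in seq_along(cache$E)) {
    idx <- which(cache$graph$layers == l)
    ed <- cache$graph$edges[idx, , drop = FALSE]
    cache$E[[l]] <- block_edge_matrix(ed, b, cache$B)
    if (cache$wm != "none") {
      st <- weight_stats(cache$graph, l, b, cache$B)
      cache$S1[[l]] <- st$s1
      cache$S2[[l]] <- st$s2
    }
  }
  cache$sigma <- cache_sigma(cache)
  if (cache$sigma <= cache$best_sigma + 1e-12) {
    cache$best_sigma <- cache$sigma
    cache$best_b <- cache$b
  }
  invisible(cache)
}

compact_membership <- function(b) {
  as.integer(factor(b, levels = unique(b)[order(unique(b))]))
}

# --- nested hierarchy -------------------------------------------------------

# Grow levels above the flat fit while the total description length falls.
grow_hierarchy <- function(cache, levels, graph) {
  E_list <- lapply(seq_len(graph$n_layers), function(l) {
    idx <- which(graph$layers == l)
    block_edge_matrix(graph$edges[idx, , drop = FALSE], levels[[1]],
                      max(levels[[1]]))
  })
  M <- max(levels[[1]])
  repeat {
    if (M <= 1L) break
    close_now <- log(M) + sum(vapply(E_list, function(E) {
      multigraph_dl(E, rep(1L, M))$dl
    }, numeric(1)))
    cand <- fit_multigraph_partition(E_list, M)
    Bc <- max(cand)
    if (Bc >= M) break
    agg <- lapply(E_list, function(E) multigraph_dl(E, cand)$E)
    with_cand <- partition_dl(cand) +
      sum(vapply(seq_along(E_list), function(l) {
        multigraph_dl(E_list[[l]], cand)$dl
      }, numeric(1))) +
      log(Bc) + sum(vapply(agg, function(E) {
        multigraph_dl(E, rep(1L, Bc))$dl
      }, numeric(1)))
    if (with_cand >= close_now - 1e-12) break
    levels <- c(levels, list(cand))
    E_list <- agg
    M <- Bc
  }
  c(levels, list(rep(1L, M)))
}

# Partition the block multigraph (uniform-multigraph likelihood) by the same
# greedy + MH scheme, full recompute per move (tiny problems).
fit_multigraph_partition <- function(E_list, M, patience = 50,
                                     max_sweeps = 500, eps = 0.2) {
  obj <- function(c_h) {
    c_h <- compact_membership(c_h)
    Bc <- max(c_h)
    partition_dl(c_h) +
      sum(vapply(E_list, function(E) multigraph_dl(E, c_h)$dl,
                 numeric(1))) +
      log(Bc) +
      sum(vapply(E_list, function(E) {
        multigraph_dl(multigraph_dl(E, c_h)$E, rep(1L, Bc))$dl
      }, numeric(1)))
  }
  A <- Reduce(`+`, E_list)
  cur <- seq_len(M)
  cur_obj <- obj(cur)
  best <- cur; best_obj <- cur_obj
  since <- 0L
  for (sweep in seq_len(max_sweeps)) {
    record_before <- best_obj
    for (i in sample.int(M)) {
      Bc <- max(cur)
      if (stats::runif(1) < eps) {
        s <- sample.int(min(Bc + 1L, M), 1L)
      } else {
        wts <- A[i, ]
        if (sum(wts) == 0) {
          s <- sample.int(Bc, 1L)
        } else {
          j <- sample.int(M, 1L, prob = wts + 1e-9)
          s <- cur[j]
        }
      }
      if (s == cur[i]) next
      prop <- cur
      prop[i] <- s
      prop_obj <- obj(prop)
      d <- prop_obj - cur_obj
      if (d < 0 || stats::runif(1) < exp(-d)) {
        cur <- compact_membership(prop)
        cur_obj <- prop_obj
        if (cur_obj < best_obj - 1e-12) {
          best <- cur; best_obj <- cur_obj
        }
      }
    }
    since <- if (best_obj < record_before - 1e-12) 0L else since + 1L
    if (since >= patience) break
  }
  compact_membership(best)
}

# Bounded refinement of the node-level memberships with the upper levels
# fixed (block count frozen).
refine_base_level <- function(cache, levels, patience = 50) {
  if (length(levels) < 2) return(invisible(cache))
  reset_cache_membership(cache, levels[[1]])
  cache$upper <- levels[-1]
  cache$sigma <- cache_sigma(cache)
  cache$best_sigma <- cache$sigma
  cache$best_b <- cache$b
  mcmc_sweeps(cache, patience = patience,
              max_sweeps = max(200, patience * 4), eps = 0.05)
  invisible(cache)
}

finalize_hierarchy <- function(graph, levels, degree_corrected,
                               weight_model, binom_trials, nested, trace) {
  levels <- normalize_levels(levels, graph$n)
  sigma <- description_length(graph, levels,
                              degree_corrected = degree_corrected,
                              weight_model = weight_model,
                              binom_trials = binom_trials)
  structure(list(levels = levels,
                 B = vapply(levels, max, integer(1)),
                 sigma = sigma,
                 options = list(degree_corrected = degree_corrected,
                                weight_model = weight_model,
                                nested = nested,
                                n_layers = graph$n_layers,
                                binom_trials = binom_trials),
                 n = graph$n,
                 trace = trace),
            class = "block_hierarchy")
}
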