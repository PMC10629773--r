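#' Complete patient-similarity graph with shared-feature edge counts
#'
#' Every pair of patients is joined by an edge carrying, per feature, a
#' binary covariate: 1 when both patients have that indicator equal to 1
#' (mutant-state agreement, and — when `wildtype_agreement` — explicit
#' wildtype agreement too; a missing result never matches).  The collapsed
#' edge weight is the count of shared features, a binomial(K) covariate
#' with K the number of features considered.  With n patients the graph has
#' choose(n, 2) edges; see [patient_edge_count()].
#'
#' @param barcode A `feature_barcode`.
#' @param wildtype_agreement Count agreement on wildtype indicators as
#'   sharing (both behaviours are defensible; default TRUE, since wildtype
#'   states are explicit indicators).
#' @param taxonomy Taxonomy identifying the wildtype state of each domain
#'   (first state); only needed when `wildtype_agreement = FALSE`.
#' @param dense_limit Hard cap on n: the graph is dense by construction and
#'   this builder is desk-scale; subsample beyond the limit.
#' @param keep_covariates Also store the per-edge, per-feature indicator
#'   matrix (memory grows as choose(n,2) x K; keep n small).
#' @return Object of class `patient_graph`: `patients`, `n`, `K`,
#'   `features`, `edges` (choose(n,2) x 2), `shared` (collapsed counts),
#'   optionally `covariates`.
#' @export
build_patient_graph <- function(barcode, wildtype_agreement = TRUE,
                                taxonomy = default_taxonomy(),
                                dense_limit = 2000,
                                keep_covariates = FALSE) {
  stopifnot(inherits(barcode, "feature_barcode"))
  n <- length(barcode$patients)
  if (n < 2) stop("need at least 2 patients")
  if (n > dense_limit) {
    stop("n = ", n, " exceeds the dense limit (", dense_limit,
         "); subsample the cohort before building the complete graph")
  }
  X <- barcode$X
  if (!wildtype_agreement) {
    wt <- unlist(lapply(names(taxonomy), function(d) {
      paste0(d, ": ", taxonomy[[d]][1])
    }))
    X <- X[, !(colnames(X) %in% wt), drop = FALSE]
  }
  A <- X; A[is.na(A)] <- 0L
  storage.mode(A) <- "double"
  Sh <- tcrossprod(A)                      # shared counts
  pr <- which(upper.tri(Sh), arr.ind = TRUE)
  edges <- cbind(pr[, 1], pr[, 2])
  out <- structure(list(patients = barcode$patients, n = n,
                        K = ncol(X), features = colnames(X),
                        edges = edges, shared = Sh[pr]),
                   class = "patient_graph")
  if (keep_covariates) {
    cov <- matrix(0L, nrow(edges), ncol(X),
                  dimnames = list(NULL, colnames(X)))
    for (k in seq_len(ncol(X))) {
      cov[, k] <- as.integer(A[edges[, 1], k] * A[edges[, 2], k])
    }
    out$covariates <- cov
  }
  out
}

#' Edge count of the complete patient graph
#'
#' The number of undirected edges on n patients, choose(n, 2); 4023
#' patients give 8,090,253 edges.
#'
#' @param n Number of patients.
#' @return Edge count.
#' @export
patient_edge_count <- function(n) choose(n, 2)

#' Minimum spanning tree of the patient graph
#'
#' Edge distance is `K - shared` (more shared features = closer), so the
#' tree threads patients through their most genetically similar neighbours.
#'
#' @param graph A `patient_graph`.
#' @return List with `edges` (tree edge matrix), `distance` (per tree
#'   edge) and `total_distance`.  A disconnected input (impossible for the
#'   complete graph, possible for subset graphs) yields a spanning forest
#'   with a warning.
#' @export
minimum_spanning_tree <- function(graph) {
  stopifnot(inherits(graph, "patient_graph"))
  d <- graph$K - graph$shared
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  igraph::E(ig)$weight <- d
  if (igraph::components(ig)$no > 1) {
    warning("graph is disconnected; returning a spanning forest")
  }
  tr <- igraph::mst(ig, weights = igraph::E(ig)$weight)
  el <- igraph::as_edgelist(tr, names = FALSE)
  list(edges = el, distance = igraph::E(tr)$weight,
       total_distance = sum(igraph::E(tr)$weight))
}

#' PCA embedding of patient barcodes
#'
#' Linear baseline representation: centered singular-value decomposition of
#' the barcode with missing entries imputed to 0.  Component signs are
#' fixed by making each component's largest-magnitude loading positive, so
#' the embedding is deterministic.
#'
#' @param barcode A `feature_barcode`.
#' @param n_components Components to return.
#' @return List with `scores` (patients x components), `loadings`,
#'   `explained` (variance ratios, all components).
#' @export
pca_embedding <- function(barcode, n_components = 2) {
  stopifnot(inherits(barcode, "feature_barcode"))
  X <- barcode$X
  X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  if (all(apply(X, 2, stats::var) == 0)) {
    warning("constant barcode matrix: zero variance explained")
    return(list(scores = matrix(0, nrow(X), n_components),
                loadings = matrix(0, ncol(X), n_components),
                explained = rep(0, min(dim(X)))))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Patient communities by stochastic block model
#'
#' Fits the (by default nested, degree-corrected) microcanonical SBM to the
#' complete patient graph with the collapsed shared-feature count as a
#' binomial(K) edge covariate.  With `per_feature_layers = TRUE` each
#' feature instead contributes its own layer of unweighted edges between
#' the patient pairs sharing it (a larger but covariate-exact encoding).
#'
#' @param graph A `patient_graph`.
#' @param degree_corrected,nested,seed,patience,... Passed to [fit_sbm()].
#' @param per_feature_layers Use the layered per-feature encoding.
#' @return A `block_hierarchy` over patients.
#' @export
fit_patient_communities <- function(graph, degree_corrected = TRUE,
                                    nested = TRUE, seed = 1,
                                    patience = 100,
                                    per_feature_layers = FALSE, ...) {
  stopifnot(inherits(graph, "patient_graph"))
  if (per_feature_layers) {
    if (is.null(graph$covariates)) {
      stop("per-feature layers need a graph built with keep_covariates")
    }
    hit <- which(graph$covariates == 1L, arr.ind = TRUE)
    sg <- sbm_graph(graph$n, graph$edges[hit[, 1], , drop = FALSE],
                    layers = hit[, 2], n_layers = graph$K,
                    node_names = graph$patients)
    fit_sbm(sg, degree_corrected = degree_corrected, nested = nested,
            seed = seed, patience = patience, ...)
  } else {
    sg <- sbm_graph(graph$n, graph$edges, weights = graph$shared,
                    binom_trials = graph$K, node_names = graph$patients)
    fit_sbm(sg, degree_corrected = degree_corrected, nested = nested,
            weight_model = "binomial", seed = seed, patience = patience,
            ...)
  }
}

#' Median survival by community
#'
#' Median and interquartile range of survival days per community at a
#' hierarchy level, over patients with survival data; communities with
#' fewer than `min_count` such patients are excluded via the iterated
#' minimum-count filter.  A community with no observed deaths has its
#' median reported as NA ("not reached").
#'
#' @param hierarchy A `block_hierarchy` over patients.
#' @param records Cohort records aligned with the hierarchy's node order.
#' @param level Hierarchy level (see [hierarchy_membership()]).
#' @param min_count Minimum patients with survival data per community.
#' @return data.frame: community, n, events, median_days, q25, q75,
#'   not_reached.
#' @export
community_survival_summary <- function(hierarchy, records, level = 1,
                                       min_count = 5) {
  b <- hierarchy_membership(hierarchy, level)
  stopifnot(length(b) == nrow(records))
  df <- data.frame(community = b,
                   time = records$survival_days,
                   event = records$event)
  df <- df[!is.na(df$time) & !is.na(df$event), , drop = FALSE]
  df <- apply_min_count_filter(df, "community", min_count)$table
  out <- lapply(split(df, df$community), function(g) {
    nr <- sum(g$event) == 0
    data.frame(community = g$community[1], n = nrow(g),
               events = sum(g$event),
               median_days = if (nr) NA_real_ else
                 stats::median(g$time),
               q25 = stats::quantile(g$time, 0.25, names = FALSE),
               q75 = stats::quantile(g$time, 0.75, names = FALSE),
               not_reached = nr)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genetic loadings of patient communities by Bayesian multinomial logit
#'
#' Regresses community membership on the feature indicators with a
#' Bayesian multinomial logistic model (reference category: community 1),
#' weakly-informative normal(0, 2.5^2) coefficient priors, sampled with
#' random-walk Metropolis-within-Gibbs (one proposal per outcome category
#' per iteration, proposal scales adapted during burn-in).  Reports the
#' posterior mean and central 95% credibility interval per (community,
#' feature) coefficient.
#'
#' @param membership Integer community labels per patient (>= 2 distinct),
#'   or a `block_hierarchy` (with `level`).
#' @param barcode A `feature_barcode` (missing entries treated as 0).
#' @param level Hierarchy level when `membership` is a hierarchy.
#' @param samples,burn,thin MCMC schedule (kept draws = samples/thin).
#' @param seed RNG seed.
#' @param prior_scale Normal prior standard deviation.
#' @return data.frame of class `community_loadings`: community, feature,
#'   mean, lo95, hi95.
#' @export
multinomial_loadings <- function(membership, barcode, level = 1,
                                 samples = 100000, burn = 100000,
                                 thin = 5, seed = 1, prior_scale = 2.5) {
  if (inherits(membership, "block_hierarchy")) {
    membership <- hierarchy_membership(membership, level)
  }
  membership <- as.integer(factor(membership))
  C <- max(membership)
  if (C < 2) stop("need at least 2 communities to contrast")
  X <- barcode$X
  X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  keep <- apply(X, 2, stats::var) > 0
  X <- X[, keep, drop = FALSE]
  Z <- cbind(`(intercept)` = 1, X)
  p <- ncol(Z)
  n <- nrow(Z)
  stopifnot(length(membership) == n)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), membership)] <- 1
  loglik <- function(beta) {       # beta: (C-1) x p, category 1 reference
    eta <- cbind(0, Z %*% t(beta))
    mx <- apply(eta, 1, max)
    sum(eta[Y == 1]) - sum(mx + log(rowSums(exp(eta - mx))))
  }
  logprior <- function(beta) -sum(beta^2) / (2 * prior_scale^2)

  beta <- matrix(0, C - 1, p)
  cur <- loglik(beta) + logprior(beta)
  scales <- rep(0.2, C - 1)
  acc <- integer(C - 1)
  n_iter <- burn + samples
  kept <- matrix(NA_real_, floor(samples / thin), (C - 1) * p)
  kidx <- 0L
  for (it in seq_len(n_iter)) {
    for (cc in seq_len(C - 1)) {
      prop <- beta
      prop[cc, ] <- prop[cc, ] + stats::rnorm(p, 0, scales[cc])
      cand <- loglik(prop) + logprior(prop)
      if (log(stats::runif(1)) < cand - cur) {
        beta <- prop
        cur <- cand
        acc[cc] <- acc[cc] + 1L
      }
    }
    if (it <= burn && it %% 100 == 0) {  # adapt toward ~25% acceptance
      rate <- acc / 100
      scales <- scales * ifelse(rate > 0.3, 1.3,
                                ifelse(rate < 0.15, 0.7, 1))
      acc[] <- 0L
    }
    if (it > burn && (it - burn) %% thin == 0 && kidx < nrow(kept)) {
      kidx <- kidx + 1L
      kept[kidx, ] <- as.vector(beta)
    }
  }
  kept <- kept[seq_len(kidx), , drop = FALSE]
  est <- colMeans(kept)
  if (any(abs(est) > 8)) {
    warning("very large coefficients: possible separation; ",
            "estimates rely on the prior for regularization")
  }
  qs <- apply(kept, 2, stats::quantile, probs = c(0.025, 0.975))
  grid <- expand.grid(community = 2:C, coef = colnames(Z),
                      stringsAsFactors = FALSE)
  out <- data.frame(community = grid$community, feature = grid$coef,
                    mean = est, lo95 = qs[1, ], hi95 = qs[2, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("community_loadings", "data.frame")
  out
}

#' Export the patient graph as a sparse edge-list TSV
#'
#' Columns i, j, shared_count; only edges with a positive shared count are
#' written (the zero edges are implicit in the complete graph).
#'
#' @param graph A `patient_graph`.
#' @param path Output TSV.
#' @export
write_patient_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "patient_graph"))
  keep <- graph$shared > 0
  df <- data.frame(i = graph$patients[graph$edges[keep, 1]],
                   j = graph$patients[graph$edges[keep, 2]],
                   shared_count = graph$shared[keep])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
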