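test_that("the complete patient graph has choose(n,2) edges with hand-enumerable covariates", {
  for (n in c(2, 5, 17, 50)) {
    expect_equal(patient_edge_count(n), n * (n - 1) / 2)
  }
  expect_equal(patient_edge_count(4023), 8090253)
  # four-patient toy over three indicator features
  X <- rbind(p1 = c(f1 = 1L, f2 = 0L, f3 = 1L),
             p2 = c(1L, 1L, 0L),
             p3 = c(0L, 1L, NA),
             p4 = c(1L, 0L, 1L))
  bc <- structure(list(patients = rownames(X), features = colnames(X),
                       domains = colnames(X), X = X),
                  class = "feature_barcode")
  pg <- build_patient_graph(bc, keep_covariates = TRUE)
  expect_equal(nrow(pg$edges), 6)
  key <- paste(pg$edges[, 1], pg$edges[, 2])
  cov <- pg$covariates
  rownames(cov) <- key
  # hand enumeration (missing never matches)
  expect_equal(unname(cov["1 2", ]), c(1L, 0L, 0L))
  expect_equal(unname(cov["1 3", ]), c(0L, 0L, 0L))
  expect_equal(unname(cov["1 4", ]), c(1L, 0L, 1L))
  expect_equal(unname(cov["2 3", ]), c(0L, 1L, 0L))
  expect_equal(unname(cov["3 4", ]), c(0L, 0L, 0L))
  expect_equal(pg$shared, rowSums(cov)[key], ignore_attr = TRUE)
  # identical barcodes share all their K active indicators
  expect_equal(pg$shared[key == "1 4"], 2)
  expect_error(build_patient_graph(bc, dense_limit = 3), "dense limit")
})

test_that("wildtype agreement is configurable", {
  rec <- toy_records()
  bc <- fractionate_features(rec)
  with_wt <- build_patient_graph(bc)
  no_wt <- build_patient_graph(bc, wildtype_agreement = FALSE)
  expect_lt(no_wt$K, with_wt$K)
  expect_true(all(no_wt$shared <= with_wt$shared))
})

test_that("the MST matches the exhaustive minimum over all K4 spanning trees", {
  # four patients, distinct pairwise distances
  X <- rbind(p1 = c(1L, 1L, 1L, 0L, 0L, 0L),
             p2 = c(1L, 1L, 0L, 1L, 0L, 0L),
             p3 = c(1L, 0L, 0L, 0L, 1L, 1L),
             p4 = c(0L, 0L, 0L, 1L, 1L, 0L))
  colnames(X) <- paste0("f", 1:6)
  bc <- structure(list(patients = rownames(X), features = colnames(X),
                       domains = colnames(X), X = X),
                  class = "feature_barcode")
  pg <- build_patient_graph(bc)
  mst <- minimum_spanning_tree(pg)
  expect_equal(nrow(mst$edges), 3)
  # brute force over all 16 labelled spanning trees of K4
  D <- matrix(0, 4, 4)
  D[pg$edges] <- pg$K - pg$shared
  D <- D + t(D)
  trees <- utils::combn(6, 3)
  pairs <- pg$edges
  best <- Inf
  for (k in seq_len(ncol(trees))) {
    sel <- pairs[trees[, k], , drop = FALSE]
    ig <- igraph::graph_from_edgelist(sel, directed = FALSE)
    if (igraph::vcount(ig) == 4 && igraph::is_connected(ig)) {
      best <- min(best, sum(D[sel]))
    }
  }
  expect_equal(mst$total_distance, best)
  # a tree input maps to itself
  Xt <- rbind(a = c(1L, 0L), b = c(1L, 1L), c = c(0L, 1L))
  bct <- structure(list(patients = rownames(Xt), features = colnames(Xt),
                        domains = colnames(Xt), X = Xt),
                   class = "feature_barcode")
  mst2 <- minimum_spanning_tree(build_patient_graph(bct))
  expect_equal(nrow(mst2$edges), 2)
})

test_that("PCA embedding is deterministic and matches a hand SVD on a 3x2 toy", {
  X <- rbind(p1 = c(0L, 0L), p2 = c(1L, 1L), p3 = c(1L, 0L))
  colnames(X) <- c("f1", "f2")
  bc <- structure(list(patients = rownames(X), features = colnames(X),
                       domains = colnames(X), X = X),
                  class = "feature_barcode")
  emb <- pca_embedding(bc)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  expect_equal(abs(emb$scores[, 1]), abs(sv$u[, 1] * sv$d[1]),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(emb$explained), 1, tolerance = 1e-12)
  expect_true(all(emb$explained >= 0))
  # collinear features: first component explains everything
  X2 <- cbind(f1 = c(0L, 1L, 0L, 1L), f2 = c(0L, 1L, 0L, 1L))
  rownames(X2) <- paste0("p", 1:4)
  bc2 <- structure(list(patients = rownames(X2), features = colnames(X2),
                        domains = colnames(X2), X = X2),
                   class = "feature_barcode")
  expect_equal(pca_embedding(bc2)$explained[1], 1, tolerance = 1e-12)
  # constant matrix warns and explains nothing
  X3 <- cbind(f1 = rep(1L, 3)); rownames(X3) <- paste0("p", 1:3)
  bc3 <- structure(list(patients = rownames(X3), features = colnames(X3),
                        domains = colnames(X3), X = X3),
                   class = "feature_barcode")
  expect_warning(e3 <- pca_embedding(bc3), "constant")
  expect_equal(sum(e3$explained), 0)
})

test_that("patient communities recover disjoint planted subtypes and ignore permuted nulls", {
  aris <- numeric(0); ari0 <- numeric(0)
  for (s in 1:3) {
    sim <- sample_cohort(two_subtype_config(100), seed = s)
    bc <- fractionate_features(sim$records)
    pg <- build_patient_graph(bc)
    fit <- fit_patient_communities(pg, seed = s, patience = 40,
                                   nested = FALSE)
    truth <- as.integer(factor(sim$truth$subtype))
    aris <- c(aris, ari(hierarchy_membership(fit, 1), truth))
    g <- sbm_graph(pg$n, pg$edges, weights = pg$shared,
                   binom_trials = pg$K)
    fit0 <- fit_sbm(permute_null(g, "edge_weights", seed = s + 40),
                    weight_model = "binomial", degree_corrected = TRUE,
                    seed = s, patience = 40)
    ari0 <- c(ari0, ari(hierarchy_membership(fit0, 1), truth))
  }
  expect_true(all(aris >= 0.9))
  expect_true(all(abs(ari0) < 0.05))
})

test_that("a single planted subtype yields one block", {
  cfg <- two_subtype_config(60)
  cfg$subtypes <- cfg$subtypes[1]
  cfg$subtypes[[1]]$prevalence <- 1
  sim <- sample_cohort(cfg, seed = 4)
  pg <- build_patient_graph(fractionate_features(sim$records))
  fit <- fit_patient_communities(pg, seed = 5, patience = 40,
                                 nested = FALSE)
  expect_equal(fit$B[1], 1L)
  # and the 1-block sigma undercuts a forced even 2-block split
  g <- sbm_graph(pg$n, pg$edges, weights = pg$shared, binom_trials = pg$K)
  forced <- rep(1:2, length.out = pg$n)
  expect_lt(fit$sigma,
            description_length(g, forced, degree_corrected = TRUE,
                               weight_model = "binomial"))
})

test_that("community survival summaries report medians, IQRs and not-reached", {
  rec <- data.frame(patient_id = paste0("p", 1:12),
                    survival_days = c(100, 200, 300, 150, 250, 350,
                                      400, 500, 600, 700, 800, 900),
                    event = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  hier <- structure(list(levels = list(rep(1:2, each = 6), c(1L, 1L)),
                         B = c(2L, 1L), n = 12),
                    class = "block_hierarchy")
  s <- community_survival_summary(hier, rec, level = 1, min_count = 5)
  expect_equal(s$median_days[s$community == 1], 225)
  expect_true(s$not_reached[s$community == 2])   # all censored
  expect_true(is.na(s$median_days[s$community == 2]))
  # communities under the minimum count are excluded
  hier2 <- structure(list(levels = list(c(rep(1L, 9), rep(2L, 3)),
                                        c(1L, 1L)),
                          B = c(2L, 1L), n = 12),
                     class = "block_hierarchy")
  s2 <- community_survival_summary(hier2, rec, level = 1, min_count = 5)
  expect_false(2 %in% s2$community)
})

test_that("community medians follow the planted hazards", {
  sim <- sample_cohort(two_subtype_config(120, median_a = 300,
                                          median_b = 2000), seed = 6)
  pg <- build_patient_graph(fractionate_features(sim$records))
  fit <- fit_patient_communities(pg, seed = 7, patience = 40,
                                 nested = FALSE)
  s <- community_survival_summary(fit, sim$records, level = 1)
  expect_equal(nrow(s), 2)
  truth_med <- tapply(sim$records$survival_days, sim$truth$subtype, median)
  expect_equal(order(s$median_days), order(sort(truth_med)))
})

test_that("multinomial loadings flag predictive features and cover null ones", {
  set.seed(31)
  n <- 150
  comm <- rep(1:2, each = n / 2)
  X <- cbind(pred = as.integer(comm == 2),  # perfectly predictive
             noise = rbinom(n, 1, 0.5))
  # 10% label noise so the predictor is strong but not separating
  flip <- sample(n, n %/% 10)
  X[flip, "pred"] <- 1L - X[flip, "pred"]
  bc <- structure(list(patients = paste0("p", 1:n),
                       features = colnames(X), domains = colnames(X),
                       X = X),
                  class = "feature_barcode")
  ld <- multinomial_loadings(comm, bc, samples = 3000, burn = 1500,
                             thin = 2, seed = 9)
  pred <- ld[ld$feature == "pred", ]
  expect_gt(pred$mean, 0)
  expect_gt(pred$lo95, 0)       # interval excludes zero
  noise <- ld[ld$feature == "noise", ]
  expect_true(noise$lo95 <= 0 && noise$hi95 >= 0)
  expect_true(all(ld$lo95 <= ld$mean & ld$mean <= ld$hi95))
  expect_error(multinomial_loadings(rep(1L, n), bc), "2 communities")
})

test_that("null-feature credible intervals cover zero at the nominal rate", {
  covered <- 0
  runs <- 12
  for (r in seq_len(runs)) {
    set.seed(100 + r)
    n <- 80
    comm <- rep(1:2, each = n / 2)
    X <- cbind(f = rbinom(n, 1, 0.5))   # independent of community
    bc <- structure(list(patients = paste0("p", 1:n),
                         features = colnames(X), domains = colnames(X),
                         X = X),
                    class = "feature_barcode")
    ld <- multinomial_loadings(comm, bc, samples = 1500, burn = 800,
                               thin = 2, seed = r)
    f <- ld[ld$feature == "f", ]
    if (f$lo95 <= 0 && f$hi95 >= 0) covered <- covered + 1
  }
  expect_gte(covered, runs - 2)   # ~95% coverage, small-sample slack
})
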