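toy_barcode <- function(X) {
  # wrap a plain 0/1/NA matrix as a barcode with one domain per feature
  structure(list(patients = rownames(X), features = colnames(X),
                 domains = colnames(X), X = X),
            class = "feature_barcode")
}

test_that("conditional weights equal brute-force counted frequencies", {
  # six-patient toy, hand-countable
  X <- rbind(p1 = c(a = 1, b = 1, c = 0),
             p2 = c(1, 1, 0),
             p3 = c(1, 0, 1),
             p4 = c(0, 1, 1),
             p5 = c(0, 0, 1),
             p6 = c(1, 0, 0))
  colnames(X) <- c("a", "b", "c")
  g <- conditional_probability_graph(toy_barcode(X))
  # P(a|b): b present in p1,p2,p4; a among them in p1,p2 -> 2/3
  expect_equal(g$W["a", "b"], 2 / 3)
  # P(b|a): a present in p1,p2,p3,p6; b among them p1,p2 -> 1/2
  expect_equal(g$W["b", "a"], 1 / 2)
  expect_equal(g$I["a", "b"], 2 / 6)
  # exact Bayes identity: W[a,b] p(b) = W[b,a] p(a) = I[a,b]
  p <- colMeans(X)
  for (u in colnames(X)) for (v in colnames(X)) {
    if (u == v) next
    expect_equal(g$W[u, v] * p[[v]], g$I[u, v], tolerance = 1e-15)
    expect_equal(g$W[u, v] * p[[v]], g$W[v, u] * p[[u]], tolerance = 1e-15)
  }
  expect_true(all(g$W >= 0 & g$W <= 1))
})

test_that("comonotone, disjoint and zero-denominator feature pairs behave as defined", {
  X <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 0))
  colnames(X) <- letters[1:4]; rownames(X) <- paste0("p", 1:3)
  g <- conditional_probability_graph(toy_barcode(X))
  expect_equal(g$W["a", "b"], 1)     # always co-present
  expect_equal(g$W["b", "a"], 1)
  expect_equal(g$W["a", "c"], 0)     # disjoint
  expect_equal(g$W["c", "a"], 0)
  expect_true(g$zero_denominator["a", "d"])  # d never present
  expect_equal(g$W["a", "d"], 0)
  expect_error(conditional_probability_graph(
    toy_barcode(X[0, , drop = FALSE])), "empty")
})

test_that("pairwise-complete estimation is invariant to patient order", {
  cfg <- default_synthetic_config(80, survival_available = 1)
  cfg$missing_probs <- numeric()
  sim <- sample_cohort(cfg, seed = 4)
  bc <- fractionate_features(sim$records)
  g1 <- conditional_probability_graph(bc)
  perm <- sample(nrow(bc$X))
  bc2 <- bc
  bc2$X <- bc$X[perm, , drop = FALSE]
  bc2$patients <- bc$patients[perm]
  g2 <- conditional_probability_graph(bc2)
  expect_equal(g1$W, g2$W)
  expect_equal(g1$S, g2$S)
})

test_that("the default taxonomy yields the 37-node graph with 1332 possible directed edges", {
  feats <- taxonomy_features(default_taxonomy())
  expect_length(feats, 37)
  expect_equal(2 * choose(length(feats), 2), 1332)
})

test_that("edge-weight histograms report hand-computable variance", {
  X <- rbind(c(1, 1), c(1, 0), c(0, 1), c(1, 1), c(1, 0))
  colnames(X) <- c("a", "b"); rownames(X) <- paste0("p", 1:5)
  g <- conditional_probability_graph(toy_barcode(X))
  h <- edge_weight_histogram(g, "conditional")
  # weights are P(a|b) = 2/3 and P(b|a) = 1/2; population variance 1/144
  expect_setequal(round(h$weights, 10), round(c(2/3, 1/2), 10))
  expect_equal(h$variance, 1 / 144)
  # the two-point convention: weights {0.2, 0.8} carry variance 0.09
  Xc <- matrix(0L, 21, 2, dimnames = list(paste0("q", 1:21), c("u", "v")))
  Xc[1:20, "u"] <- 1L          # P(v|u) = 4/20 = 0.2
  Xc[17:21, "v"] <- 1L         # P(u|v) = 4/5  = 0.8
  hc <- edge_weight_histogram(conditional_probability_graph(toy_barcode(Xc)),
                              "conditional")
  expect_setequal(hc$weights, c(0.2, 0.8))
  expect_equal(hc$variance, 0.09)
  expect_equal(sum(h$counts), length(h$weights))
})

test_that("conditional weights spread wider than intersection weights on planted data", {
  cfg <- default_synthetic_config(150, survival_available = 1)
  sim <- sample_cohort(cfg, seed = 12)
  g <- conditional_probability_graph(fractionate_features(sim$records))
  expect_gt(edge_weight_histogram(g, "conditional")$variance,
            edge_weight_histogram(g, "intersection")$variance)
})

test_that("rescaling maps onto [0,1] with the stated endpoint and constant conventions", {
  expect_equal(rescale_weights(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- rescale_weights(c(3, 3)), "constant")
  expect_equal(z, c(0, 0))
  x <- rexp(20)
  r <- rescale_weights(x)
  expect_equal(r[which.min(x)], 0)
  expect_equal(r[which.max(x)], 1)
  expect_error(rescale_weights(numeric(0)), "empty")
})

test_that("centralities match brute-force expectations on symmetric toys", {
  # undirected star, unit weights: centre lies on all C(4,2) leaf pairs
  A <- matrix(0, 5, 5)
  A[1, 2:5] <- 1; A[2:5, 1] <- 1
  ct <- weighted_centralities(A)
  expect_equal(ct$betweenness[1], choose(4, 2))
  expect_equal(ct$betweenness[2:5], rep(0, 4))
  # 2-regular ring: pagerank uniform by symmetry
  R <- matrix(0, 6, 6)
  for (i in 1:6) { R[i, i %% 6 + 1] <- 1; R[i %% 6 + 1, i] <- 1 }
  cr <- weighted_centralities(R)
  expect_equal(cr$pagerank, rep(1 / 6, 6), tolerance = 1e-10)
  # 2-cycle with equal weights: hub equals authority at both nodes
  C2 <- rbind(c(0, 1), c(1, 0))
  cc <- weighted_centralities(C2)
  expect_equal(cc$hub, cc$authority, tolerance = 1e-8)
  expect_error(weighted_centralities(matrix(0, 1, 1)), "2 nodes")
})

test_that("one-way ANOVA matches the textbook table and is shift invariant", {
  v <- c(1, 2, 3, 4, 5, 6)
  gr <- rep(c("x", "y"), each = 3)
  res <- group_anova(v, gr)
  expect_equal(res$F, 13.5)
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  res2 <- group_anova(v + 100, gr)
  expect_equal(res2$F, res$F)
  # identical groups: F = 0, p = 1 by convention
  res3 <- group_anova(rep(2, 6), gr)
  expect_equal(res3$F, 0)
  expect_equal(res3$p, 1)
  expect_error(group_anova(1:3, rep("a", 3)), "2 groups")
})

test_that("graph diagnostics return textbook diameters and planted mixing gaps", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(graph_diagnostics(K4)$diameter, 1)
  P5 <- matrix(0, 5, 5)
  for (i in 1:4) { P5[i, i + 1] <- 1; P5[i + 1, i] <- 1 }
  expect_equal(graph_diagnostics(P5)$diameter, 4)
  # two dense blocks joined weakly mix slower than a uniform graph
  set.seed(42)
  B <- matrix(0.02, 20, 20)
  B[1:10, 1:10] <- 0.9; B[11:20, 11:20] <- 0.9
  diag(B) <- 0
  U <- matrix(mean(B[row(B) != col(B)]), 20, 20); diag(U) <- 0
  expect_gt(graph_diagnostics(B)$mixing_time,
            graph_diagnostics(U)$mixing_time)
})

test_that("the layered feature graph carries both orientations and rescaled weights", {
  cfg <- two_subtype_config(50, missing_probs = c(ATRX = 0.2))
  sim <- sample_cohort(cfg, seed = 8)
  g <- conditional_probability_graph(fractionate_features(sim$records))
  lg <- feature_layered_graph(g)
  expect_s3_class(lg, "sbm_graph")
  expect_equal(lg$n_layers, 2L)
  expect_equal(sum(lg$layers == 1), sum(g$W > 0))      # one per ordered pair
  expect_equal(sum(lg$layers == 2), sum(g$S[upper.tri(g$S)] > 0))
  expect_true(all(lg$weights >= 0 & lg$weights <= 1))
})
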