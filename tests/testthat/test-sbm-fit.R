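test_that("the MCMC search attains the exhaustive flat-model optimum on small graphs", {
  fixtures <- list(two_cliques = two_cliques_graph(4),
                   er8 = er_graph(8, 0.35, seed = 11))
  for (nm in names(fixtures)) {
    g <- fixtures[[nm]]
    for (dc in c(FALSE, TRUE)) {
      oracle <- exhaustive_minimum_dl(g, degree_corrected = dc)
      fit <- fit_sbm(g, degree_corrected = dc, seed = 17)
      expect_equal(fit$sigma, oracle$sigma, tolerance = 1e-9,
                   label = paste(nm, "dc =", dc))
    }
  }
})

test_that("two disconnected 5-cliques are recovered as the two components", {
  g <- sbm_graph(10, rbind(clique_edges(1:5), clique_edges(6:10)))
  fit <- fit_sbm(g, seed = 3)
  expect_equal(fit$B[1], 2L)
  expect_equal(ari(fit$levels[[1]], rep(1:2, each = 5)), 1)
  expect_equal(fit$sigma, description_length(g, rep(1:2, each = 5)),
               tolerance = 1e-9)
})

test_that("reported sigma is self-consistent with description_length", {
  g <- er_graph(25, 0.25, seed = 21)
  fit <- fit_sbm(g, seed = 4, patience = 40)
  expect_equal(description_length(g, fit$levels), fit$sigma,
               tolerance = 1e-9)
  fitn <- fit_sbm(g, nested = TRUE, seed = 4, patience = 40)
  expect_equal(description_length(g, fitn$levels), fitn$sigma,
               tolerance = 1e-9)
  fitd <- fit_sbm(g, degree_corrected = TRUE, seed = 4, patience = 40)
  expect_equal(description_length(g, fitd$levels,
                                  degree_corrected = TRUE),
               fitd$sigma, tolerance = 1e-9)
})

test_that("an empty graph collapses to a single block", {
  fit <- fit_sbm(sbm_graph(6, matrix(0L, 0, 2)), seed = 1)
  expect_equal(fit$B[1], 1L)
})

test_that("fits are reproducible from the seed", {
  pp <- sample_ppm(40, 2, 0.5, 0.05, seed = 8)
  f1 <- fit_sbm(pp$graph, seed = 99, patience = 30)
  f2 <- fit_sbm(pp$graph, seed = 99, patience = 30)
  expect_identical(f1$levels, f2$levels)
  expect_identical(f1$sigma, f2$sigma)
})

test_that("duplicating the planted signal does not hurt recovery", {
  # doubled within-structure edge counts can only sharpen the partition
  base <- numeric(0); dup <- numeric(0)
  for (s in 1:4) {
    pp <- sample_ppm(24, 2, 0.45, 0.08, seed = s)
    g2 <- sbm_graph(pp$graph$n, rbind(pp$graph$edges, pp$graph$edges))
    fb <- fit_sbm(pp$graph, seed = s + 50, patience = 40)
    fd <- fit_sbm(g2, seed = s + 50, patience = 40)
    base <- c(base, ari(fb$levels[[1]], pp$truth))
    dup <- c(dup, ari(fd$levels[[1]], pp$truth))
  }
  expect_gte(mean(dup), mean(base) - 1e-9)
})

test_that("layered fits share partitions and beat the layer-shuffled null on planted layers", {
  lp <- sample_layered_planted(30, 0.6, 0.6, seed = 2)
  f <- fit_layered_sbm(lp$graph, seed = 5, patience = 40)
  null_g <- permute_null(lp$graph, "layer_membership", seed = 77)
  f0 <- fit_layered_sbm(null_g, seed = 5, patience = 40)
  expect_lt(f$sigma, f0$sigma)
  expect_equal(ari(f$levels[[1]], lp$truth), 1)
  expect_error(fit_layered_sbm(two_cliques_graph(4)), "2 layers")
})

test_that("permutation nulls conserve what they must", {
  lp <- sample_layered_planted(20, 0.5, 0.5, seed = 4)
  g <- lp$graph
  g$weights <- stats::runif(nrow(g$edges))
  pw <- permute_null(g, "edge_weights", seed = 13)
  for (l in 1:2) {   # weight multiset preserved within each layer
    expect_setequal(round(pw$weights[pw$layers == l], 12),
                    round(g$weights[g$layers == l], 12))
  }
  expect_identical(pw$edges, g$edges)
  pl <- permute_null(g, "layer_membership", seed = 13)
  expect_equal(tabulate(pl$layers, 2), tabulate(g$layers, 2))
  expect_identical(pl$edges, g$edges)
  g1 <- sbm_graph(2, rbind(c(1L, 2L)), weights = 1)
  expect_warning(permute_null(g1, "edge_weights"), "identity")
})

test_that("model selection prefers the data-generating variant", {
  # heavy-tailed degrees: degree correction pays
  set.seed(6)
  hub_edges <- rbind(cbind(1L, 2:12), cbind(2L, 13:20),
                     t(utils::combn(21:26, 2)))
  gh <- sbm_graph(26, hub_edges)
  sel <- select_model(gh, degree_corrected = c(FALSE, TRUE),
                      nested = FALSE, seed = 9, patience = 30)
  expect_equal(nrow(sel$table), 2)
  expect_equal(sel$best$sigma, min(sel$table$sigma))
  # exponential-weighted planted graph: exponential marginal beats normal
  pp <- sample_ppm(40, 2, 0.5, 0.1, seed = 9)
  g <- pp$graph
  set.seed(10)
  win <- pp$truth[g$edges[, 1]] == pp$truth[g$edges[, 2]]
  g$weights <- ifelse(win, stats::rexp(nrow(g$edges), 1 / 2),
                      stats::rexp(nrow(g$edges), 2))
  sel2 <- select_model(g, degree_corrected = FALSE, nested = FALSE,
                       weight_models = c("normal", "exponential"),
                       seed = 10, patience = 40)
  tab <- sel2$table
  expect_lt(tab$sigma[tab$weight_model == "exponential"],
            tab$sigma[tab$weight_model == "normal"])
  # a single-candidate search returns that candidate
  sel1 <- select_model(two_cliques_graph(4), degree_corrected = FALSE,
                       nested = FALSE, seed = 2)
  expect_equal(nrow(sel1$table), 1)
})

test_that("nested hierarchies end in a single block and expose level memberships", {
  pp <- sample_ppm(60, 4, 0.5, 0.02, seed = 14)
  fit <- fit_sbm(pp$graph, nested = TRUE, seed = 15, patience = 50)
  expect_equal(fit$B[length(fit$B)], 1L)
  expect_equal(length(hierarchy_membership(fit, 1)), 60)
  top <- hierarchy_membership(fit, length(fit$levels))
  expect_true(all(top == 1L))
  # memberships compose consistently
  l2 <- hierarchy_membership(fit, min(2, length(fit$levels)))
  expect_true(all(l2 <= fit$B[min(2, length(fit$B))]))
})
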