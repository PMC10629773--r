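# Independent hand evaluation of the documented description-length terms,
# written directly from the formulas (not by calling the implementation).
hand_flat_dl <- function(n, E_mat, nr, B, E_total) {
  lnms <- function(nn, m) lchoose(nn + m - 1, m)
  # partition prior
  s <- log(n) + lchoose(n - 1, B - 1) + lgamma(n + 1) - sum(lgamma(nr + 1))
  # adjacency (plain)
  er <- rowSums(E_mat)
  s <- s - sum(lgamma(E_mat[upper.tri(E_mat)] + 1))
  s <- s - sum((diag(E_mat) / 2) * log(2) + lgamma(diag(E_mat) / 2 + 1))
  s <- s + sum(er * log(nr))
  # edge-count prior via the single-block top level, plus its partition
  s + lnms(B * (B + 1) / 2, E_total) + log(B)
}

test_that("a single isolated node has the closed-form prior-only description length", {
  g <- sbm_graph(1, matrix(0L, 0, 2))
  # every prior is certainty for N = 1, B = 1: Sigma = 0 exactly
  expect_equal(description_length(g, 1L), 0)
})

test_that("flat description length equals independent hand evaluation", {
  g <- two_cliques_graph(4)
  b2 <- rep(1:2, each = 4)
  E2 <- matrix(c(12, 0, 0, 12), 2, 2)
  expect_equal(description_length(g, b2),
               hand_flat_dl(8, E2, c(4, 4), 2, 12))
  b1 <- rep(1L, 8)
  expect_equal(description_length(g, b1),
               hand_flat_dl(8, matrix(24, 1, 1), 8, 1, 12))
})

test_that("description length is invariant to block label permutation", {
  g <- er_graph(10, 0.4, seed = 3)
  b <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  perm <- c(3, 1, 2)
  for (dc in c(FALSE, TRUE)) {
    expect_equal(description_length(g, b, degree_corrected = dc),
                 description_length(g, perm[b], degree_corrected = dc),
                 tolerance = 1e-12)
  }
})

test_that("term breakdown sums to the total and degree terms appear only when corrected", {
  g <- er_graph(12, 0.3, seed = 5)
  b <- rep(1:3, each = 4)
  p <- description_length(g, b, parts = TRUE)
  expect_equal(sum(p), description_length(g, b))
  expect_false(any(grepl("degree", names(p))))
  pd <- description_length(g, b, degree_corrected = TRUE, parts = TRUE)
  expect_true(any(grepl("degree", names(pd))))
  expect_equal(sum(pd), description_length(g, b, degree_corrected = TRUE))
})

test_that("edge-covariate marginal likelihoods match hand arithmetic", {
  # one edge, weight x, exponential model with Gamma(1,1) rate prior:
  # marginal = Gamma(2) / (1+x)^2 so -ln = 2 ln(1+x)
  g1 <- sbm_graph(2, rbind(c(1L, 2L)), weights = 0.7)
  d_with <- description_length(g1, c(1L, 1L), weight_model = "exponential")
  d_none <- description_length(g1, c(1L, 1L))
  expect_equal(d_with - d_none, 2 * log(1.7))
  # binomial: one edge, x of K, Beta(1,1): marginal = C(K,x) B(x+1, K-x+1)
  K <- 5; x <- 3
  gb <- sbm_graph(2, rbind(c(1L, 2L)), weights = x, binom_trials = K)
  db <- description_length(gb, c(1L, 1L), weight_model = "binomial")
  hand <- -(lchoose(K, x) + lgamma(x + 1) + lgamma(K - x + 1) -
              lgamma(K + 2))
  expect_equal(db - d_none, hand)
  # normal: one edge, NIG(mu0=0, k0=1, a0=1, b0=1) marginal is Student-like
  xw <- 0.4
  gn <- sbm_graph(2, rbind(c(1L, 2L)), weights = xw)
  dn <- description_length(gn, c(1L, 1L), weight_model = "normal")
  kn <- 2; an <- 1.5
  bn <- 1 + 0 + 1 * 1 * xw^2 / (2 * kn)
  hand_n <- -(-0.5 * log(2 * pi) + 0.5 * log(1 / kn) +
                lgamma(an) - lgamma(1) + 1 * log(1) - an * log(bn))
  expect_equal(dn - d_none, hand_n)
  # requesting weights without any present is an error
  g0 <- sbm_graph(2, rbind(c(1L, 2L)))
  expect_error(description_length(g0, c(1L, 1L), weight_model = "normal"),
               "no weights")
})

test_that("layered bookkeeping: empty layers and identical layers behave as documented", {
  e <- clique_edges(1:4)
  g1 <- sbm_graph(4, e)
  # a second, empty layer adds only the composition constant
  g_empty <- sbm_graph(4, e, layers = rep(1L, nrow(e)), n_layers = 2L)
  const <- lchoose(nrow(e) + 1, 1)
  expect_equal(description_length(g_empty, rep(1L, 4)),
               description_length(g1, rep(1L, 4)) + const)
  # duplicated layers double the data terms but not the partition terms
  g_dup <- sbm_graph(4, rbind(e, e),
                     layers = rep(1:2, each = nrow(e)), n_layers = 2L)
  p1 <- description_length(g1, rep(1L, 4), parts = TRUE)
  p2 <- description_length(g_dup, rep(1L, 4), parts = TRUE)
  expect_equal(unname(p2["adjacency_layer2"]),
               unname(p1["adjacency_layer1"]))
  expect_equal(unname(p2["partition_L0"]), unname(p1["partition_L0"]))
})

test_that("hierarchy validation enforces surjectivity and the single-block top", {
  g <- two_cliques_graph(4)
  expect_error(description_length(g, c(rep(1L, 4), rep(3L, 4))),
               "surjective")
  expect_error(description_length(g, list(rep(1:2, each = 4), c(1L, 3L))),
               "surjective")
  # a flat membership gets the trivial top appended automatically
  lev <- list(rep(1:2, each = 4), c(1L, 1L))
  expect_equal(description_length(g, rep(1:2, each = 4)),
               description_length(g, lev))
})

test_that("posterior odds follow the description-length difference", {
  po <- posterior_odds(10, 10)
  expect_equal(po$log_odds, 0)
  expect_equal(po$odds, 1)
  expect_equal(posterior_odds(9, 10)$log_odds, 1)
  expect_equal(posterior_odds(5, 5, prior_a = 0.9, prior_b = 0.1)$log_odds,
               log(9))
  # equal priors: Lambda > 1 iff sigma_a < sigma_b
  expect_gt(posterior_odds(3, 4)$odds, 1)
  expect_lt(posterior_odds(4, 3)$odds, 1)
})
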