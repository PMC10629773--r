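test_that("the Newton maximizer matches a dense grid search of the partial likelihood", {
  # no ties, single binary covariate, unpenalized
  set.seed(1)
  n <- 40
  x <- rep(0:1, each = n / 2)
  tm <- round(rexp(n, exp(0.8 * x)) * 1000) + seq_len(n) * 1e-3  # distinct
  ev <- rep(1L, n)
  fit <- fit_cox_design(tm, ev, cbind(x = x), penalizer = 0)
  grid <- seq(-2, 3, by = 1e-4)
  ll <- vapply(grid, function(b) {
    cox_partial_loglik(b, tm, ev, cbind(x))$loglik
  }, numeric(1))
  expect_lt(abs(fit$coefficients - grid[which.max(ll)]), 1e-4)
})

test_that("the gradient matches central finite differences on random data", {
  for (s in 1:3) {
    set.seed(s)
    n <- 25
    X <- cbind(stats::rnorm(n), stats::rbinom(n, 1, 0.4))
    tm <- stats::rexp(n)
    ev <- stats::rbinom(n, 1, 0.7)
    beta <- stats::rnorm(2, 0, 0.5)
    g <- cox_partial_loglik(beta, tm, ev, X, penalizer = 0.2)$gradient
    for (j in 1:2) {
      e <- numeric(2); e[j] <- 1e-6
      fd <- (cox_partial_loglik(beta + e, tm, ev, X, 0.2)$loglik -
               cox_partial_loglik(beta - e, tm, ev, X, 0.2)$loglik) / 2e-6
      expect_lt(abs(g[j] - fd), 1e-5)
    }
  }
})

test_that("fits agree with the survival package with and without ridge penalty", {
  set.seed(2)
  n <- 150
  x1 <- stats::rnorm(n); x2 <- stats::rbinom(n, 1, 0.5)
  tm <- stats::rexp(n, exp(0.5 * x1 - 0.3 * x2))
  ev <- stats::rbinom(n, 1, 0.8)
  f <- fit_cox_design(tm, ev, cbind(x1, x2), penalizer = 0)
  ref <- survival::coxph(survival::Surv(tm, ev) ~ x1 + x2,
                         ties = "breslow")
  expect_equal(unname(f$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  fp <- fit_cox_design(tm, ev, cbind(x1, x2), penalizer = 0.1)
  refp <- survival::coxph(
    survival::Surv(tm, ev) ~ survival::ridge(x1, x2, theta = 0.1,
                                             scale = FALSE),
    ties = "breslow")
  expect_equal(unname(fp$coefficients), unname(coef(refp)),
               tolerance = 1e-4)
})

test_that("a zero-variance covariate is pulled to zero by the penalty", {
  set.seed(3)
  tm <- stats::rexp(30); ev <- rep(1L, 30)
  f <- fit_cox_design(tm, ev, cbind(flat = rep(1, 30), x = rnorm(30)),
                      penalizer = 0.5)
  expect_equal(unname(f$coefficients["flat"]), 0, tolerance = 1e-8)
})

test_that("the Breslow baseline is non-decreasing and hazard ratios positive", {
  set.seed(4)
  n <- 120
  x <- stats::rnorm(n)
  tm <- stats::rexp(n, exp(0.4 * x)); ev <- stats::rbinom(n, 1, 0.7)
  f <- fit_cox_design(tm, ev, cbind(x = x))
  expect_true(all(diff(f$baseline$cumhaz) >= 0))
  expect_true(all(f$hazard_ratios$hr > 0))
  expect_true(all(f$hazard_ratios$lo95 <= f$hazard_ratios$hr))
  expect_true(all(f$hazard_ratios$hi95 >= f$hazard_ratios$hr))
})

test_that("a known log-hazard ratio is recovered within sampling error", {
  set.seed(5)
  n <- 1000
  x <- stats::rbinom(n, 1, 0.5)
  tm <- stats::rexp(n, exp(0.7 * x))
  ev <- rep(1L, n)
  f <- fit_cox_design(tm, ev, cbind(x = x), penalizer = 0)
  expect_lt(abs(f$coefficients - 0.7), 3 * f$se)
})

test_that("the concordance index counts pairs exactly and respects monotone transforms", {
  # perfectly anti-ordered risk: highest risk dies first
  tm <- c(1, 2, 3, 4, 5); ev <- rep(1, 5)
  risk <- c(5, 4, 3, 2, 1)
  expect_equal(concordance_index(tm, ev, risk), 1)
  # hand-countable 5-observation toy with a censored case
  tm2 <- c(2, 4, 6, 8, 10)
  ev2 <- c(1, 0, 1, 1, 0)
  r2 <- c(3, 1, 4, 2, 0.5)
  # usable pairs and concordant count by brute force
  conc <- 0; usable <- 0
  for (i in 1:5) for (j in 1:5) {
    if (tm2[i] < tm2[j] && ev2[i] == 1) {
      usable <- usable + 1
      if (r2[i] > r2[j]) conc <- conc + 1
      if (r2[i] == r2[j]) conc <- conc + 0.5
    }
  }
  expect_equal(concordance_index(tm2, ev2, r2), conc / usable)
  # invariance under strictly monotone transforms of the score
  expect_equal(concordance_index(tm2, ev2, exp(r2)),
               concordance_index(tm2, ev2, r2))
  expect_equal(concordance_index(tm2, ev2, 10 * r2 - 3),
               concordance_index(tm2, ev2, r2))
})

test_that("random risk scores score near chance concordance", {
  set.seed(6)
  n <- 1500
  tm <- stats::rexp(n); ev <- stats::rbinom(n, 1, 0.8)
  ci <- concordance_index(tm, ev, stats::rnorm(n))
  expect_gt(ci, 0.45); expect_lt(ci, 0.55)
})

test_that("cross-validated concordance separates informative from null designs", {
  sim <- sample_cohort(two_subtype_config(400, median_a = 300,
                                          median_b = 2000,
                                          censor_rate = 0.1), seed = 7)
  bc <- fractionate_features(sim$records)
  comm <- as.integer(factor(sim$truth$subtype))
  st <- survival_table(sim$records, barcode = bc, community = comm)
  cvc <- cv_concordance(st$time, st$event, st$designs$communities,
                        seed = 11)
  expect_length(cvc$fold_c, 5)
  expect_gt(cvc$median_c, 0.6)
  # pure-noise design: chance level
  noise <- cbind(z = stats::rnorm(length(st$time)))
  cv0 <- cv_concordance(st$time, st$event, noise, seed = 11)
  expect_gt(cv0$median_c, 0.4); expect_lt(cv0$median_c, 0.6)
})

test_that("horizon labels implement the exclusion convention at 30.44 days/month", {
  lab <- make_horizon_labels(100, 1, 12)
  expect_equal(lab$label, 0L)               # died before 365.28 days
  lab2 <- make_horizon_labels(200, 0, 12)
  expect_false(lab2$include)                # censored early: excluded
  expect_true(is.na(lab2$label))
  # ten-patient hand enumeration at 24 months (730.56 days)
  tm <- c(100, 700, 731, 800, 2000, 50, 731, 600, 900, 730)
  ev <- c(1, 1, 0, 0, 1, 0, 1, 1, 0, 1)
  lab3 <- make_horizon_labels(tm, ev, 24)
  hand_inc <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                TRUE)
  hand_lab <- c(0L, 0L, 1L, 1L, 1L, NA, 1L, 0L, 1L, 0L)
  expect_equal(lab3$include, hand_inc)
  expect_equal(lab3$label, hand_lab)
})
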