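#' Bayesian logistic regression with shrinkage priors
#'
#' Posterior sampling for a fixed-horizon survival logit under a shrinkage
#' prior on the (non-intercept) coefficients:
#'
#' * `ridge`: beta_j ~ Normal(0, scale^2), fixed scale;
#' * `horseshoe`: beta_j ~ Normal(0, tau^2 lambda_j^2) with half-Cauchy(1)
#'   local scales lambda_j and global scale tau.
#'
#' The remaining named schemes alias to the closest implemented prior with
#' a warning (`g`, `lasso` -> ridge; `horseshoe+`, `logt` -> horseshoe);
#' fidelity of all six is not claimed.  The intercept always has a diffuse
#' Normal(0, 10^2) prior.  Sampling is random-walk Metropolis within
#' Gibbs: componentwise proposals for beta with scales adapted during
#' burn-in, and log-scale random-walk updates for the horseshoe's lambda
#' and tau.  Total iterations are `burn + samples`; every `thin`-th
#' post-burn draw is kept.
#'
#' @param y Binary outcome (both classes must be present).
#' @param X Design matrix, no intercept column (added internally).
#' @param prior Prior scheme.
#' @param samples,burn,thin MCMC schedule.
#' @param seed RNG seed.
#' @param scale Ridge prior standard deviation.
#' @return Object of class `bayes_logit`: `draws` (kept draws x
#'   coefficients, first column the intercept), `prior`, `accept_rate`.
#' @export
fit_bayes_logit <- function(y, X, prior = c("ridge", "horseshoe", "g",
                                            "horseshoe+", "lasso", "logt"),
                            samples = 100000, burn = 100000, thin = 5,
                            seed = 1, scale = 2.5) {
  prior <- match.arg(prior)
  alias <- c(g = "ridge", lasso = "ridge",
             `horseshoe+` = "horseshoe", logt = "horseshoe")
  if (prior %in% names(alias)) {
    warning("prior '", prior, "' aliases to '", alias[[prior]], "'")
    prior <- alias[[prior]]
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  X <- as.matrix(X)
  Z <- cbind(`(intercept)` = 1, X)
  n <- nrow(Z); p <- ncol(Z)
  stopifnot(length(y) == n)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  loglik_eta <- function(eta) sum(y * eta) - sum(log1pexp(eta))
  beta <- rep(0, p)
  eta <- drop(Z %*% beta)
  ll <- loglik_eta(eta)
  lam <- rep(1, p - 1)          # horseshoe local scales
  tau <- 1
  prior_sd <- function() {
    if (prior == "ridge") c(10, rep(scale, p - 1)) else c(10, tau * lam)
  }
  sdv <- prior_sd()
  lp_beta <- function(b, s) -b^2 / (2 * s^2)

  scales <- rep(0.5, p)
  acc <- numeric(p); tries <- numeric(p)
  n_iter <- burn + samples
  kept <- matrix(NA_real_, floor(samples / thin), p,
                 dimnames = list(NULL, colnames(Z)))
  kidx <- 0L
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      bj <- beta[j] + stats::rnorm(1, 0, scales[j])
      eta_new <- eta + Z[, j] * (bj - beta[j])
      ll_new <- loglik_eta(eta_new)
      a <- ll_new - ll + lp_beta(bj, sdv[j]) - lp_beta(beta[j], sdv[j])
      tries[j] <- tries[j] + 1
      if (log(stats::runif(1)) < a) {
        beta[j] <- bj; eta <- eta_new; ll <- ll_new
        acc[j] <- acc[j] + 1
      }
    }
    if (prior == "horseshoe") {
      # local scales: half-Cauchy(0,1) prior, log-random-walk
      for (j in seq_len(p - 1)) {
        prop <- lam[j] * exp(stats::rnorm(1, 0, 0.5))
        a <- lp_beta(beta[j + 1], tau * prop) -
          lp_beta(beta[j + 1], tau * lam[j]) +
          log(prop) - log(lam[j]) +            # log-scale Jacobian
          log(1 + lam[j]^2) - log(1 + prop^2)  # half-Cauchy density ratio
        a <- a - log(prop) + log(lam[j])       # normal sd in prior normalizer
        if (log(stats::runif(1)) < a) lam[j] <- prop
      }
      prop <- tau * exp(stats::rnorm(1, 0, 0.25))
      a <- sum(lp_beta(beta[-1], prop * lam) -
                 lp_beta(beta[-1], tau * lam)) +
        (p - 1) * (log(tau) - log(prop)) +
        log(prop) - log(tau) +
        log(1 + tau^2) - log(1 + prop^2)
      if (log(stats::runif(1)) < a) tau <- prop
      sdv <- prior_sd()
    }
    if (it <= burn && it %% 100 == 0) {
      rate <- acc / pmax(tries, 1)
      scales <- scales * ifelse(rate > 0.5, 1.4,
                                ifelse(rate < 0.25, 0.7, 1))
      acc[] <- 0; tries[] <- 0
    }
    if (it > burn && (it - burn) %% thin == 0 && kidx < nrow(kept)) {
      kidx <- kidx + 1L
      kept[kidx, ] <- beta
    }
  }
  structure(list(draws = kept[seq_len(kidx), , drop = FALSE],
                 prior = prior,
                 accept_rate = acc / pmax(tries, 1),
                 y = y, Z = Z),
            class = "bayes_logit")
}

#' Widely applicable information criterion (deviance scale)
#'
#' `WAIC = -2 (lppd - p_waic)` where
#' `lppd = sum_i ln mean_s p(y_i | theta_s)` and
#' `p_waic = sum_i var_s ln p(y_i | theta_s)` over the posterior draws.
#'
#' @param fit A `bayes_logit`.
#' @param y,X Optionally score a different dataset than the one fitted
#'   (defaults to the training data).
#' @return List with `waic`, `lppd`, `p_waic` and the pointwise matrix
#'   dimensions used.
#' @export
waic <- function(fit, y = NULL, X = NULL) {
  stopifnot(inherits(fit, "bayes_logit"))
  if (nrow(fit$draws) < 2) stop("need >= 2 posterior draws")
  Z <- if (is.null(X)) fit$Z else cbind(1, as.matrix(X))
  y <- if (is.null(y)) fit$y else as.integer(y)
  ll <- pointwise_loglik(fit$draws, y, Z)   # draws x n
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
       n = length(y), draws = nrow(ll))
}

pointwise_loglik <- function(draws, y, Z) {
  eta <- draws %*% t(Z)                     # draws x n
  sweep(eta, 2, y, function(e, yy) yy * e) - log1pexp(eta)
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 30
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
  out
}

#' McFadden pseudo-R2 of a Bayesian logit
#'
#' `1 - l(beta_hat) / l0` with `l(beta_hat)` the log-likelihood at the
#' posterior-mean coefficients and `l0` the intercept-only maximum
#' log-likelihood.  (The pseudo-R2 definition is a documented choice.)
#'
#' @param fit A `bayes_logit`.
#' @param y,X Optional alternative data (default: training data).
#' @return Value in (-Inf, 1\].
#' @export
pseudo_r2 <- function(fit, y = NULL, X = NULL) {
  stopifnot(inherits(fit, "bayes_logit"))
  Z <- if (is.null(X)) fit$Z else cbind(1, as.matrix(X))
  y <- if (is.null(y)) fit$y else as.integer(y)
  beta <- colMeans(fit$draws)
  eta <- drop(Z %*% beta)
  ll <- sum(y * eta) - sum(log1pexp(eta))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  if (ll0 == 0) return(1)
  1 - ll / ll0
}
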