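#' Cox partial log-likelihood with Breslow tie handling
#'
#' Value, gradient and Hessian of the (optionally L2-penalized) Cox partial
#' log-likelihood under the Breslow approximation for ties: every event at
#' time t uses the full risk set \{j : t_j >= t\}.  The penalty is
#' `-(penalizer/2) * sum(beta^2)`.
#'
#' @param beta Coefficient vector.
#' @param time,event Survival times and event indicators (1 = death).
#' @param X Covariate matrix (rows = subjects).
#' @param penalizer L2 penalty strength (0 = none).
#' @param hessian Also compute the Hessian.
#' @return List with `loglik`, `gradient` and (optionally) `hessian`, all
#'   of the penalized objective.
#' @export
cox_partial_loglik <- function(beta, time, event, X, penalizer = 0,
                               hessian = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(time) == n, length(event) == n, length(beta) == p)
  ord <- order(time, decreasing = TRUE)   # risk sets by cumulative sums
  tt <- time[ord]; ev <- event[ord]; Xo <- X[ord, , drop = FALSE]
  eta <- drop(Xo %*% beta)
  eta_c <- eta - max(eta)                 # guard overflow
  w <- exp(eta_c)
  S0 <- cumsum(w)
  S1 <- apply(Xo * w, 2, cumsum)
  # risk-set index of each position: last position of its tie block
  tie_end <- cummax_last_tie(tt)
  ei <- which(ev == 1)
  ri <- tie_end[ei]
  ll <- sum(eta[ei]) - sum(log(S0[ri]) + max(eta))
  grad <- colSums(Xo[ei, , drop = FALSE]) -
    colSums(S1[ri, , drop = FALSE] / S0[ri])
  out <- list(loglik = ll - penalizer / 2 * sum(beta^2),
              gradient = grad - penalizer * beta)
  if (hessian) {
    H <- matrix(0, p, p)
    # cumulative sums of x x^T w, evaluated at the risk-set indices
    cp <- array(0, c(n, p, p))
    for (a in seq_len(p)) {
      for (bb in a:p) {
        cs <- cumsum(Xo[, a] * Xo[, bb] * w)
        cp[, a, bb] <- cs
        cp[, bb, a] <- cs
      }
    }
    for (e in seq_along(ei)) {
      r <- ri[e]
      m1 <- S1[r, ] / S0[r]
      H <- H - (cp[r, , ] / S0[r] - tcrossprod(m1))
    }
    out$hessian <- H - diag(penalizer, p)
  }
  out
}

# position of the last element of each tie block (times sorted decreasing)
cummax_last_tie <- function(tt) {
  n <- length(tt)
  last <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1L] == tt[i]) j <- j + 1L
    last[i:j] <- j
    i <- j + 1L
  }
  last
}

#' Penalized Cox proportional-hazards fit
#'
#' Maximizes the Breslow-tie partial log-likelihood minus
#' `(penalizer/2) * ||beta||^2` by Newton iterations, stopping when the
#' penalized gradient norm falls below 1e-8.  Standard errors come from
#' the inverse penalized information; the Breslow baseline cumulative
#' hazard is computed at the fitted coefficients.
#'
#' @param time,event Survival data (>= 2 events required).
#' @param X Covariate matrix (column names kept).
#' @param penalizer L2 penalty (default 0.1).
#' @param max_iter Newton iteration cap (error past it).
#' @param tol Gradient-norm convergence tolerance.
#' @return Object of class `cox_fit`: `coefficients`, `se`,
#'   `hazard_ratios` (with 95% CI), `baseline` (data.frame time,
#'   cumhaz), `loglik`, `penalizer`, `iterations`.
#' @export
fit_cox_design <- function(time, event, X, penalizer = 0.1,
                           max_iter = 500, tol = 1e-8) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X) & !is.na(time) & !is.na(event)
  X <- X[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (sum(event) < 2) stop("need at least 2 events")
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    pl <- cox_partial_loglik(beta, time, event, X, penalizer,
                             hessian = TRUE)
    gn <- sqrt(sum(pl$gradient^2))
    if (gn < tol) break
    step <- tryCatch(solve(pl$hessian, pl$gradient),
                     error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(pl$hessian - diag(1e-8, p), pl$gradient)
    }
    new_beta <- beta - step
    # halve the step while the objective worsens
    f_old <- pl$loglik
    for (h in 1:30) {
      f_new <- cox_partial_loglik(new_beta, time, event, X,
                                  penalizer)$loglik
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      new_beta <- (beta + new_beta) / 2
    }
    beta <- new_beta
    if (it == max_iter) {
      stop("Cox fit did not converge after ", max_iter,
           " iterations (|grad| = ", format(gn), ")")
    }
  }
  pl <- cox_partial_loglik(beta, time, event, X, penalizer, hessian = TRUE)
  V <- solve(-pl$hessian)
  se <- sqrt(pmax(diag(V), 0))
  hr <- data.frame(covariate = colnames(X), coef = beta, se = se,
                   hr = exp(beta),
                   lo95 = exp(beta - 1.96 * se),
                   hi95 = exp(beta + 1.96 * se),
                   stringsAsFactors = FALSE)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hazard_ratios = hr,
                 baseline = breslow_baseline(beta, time, event, X),
                 loglik = pl$loglik, penalizer = penalizer,
                 iterations = it,
                 data = list(time = time, event = event, X = X)),
            class = "cox_fit")
}

#' Breslow baseline cumulative hazard
#'
#' `H0(t) = sum over event times s <= t of d_s / sum_{j at risk at s}
#' exp(x_j beta)`.
#'
#' @param beta Fitted coefficients.
#' @param time,event,X Survival data and design.
#' @return data.frame with `time` (distinct event times, increasing) and
#'   `cumhaz` (non-decreasing).
#' @export
breslow_baseline <- function(beta, time, event, X) {
  eta <- drop(as.matrix(X) %*% beta)
  w <- exp(eta)
  et <- sort(unique(time[event == 1]))
  h <- vapply(et, function(s) {
    sum(event == 1 & time == s) / sum(w[time >= s])
  }, numeric(1))
  data.frame(time = et, cumhaz = cumsum(h))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Penalized Cox fit (Breslow ties, penalizer =", x$penalizer, ")\n")
  print(x$hazard_ratios, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cross-validated Harrell concordance of a Cox design
#'
#' 5-fold cross-validation with folds stratified by the event indicator;
#' each held-out fold is scored by Harrell's c-index of its fold-trained
#' linear predictor (higher predictor = higher risk).  If a fold draw
#' leaves a fold without events, the split is redrawn with the next seed
#' (with a warning).
#'
#' @param time,event,X Survival data and design matrix.
#' @param k Folds (default 5).
#' @param seed Fold-assignment seed.
#' @param penalizer Passed to [fit_cox_design()].
#' @return List with `median_c` (median out-of-fold c-index) and
#'   `fold_c` (per-fold values).
#' @export
cv_concordance <- function(time, event, X, k = 5, seed = 1,
                           penalizer = 0.1) {
  X <- as.matrix(X)
  n <- length(time)
  for (attempt in 0:10) {
    rng <- local_rng(seed + attempt)
    folds <- integer(n)
    for (g in unique(event)) {   # stratify by event status
      idx <- which(event == g)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    rng()
    ok <- all(vapply(seq_len(k), function(f) {
      sum(event[folds != f]) >= 2 && sum(folds == f) >= 2
    }, logical(1)))
    if (ok) break
    warning("degenerate fold; redrawing with next seed")
  }
  fold_c <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- fit_cox_design(time[tr], event[tr], X[tr, , drop = FALSE],
                          penalizer = penalizer)
    lp <- drop(X[!tr, , drop = FALSE] %*% fit$coefficients)
    concordance_index(time[!tr], event[!tr], lp)
  }, numeric(1))
  list(median_c = stats::median(fold_c), fold_c = fold_c)
}

#' Harrell's concordance index
#'
#' Probability that, of a usable pair, the subject with the higher risk
#' score fails first (ties counted half), via [survival::concordance()].
#'
#' @param time,event Survival data.
#' @param risk Risk scores (higher = worse).
#' @return c-index in \[0, 1\].
#' @export
concordance_index <- function(time, event, risk) {
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  as.numeric(cc$concordance)
}

#' Fixed-horizon survival labels
#'
#' Converts survival data into an alive-at-horizon binary outcome: label 1
#' if follow-up reaches the horizon (survived), 0 if death occurred before
#' it; patients censored before the horizon carry no information about it
#' and are excluded (inclusion mask 0).  Months convert at 30.44
#' days/month.
#'
#' @param time Survival days.
#' @param event Event indicator.
#' @param horizon_months Horizon (the analysis uses 12, 24, 36).
#' @return List with `label` (0/1, NA where excluded) and `include`
#'   (logical mask).
#' @export
make_horizon_labels <- function(time, event, horizon_months) {
  h <- horizon_months * 30.44
  alive <- time >= h
  died_before <- time < h & event == 1
  include <- !is.na(time) & !is.na(event) & (alive | died_before)
  label <- ifelse(alive, 1L, 0L)
  label[!include] <- NA_integer_
  list(label = label, include = include, horizon_days = h)
}
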