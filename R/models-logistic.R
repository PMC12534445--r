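# log(1 + exp(eta)) without overflow
log1pexp <- function(eta) {
  out <- numeric(length(eta))
  big <- eta > 30
  out[big] <- eta[big] + log1p(exp(-eta[big]))
  out[!big] <- log1p(exp(eta[!big]))
  out
}

#' Logistic regression by Newton-Raphson
#'
#' Maximizes the (optionally weighted) Bernoulli log-likelihood by Newton's
#' method with step-halving, so the log-likelihood is non-decreasing across
#' iterations. Standard errors come from the observed information at the
#' optimum; Wald z, normal p-values and 95\% confidence intervals follow.
#'
#' Perfect separation is detected (fitted probabilities collapsing to 0/1
#' with an exact split of the classes) and raised as an
#' `explor_separation_error` naming the covariate carrying the diverging
#' coefficient; failure to converge within `max_iter` iterations raises an
#' `explor_convergence_error` whose message carries the iteration trace.
#'
#' @param y numeric response in \[0, 1\] (0/1 outcomes, or proportions with
#'   `weights` as binomial denominators).
#' @param X design matrix including the intercept column.
#' @param weights optional prior weights (binomial denominators).
#' @param max_iter,tol Newton iteration cap and convergence tolerance on the
#'   largest absolute coefficient change.
#' @return An `explor_fit`; element `loglik_trace` holds the per-iteration
#'   log-likelihood.
#' @export
logistic_fit <- function(y, X, weights = NULL, max_iter = 50, tol = 1e-10) {
  X <- check_design(y, X)
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w > 0), all(y >= 0 & y <= 1))
  beta <- numeric(ncol(X))
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(w * (y * eta - log1pexp(eta)))
  }
  ll_old <- ll(beta)
  trace <- ll_old
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    info <- crossprod(X, X * (w * p * (1 - p)))
    score <- crossprod(X, w * (y - p))
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    for (h in 1:30) {
      cand <- beta + step * drop(delta)
      ll_new <- ll(cand)
      if (ll_new >= ll_old - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step * drop(delta)
    trace <- c(trace, ll_new)
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  # separation: classes split exactly and the likelihood is saturating
  if (any(abs(beta) > 25)) {
    y1 <- y > 0.5
    if (any(y1) && any(!y1) && (min(eta[y1]) > max(eta[!y1]) ||
                                max(eta[y1]) < min(eta[!y1]))) {
      sds <- apply(X, 2, stats::sd)
      culprit <- colnames(X)[which.max(abs(beta) * ifelse(sds > 0, sds, 0))]
      explor_error(paste("perfect separation detected; separating covariate:",
                         culprit), "explor_separation_error")
    }
  }
  if (!converged)
    explor_error(paste0("logistic fit did not converge in ", max_iter,
                        " iterations; log-likelihood trace: ",
                        paste(signif(trace, 8), collapse = " -> ")),
                 "explor_convergence_error")
  info <- crossprod(X, X * (w * p * (1 - p)))
  se <- sqrt(diag(solve(info)))
  fit <- new_model_fit(colnames(X), drop(beta), se, n_obs = n,
                       converged = converged, n_iter = iter,
                       method = "logistic")
  fit$loglik_trace <- trace
  fit$loglik <- trace[length(trace)]
  fit
}
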