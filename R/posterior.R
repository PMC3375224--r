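# Log-posterior of the Poisson APC model at fixed RW2 precisions, and its
# gradient / mode. The Metropolis-within-Gibbs sampler (src/sampler.cpp)
# integrates over the precisions; the R-side functions here are used for
# initialization, the MLE bridge, and as the reference the compiled code is
# tested against.

#' Log-posterior of the Poisson APC model
#'
#' Poisson log-likelihood (up to the `y!` constant),
#' \eqn{\sum_{cells} [y \eta - E e^{\eta}]}, plus the RW2 log-priors of every
#' included effect vector (reconstructed with references at zero), the normal
#' priors on intercept and sex offset, and (optionally) the Gamma hyperprior
#' density at the supplied precisions.
#'
#' @param beta Free parameter vector of length `design$n_par`.
#' @param table A [lexis_table()].
#' @param design A [build_design()] object.
#' @param priors A [prior_spec()] object.
#' @param precisions Named numeric vector of RW2 precisions, one per
#'   `design$rw2_terms` (a scalar is recycled).
#' @param include_hyperprior Add the Gamma log-density of `precisions`
#'   (default `TRUE`).
#' @param parts If `TRUE`, return `list(loglik, logprior)` instead of their
#'   sum.
#' @return Scalar log-posterior (finite for finite inputs), or a list when
#'   `parts = TRUE`.
#' @export
log_posterior <- function(beta, table, design, priors = prior_spec(),
                          precisions = 100, include_hyperprior = TRUE,
                          parts = FALSE) {
  stopifnot(is_apc_design(design))
  beta <- as.numeric(beta)
  if (length(beta) != design$n_par) {
    stop("beta must have length ", design$n_par)
  }
  if (any(!is.finite(beta))) stop("non-finite parameter values")
  precisions <- expand_precisions(precisions, design)
  tv <- table_vectors(table, design)
  eta <- as.numeric(design$X %*% beta)
  ll <- sum(tv$y * eta - tv$E * exp(eta))
  lp <- 0
  for (t in design$rw2_terms) {
    x <- reconstruct_full(design, beta, t)
    lp <- lp + rw2_log_prior(x, precisions[[t]], priors$baseline_sd)
    if (include_hyperprior) {
      lp <- lp + stats::dgamma(precisions[[t]], shape = priors$rw2_shape,
                               rate = priors$rw2_rate, log = TRUE)
    }
  }
  lp <- lp + stats::dnorm(beta[1], 0, priors$intercept_sd, log = TRUE)
  sx <- design$index_map[["sex"]]
  if (!is.null(sx)) {
    lp <- lp + stats::dnorm(beta[sx], 0, priors$sex_offset_sd, log = TRUE)
  }
  if (parts) list(loglik = ll, logprior = lp) else ll + lp
}

expand_precisions <- function(precisions, design) {
  terms <- design$rw2_terms
  if (length(precisions) == 1L && is.null(names(precisions))) {
    precisions <- stats::setNames(rep(as.numeric(precisions), length(terms)),
                                  terms)
  }
  if (!all(terms %in% names(precisions))) {
    stop("precisions must be named for terms: ", paste(terms, collapse = ", "))
  }
  if (any(!is.finite(unlist(precisions[terms]))) ||
      any(unlist(precisions[terms]) <= 0)) {
    stop("precisions must be positive")
  }
  as.list(precisions[terms])
}

# analytic gradient of log_posterior w.r.t. beta (hyperprior term constant)
log_posterior_grad <- function(beta, table, design, priors = prior_spec(),
                               precisions = 100) {
  precisions <- expand_precisions(precisions, design)
  tv <- table_vectors(table, design)
  eta <- as.numeric(design$X %*% beta)
  g <- as.numeric(crossprod(design$X, tv$y - tv$E * exp(eta)))
  for (t in design$rw2_terms) {
    map <- design$index_map[[t]]
    x <- reconstruct_full(design, beta, t)
    n <- length(x)
    gx <- numeric(n)
    if (n >= 3L) {
      d <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]
      tau <- precisions[[t]]
      gx[1:(n - 2)] <- gx[1:(n - 2)] - tau * d
      gx[2:(n - 1)] <- gx[2:(n - 1)] + 2 * tau * d
      gx[3:n] <- gx[3:n] - tau * d
    }
    gx[seq_len(min(2L, n))] <- gx[seq_len(min(2L, n))] -
      x[seq_len(min(2L, n))] / priors$baseline_sd^2
    ok <- !is.na(map)
    g[map[ok]] <- g[map[ok]] + gx[ok]
  }
  g[1] <- g[1] - beta[1] / priors$intercept_sd^2
  sx <- design$index_map[["sex"]]
  if (!is.null(sx)) g[sx] <- g[sx] - beta[sx] / priors$sex_offset_sd^2
  g
}

# Gaussian (Laplace) approximation at a given point: Hessian of the negative
# log-posterior (fixed precisions) and the lower Cholesky factor of its
# inverse, used to precondition the sampler's full-vector proposals.
laplace_chol <- function(table, design, priors, precisions, beta) {
  precisions <- expand_precisions(precisions, design)
  tv <- table_vectors(table, design)
  w <- as.numeric(tv$E * exp(design$X %*% beta))
  H <- crossprod(design$X, design$X * w)
  for (t in design$rw2_terms) {
    map <- design$index_map[[t]]
    n <- length(map)
    P <- matrix(0, n, n)
    if (n >= 3L) {
      D <- diff(diag(n), differences = 2)
      P <- precisions[[t]] * crossprod(D)
    }
    bi <- seq_len(min(2L, n))
    P[cbind(bi, bi)] <- P[cbind(bi, bi)] + 1 / priors$baseline_sd^2
    ok <- !is.na(map)
    H[map[ok], map[ok]] <- H[map[ok], map[ok]] + P[ok, ok]
  }
  H[1, 1] <- H[1, 1] + 1 / priors$intercept_sd^2
  sx <- design$index_map[["sex"]]
  if (!is.null(sx)) H[sx, sx] <- H[sx, sx] + 1 / priors$sex_offset_sd^2
  Sigma <- solve(H)
  Sigma <- (Sigma + t(Sigma)) / 2
  t(chol(Sigma))
}

#' Posterior mode at fixed RW2 precisions
#'
#' Maximizes [log_posterior()] over the free parameters by BFGS with the
#' analytic gradient. With precisions near zero and wide baselines this is
#' the corner-constrained Poisson maximum-likelihood fit; with the default
#' precisions it provides the starting point for the MCMC chains.
#'
#' @inheritParams log_posterior
#' @param init Optional start vector (default: log crude rate for the
#'   intercept, zeros elsewhere).
#' @return List with `par`, `value` (the log-posterior at the mode) and
#'   `convergence` (0 for success, from [stats::optim()]).
#' @export
posterior_mode <- function(table, design, priors = prior_spec(),
                           precisions = 100, init = NULL) {
  tv <- table_vectors(table, design)
  if (is.null(init)) {
    init <- numeric(design$n_par)
    init[1] <- log(max(sum(tv$y), 0.5) / sum(tv$E))
  }
  fn <- function(b) -log_posterior(b, table, design, priors, precisions,
                                   include_hyperprior = FALSE)
  gr <- function(b) -log_posterior_grad(b, table, design, priors, precisions)
  opt <- stats::optim(init, fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(par = opt$par, value = -opt$value, convergence = opt$convergence)
}
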