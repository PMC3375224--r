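#' Prior specification for the Bayesian APC model
#'
#' Each smoothed effect vector (age, period, cohort, and the female deviation
#' vectors) carries a second-order Gaussian autoregressive (RW2) prior in the
#' forward direction: each level is centred on the linear extrapolation of
#' its two immediate predecessors, penalizing curvature. The RW2 precisions
#' get vague Gamma hyperpriors; the intercept and sex offset get wide normal
#' priors; the first two levels of each RW2 chain carry diffuse normal
#' baselines.
#'
#' @param rw2_shape,rw2_rate Gamma hyperprior shape and rate for each RW2
#'   precision (defaults 1 and 0.01: prior mean 100, vague).
#' @param intercept_sd,sex_offset_sd Normal prior standard deviations for the
#'   intercept and the female log-rate offset (default 10).
#' @param baseline_sd Diffuse normal sd for the first two levels of each RW2
#'   chain (default 10).
#' @return An object of class `apc_priors`.
#' @export
prior_spec <- function(rw2_shape = 1, rw2_rate = 0.01, intercept_sd = 10,
                       sex_offset_sd = 10, baseline_sd = 10) {
  vals <- c(rw2_shape, rw2_rate, intercept_sd, sex_offset_sd, baseline_sd)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all prior hyperparameters must be positive")
  }
  structure(list(rw2_shape = rw2_shape, rw2_rate = rw2_rate,
                 intercept_sd = intercept_sd, sex_offset_sd = sex_offset_sd,
                 baseline_sd = baseline_sd),
            class = "apc_priors")
}

#' RW2 (second-order random walk) log-prior density
#'
#' Evaluates the forward-direction RW2 prior for one effect vector:
#' \deqn{\sum_{i \ge 3} \log N(x_i \mid 2x_{i-1} - x_{i-2}, 1/\tau)}
#' plus diffuse `N(0, baseline_sd^2)` baselines on the first two levels. Up
#' to additive constants this equals
#' \eqn{-(\tau/2) \sum_i (\Delta^2 x)_i^2}: exactly linear vectors incur no
#' curvature penalty. Vectors shorter than 3 carry only the baseline terms.
#'
#' @param effect Numeric effect vector.
#' @param precision RW2 precision \eqn{\tau > 0}.
#' @param baseline_sd Diffuse sd for the first two levels (default 10).
#' @return Log-density (scalar).
#' @export
rw2_log_prior <- function(effect, precision, baseline_sd = 10) {
  effect <- as.numeric(effect)
  if (any(!is.finite(effect))) stop("non-finite effect vector")
  if (!is.finite(precision) || precision <= 0) stop("precision must be > 0")
  n <- length(effect)
  lp <- sum(stats::dnorm(effect[seq_len(min(2L, n))], 0, baseline_sd,
                         log = TRUE))
  if (n >= 3L) {
    pred <- 2 * effect[2:(n - 1)] - effect[1:(n - 2)]
    lp <- lp + sum(stats::dnorm(effect[3:n], pred, 1 / sqrt(precision),
                                log = TRUE))
  }
  lp
}
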