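#' MCMC configuration
#'
#' The reporting defaults mirror the scale of the registry analysis: 5
#' concurrent chains, 10,000 burn-in iterations and 40,000 retained samples
#' per chain. Tests and examples use scaled-down values (e.g. 4 chains,
#' 1,000 / 4,000).
#'
#' @param n_chains Number of chains (>= 2, required by R-hat).
#' @param n_burn Burn-in iterations per chain (discarded; proposal scales
#'   adapt only during this phase).
#' @param n_keep Retained post-burn-in draws per chain (>= 1).
#' @param seed Integer master seed; each chain's RNG stream and distinct
#'   initial values derive deterministically from it.
#' @param thin Keep every `thin`-th post-burn-in iteration (default 1).
#' @param init_jitter_sd Standard deviation of the Gaussian jitter applied to
#'   the posterior-mode start of each chain, so chains begin at different
#'   initial values.
#' @param target_accept Per-coordinate acceptance rate targeted by the
#'   burn-in adaptation (default 0.44, the scalar random-walk optimum).
#' @param fixed_precisions Optional named vector of RW2 precisions to hold
#'   fixed instead of sampling (names among the design's RW2 terms); mainly
#'   for sensitivity and shrinkage checks.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 5L, n_burn = 10000L, n_keep = 40000L,
                        seed = 1L, thin = 1L, init_jitter_sd = 0.1,
                        target_accept = 0.44, fixed_precisions = NULL) {
  n_chains <- as.integer(n_chains)
  n_keep <- as.integer(n_keep)
  if (is.na(n_chains) || n_chains < 2L) {
    stop("n_chains must be >= 2 (R-hat needs multiple chains)")
  }
  if (is.na(n_keep) || n_keep < 1L) stop("n_keep must be >= 1")
  structure(list(n_chains = n_chains, n_burn = as.integer(n_burn),
                 n_keep = n_keep, seed = as.integer(seed),
                 thin = as.integer(thin),
                 init_jitter_sd = init_jitter_sd,
                 target_accept = target_accept,
                 fixed_precisions = fixed_precisions),
            class = "mcmc_config")
}

new_apc_samples <- function(chains, design, priors, config, mode = NULL) {
  structure(list(chains = chains, design = design, priors = priors,
                 config = config, mode = mode,
                 par_names = design$par_names,
                 prec_names = paste0("tau_", design$rw2_terms)),
            class = "apc_samples")
}

#' Run the MCMC sampler for a Poisson APC model
#'
#' Samples the free parameters and RW2 precisions by adaptive
#' Metropolis-within-Gibbs: Gaussian random-walk proposals per coordinate
#' (scales adapted during burn-in only, then frozen to preserve detailed
#' balance) and conjugate Gamma Gibbs updates for the precisions. Chains are
#' initialized at the posterior mode plus chain-specific Gaussian jitter and
#' run on separate RNG streams derived from the master seed, so the result is
#' fully reproducible from `(table, design, priors, config)`.
#'
#' @param table A [lexis_table()].
#' @param design A [build_design()] object.
#' @param priors A [prior_spec()] object.
#' @param config An [mcmc_config()] object.
#' @return An object of class `apc_samples`: per-chain draws (`n_keep x
#'   n_par`), precision draws, the Poisson log-likelihood (up to the `y!`
#'   constant) of every stored draw, acceptance rates and frozen proposal
#'   scales.
#' @export
run_mcmc <- function(table, design, priors = prior_spec(),
                     config = mcmc_config()) {
  stopifnot(is_lexis_table(table), is_apc_design(design),
            inherits(config, "mcmc_config"))
  tv <- table_vectors(table, design)
  fixed <- config$fixed_precisions
  if (!is.null(fixed) && !all(names(fixed) %in% design$rw2_terms)) {
    stop("fixed_precisions names must be among: ",
         paste(design$rw2_terms, collapse = ", "))
  }
  prec0 <- vapply(design$rw2_terms, function(t) {
    if (!is.null(fixed) && t %in% names(fixed)) as.numeric(fixed[[t]])
    else priors$rw2_shape / priors$rw2_rate
  }, numeric(1))
  mode_prec <- stats::setNames(as.list(prec0), design$rw2_terms)
  mode <- posterior_mode(table, design, priors, precisions = mode_prec)
  if (mode$convergence != 0) {
    warning("posterior-mode initialization did not fully converge (optim code ",
            mode$convergence, ")")
  }
  term_of <- rep(-1L, design$n_par)
  pos_of <- rep(-1L, design$n_par)
  rw2_list <- vector("list", length(design$rw2_terms))
  for (ti in seq_along(design$rw2_terms)) {
    t <- design$rw2_terms[ti]
    map <- design$index_map[[t]]
    ok <- !is.na(map)
    term_of[map[ok]] <- ti - 1L
    pos_of[map[ok]] <- which(ok) - 1L
    rw2_list[[ti]] <- list(map = ifelse(is.na(map), -1L, map - 1L),
                           shape = priors$rw2_shape, rate = priors$rw2_rate,
                           fixed = !is.null(fixed) &&
                             t %in% names(fixed))
  }
  normal_sd <- rep(priors$intercept_sd, design$n_par)
  sx <- design$index_map[["sex"]]
  if (!is.null(sx)) normal_sd[sx] <- priors$sex_offset_sd
  scale0 <- rep(0.05, design$n_par)
  Lprop <- laplace_chol(table, design, priors, mode_prec, mode$par)
  gscale0 <- 2.38 / sqrt(design$n_par)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * (ch - 1L))
    init <- mode$par + stats::rnorm(design$n_par, 0, config$init_jitter_sd)
    res <- apc_sampler_cpp(tv$y, tv$E, design$X, rw2_list, term_of, pos_of,
                           normal_sd, priors$baseline_sd, init, prec0,
                           scale0, Lprop, gscale0, 2L,
                           config$n_burn, config$n_keep, config$thin,
                           config$target_accept, TRUE)
    colnames(res$draws) <- design$par_names
    colnames(res$prec) <- paste0("tau_", design$rw2_terms)
    chains[[ch]] <- res
  }
  new_apc_samples(chains, design, priors, config, mode)
}

#' @export
print.apc_samples <- function(x, ...) {
  cat("APC posterior samples: ", length(x$chains), " chains x ",
      nrow(x$chains[[1]]$draws), " draws of ", x$design$n_par,
      " parameters (+", length(x$prec_names), " RW2 precisions); max R-hat ",
      round(max(rhat_all(x), na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

is_apc_samples <- function(x) inherits(x, "apc_samples")

# pooled draws across chains: (n_chains * n_keep) x n_par, plus precisions
pooled_draws <- function(samples, what = c("beta", "prec", "loglik")) {
  what <- match.arg(what)
  key <- switch(what, beta = "draws", prec = "prec", loglik = "loglik")
  out <- lapply(samples$chains, `[[`, key)
  if (what == "loglik") unlist(out) else do.call(rbind, out)
}

#' Gelman-Rubin potential scale reduction factor (R-hat)
#'
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \; W + B/n}{W}}}
#' with `W` the mean within-chain variance and `B` the between-chain variance
#' of the chain means (times `n`). Values near 1 indicate mixing; reports in
#' this package flag parameters above 1.1. If every chain has zero within-
#' chain variance the statistic is undefined and `NA` is returned (a constant
#' chain is not evidence of convergence).
#'
#' @param x Either a numeric matrix with one column per chain (iterations in
#'   rows), or an `apc_samples` object (then `parameter` selects the column
#'   by name, e.g. `"cohort[3]"` or `"tau_cohort"`).
#' @param parameter Parameter name, when `x` is an `apc_samples` object.
#' @return Scalar R-hat (possibly `NA`).
#' @export
rhat <- function(x, parameter = NULL) {
  if (is_apc_samples(x)) {
    if (is.null(parameter)) stop("parameter name required for apc_samples")
    x <- chain_matrix(x, parameter)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat needs at least 2 chains")
  if (nrow(x) < 2L) stop("R-hat needs at least 2 draws per chain")
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

chain_matrix <- function(samples, parameter) {
  if (parameter %in% samples$par_names) {
    sapply(samples$chains, function(ch) ch$draws[, parameter])
  } else if (parameter %in% samples$prec_names) {
    sapply(samples$chains, function(ch) ch$prec[, parameter])
  } else {
    stop("unknown parameter: ", parameter)
  }
}

#' R-hat for every sampled parameter
#'
#' @param samples An `apc_samples` object.
#' @return Named numeric vector over free parameters and RW2 precisions.
#' @export
rhat_all <- function(samples) {
  stopifnot(is_apc_samples(samples))
  pars <- c(samples$par_names, samples$prec_names)
  stats::setNames(vapply(pars, function(p) rhat(samples, p), numeric(1)),
                  pars)
}

# posterior draws of one full effect curve (levels as columns, zeros at
# references). sex = "M": male curve; "F": male curve + female deviation
# (the deviation is zero when the interaction is not in the model).
curve_draws <- function(samples, term, sex = "M") {
  stopifnot(is_apc_samples(samples))
  term <- match.arg(term, c("age", "period", "cohort"))
  sex <- match.arg(sex, c("M", "F"))
  design <- samples$design
  map <- design$index_map[[term]]
  if (is.null(map)) stop("term '", term, "' not in the fitted design")
  beta <- pooled_draws(samples, "beta")
  out <- matrix(0, nrow(beta), length(map))
  ok <- !is.na(map)
  out[, ok] <- beta[, map[ok], drop = FALSE]
  if (sex == "F") {
    dmap <- design$index_map[[paste0("sex_", term)]]
    if (!is.null(dmap)) {
      okd <- !is.na(dmap)
      out[, okd] <- out[, okd, drop = FALSE] + beta[, dmap[okd], drop = FALSE]
    }
  }
  out
}

level_labels <- function(design, term) {
  switch(term,
         age = age_labels(design$grid),
         period = period_labels(design$grid),
         cohort = as.character(cohort_labels(design$grid)$label))
}

#' Posterior summaries of the effect curves
#'
#' Pooled-chain posterior means and equal-tailed 95% (or `level`) credible
#' intervals for every level of every fitted effect, on the log scale and as
#' relative risks `exp(effect)` against the reference levels (which sit at RR
#' exactly 1 with a zero-width interval). Female curves are male curve plus
#' female deviation, i.e. relative to the common male reference point; the
#' female-vs-male log offset is summarized separately in `$scalars`.
#'
#' @param samples An `apc_samples` object.
#' @param level Credible level (default 0.95).
#' @return An object of class `apc_effect_summary`: `$effects` (data frame
#'   with term, sex, level index/label, posterior mean, interval and RR) and
#'   `$scalars` (intercept, sex offset, RW2 precisions).
#' @export
summarize_effects <- function(samples, level = 0.95) {
  stopifnot(is_apc_samples(samples))
  a <- (1 - level) / 2
  design <- samples$design
  sexes <- if (length(design$sex_terms)) c("M", "F") else "M"
  rows <- list()
  for (term in intersect(c("age", "period", "cohort"), design$terms)) {
    map <- design$index_map[[term]]
    labs <- level_labels(design, term)
    for (sex in sexes) {
      cd <- curve_draws(samples, term, sex)
      qs <- apply(cd, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
      rows[[paste(term, sex)]] <- data.frame(
        term = term, sex = sex, level_index = seq_along(map),
        label = labs, mean = colMeans(cd), lower = qs[1, ], upper = qs[2, ],
        reference = is.na(map))
    }
  }
  eff <- do.call(rbind, rows)
  rownames(eff) <- NULL
  eff$rr <- exp(eff$mean)
  eff$rr_lower <- exp(eff$lower)
  eff$rr_upper <- exp(eff$upper)
  beta <- pooled_draws(samples, "beta")
  prec <- pooled_draws(samples, "prec")
  sc <- cbind(beta[, 1, drop = FALSE],
              if (!is.null(design$index_map[["sex"]]))
                beta[, design$index_map[["sex"]], drop = FALSE],
              prec)
  colnames(sc)[1] <- "intercept"
  if (!is.null(design$index_map[["sex"]])) colnames(sc)[2] <- "sex_offset"
  scalars <- data.frame(
    parameter = colnames(sc),
    mean = colMeans(sc),
    lower = apply(sc, 2, stats::quantile, probs = a, names = FALSE),
    upper = apply(sc, 2, stats::quantile, probs = 1 - a, names = FALSE))
  rownames(scalars) <- NULL
  structure(list(effects = eff, scalars = scalars, level = level,
                 model = design_label(design)),
            class = "apc_effect_summary")
}

#' @export
print.apc_effect_summary <- function(x, ...) {
  cat("Effect summaries for model ", x$model, " (", 100 * x$level,
      "% credible intervals)\n", sep = "")
  print(utils::head(x$effects, 12), digits = 3)
  if (nrow(x$effects) > 12) cat("... (", nrow(x$effects), " rows)\n", sep = "")
  invisible(x)
}

#' Export posterior draws as delimited text
#'
#' Long format with columns `chain`, `iteration`, `parameter`, `value`
#' (comma-separated, header included), covering the free parameters and the
#' RW2 precisions.
#'
#' @param samples An `apc_samples` object.
#' @param path File path.
#' @param thin Write every `thin`-th stored draw (default 1).
#' @return `path`, invisibly.
#' @export
write_draws <- function(samples, path, thin = 1L) {
  stopifnot(is_apc_samples(samples))
  rows <- lapply(seq_along(samples$chains), function(ch) {
    d <- cbind(samples$chains[[ch]]$draws, samples$chains[[ch]]$prec)
    keep <- seq(1L, nrow(d), by = as.integer(thin))
    data.frame(chain = ch, iteration = keep,
               parameter = rep(colnames(d), each = length(keep)),
               value = as.numeric(d[keep, ]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
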