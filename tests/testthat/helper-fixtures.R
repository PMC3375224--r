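# shared fixtures and independent (naive) oracles used across the suite

paper_grid <- function() make_grid(20, 5, 14, 1976, 5, 6)
small_grid <- function() make_grid(60, 5, 6, 1980, 5, 4)

# brute-force RW2 log prior: explicit loop over the conditional densities
naive_rw2_lp <- function(x, tau, bsd = 10) {
  lp <- 0
  for (i in seq_len(min(2, length(x)))) {
    lp <- lp + dnorm(x[i], 0, bsd, log = TRUE)
  }
  if (length(x) >= 3) {
    for (i in 3:length(x)) {
      lp <- lp + dnorm(x[i], 2 * x[i - 1] - x[i - 2], sqrt(1 / tau),
                       log = TRUE)
    }
  }
  lp
}

# term-by-term log posterior computed cell by cell with explicit lookups,
# never through the design matrix
naive_log_posterior <- function(beta, table, design, priors, precisions) {
  g <- design$grid
  precisions <- rep_len(as.numeric(precisions), length(design$rw2_terms))
  names(precisions) <- design$rw2_terms
  lookup <- function(term, lvl) {
    j <- design$index_map[[term]][lvl]
    if (is.na(j)) 0 else beta[j]
  }
  ll <- 0
  for (s in 1:2) {
    for (p in seq_len(g$n_period)) {
      for (a in seq_len(g$n_age)) {
        eta <- beta[1]
        for (t in intersect(c("age", "period", "cohort"), design$terms)) {
          lvl <- switch(t, age = a, period = p,
                        cohort = cohort_index(g, a, p))
          eta <- eta + lookup(t, lvl)
        }
        if (s == 2L) {
          if (!is.null(design$index_map$sex)) {
            eta <- eta + beta[design$index_map$sex]
          }
          for (t in setdiff(design$sex_terms, "offset")) {
            lvl <- switch(t, age = a, period = p,
                          cohort = cohort_index(g, a, p))
            eta <- eta + lookup(paste0("sex_", t), lvl)
          }
        }
        y <- table$deaths[a, p, s]
        E <- table$exposure[a, p, s]
        ll <- ll + y * eta - E * exp(eta)
      }
    }
  }
  lp <- 0
  for (t in design$rw2_terms) {
    map <- design$index_map[[t]]
    x <- numeric(length(map))
    for (i in seq_along(map)) if (!is.na(map[i])) x[i] <- beta[map[i]]
    lp <- lp + naive_rw2_lp(x, precisions[[t]], priors$baseline_sd) +
      dgamma(precisions[[t]], shape = priors$rw2_shape,
             rate = priors$rw2_rate, log = TRUE)
  }
  lp <- lp + dnorm(beta[1], 0, priors$intercept_sd, log = TRUE)
  if (!is.null(design$index_map$sex)) {
    lp <- lp + dnorm(beta[design$index_map$sex], 0, priors$sex_offset_sd,
                     log = TRUE)
  }
  ll + lp
}

# cell-by-cell saturated Poisson deviance
naive_deviance <- function(table, design, beta) {
  g <- design$grid
  dev <- 0
  for (s in 1:2) {
    for (p in seq_len(g$n_period)) {
      for (a in seq_len(g$n_age)) {
        i <- a + (p - 1) * g$n_age + (s - 1) * g$n_age * g$n_period
        eta <- sum(design$X[i, ] * beta)
        mu <- table$exposure[a, p, s] * exp(eta)
        y <- table$deaths[a, p, s]
        dev <- dev + 2 * ((if (y > 0) y * log(y / mu) else 0) - (y - mu))
      }
    }
  }
  dev
}

# Gelman-Rubin statistic straight from its definition
naive_rhat <- function(mat) {
  n <- nrow(mat)
  W <- mean(apply(mat, 2, var))
  B <- n * var(colMeans(mat))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# wrap externally supplied draws as an apc_samples object so the posterior
# summaries can be exercised on known distributions
fake_samples <- function(design, draws_list, prec_list = NULL) {
  nt <- length(design$rw2_terms)
  chains <- lapply(seq_along(draws_list), function(i) {
    d <- draws_list[[i]]
    colnames(d) <- design$par_names
    pr <- if (is.null(prec_list)) {
      matrix(100, nrow(d), nt)
    } else prec_list[[i]]
    if (nt > 0) colnames(pr) <- paste0("tau_", design$rw2_terms)
    list(draws = d, prec = pr, loglik = numeric(nrow(d)),
         accept_rate = rep(NA_real_, ncol(d)), scales = rep(1, ncol(d)))
  })
  cfg <- mcmc_config(n_chains = max(2L, length(draws_list)),
                     n_burn = 0L, n_keep = nrow(draws_list[[1]]), seed = 1L)
  apcmort:::new_apc_samples(chains, design, prior_spec(), cfg)
}

# small deterministic record set for tabulation tests
random_records <- function(n, seed, grid = paper_grid()) {
  set.seed(seed)
  data.frame(
    year = sample(seq(grid$period_start - 3,
                      grid$period_start + grid$n_period * grid$period_width + 2),
                  n, replace = TRUE),
    age = sample(15:99, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    icd_version = sample(c(9L, 10L), n, replace = TRUE),
    code = sample(c("038.9", "38", "A41.9", "A02.1", "J18.9", "480.1",
                    "C50", "I21", "J45"), n, replace = TRUE))
}
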