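scaled_cfg <- function(seed = 1L, n_chains = 4L) {
  mcmc_config(n_chains = n_chains, n_burn = 500L, n_keep = 1500L, seed = seed)
}

test_that("the sampler is bit-reproducible from its seed", {
  g <- small_grid()
  tab <- simulate_table(make_scenario("null", grid = g, exposure_scale = 1e4,
                                      seed = 4))
  d <- build_design(g, c("age", "period", "cohort"))
  cfg <- mcmc_config(n_chains = 2, n_burn = 200, n_keep = 300, seed = 11)
  f1 <- run_mcmc(tab, d, prior_spec(), cfg)
  f2 <- run_mcmc(tab, d, prior_spec(), cfg)
  expect_identical(f1$chains[[1]]$draws, f2$chains[[1]]$draws)
  expect_identical(f1$chains[[2]]$prec, f2$chains[[2]]$prec)
  # chains start from different initial values
  expect_false(identical(f1$chains[[1]]$draws[1, ], f1$chains[[2]]$draws[1, ]))
})

test_that("stored log-likelihoods match an independent recomputation", {
  g <- small_grid()
  tab <- simulate_table(make_scenario("septicaemia_like", grid = g,
                                      exposure_scale = 2e4, seed = 6))
  d <- build_design(g, c("age", "period", "cohort"), "offset")
  cfg <- mcmc_config(n_chains = 2, n_burn = 200, n_keep = 100, seed = 3)
  fit <- run_mcmc(tab, d, prior_spec(), cfg)
  tv <- apcmort:::table_vectors(tab, d)
  ch <- fit$chains[[1]]
  for (i in c(1, 50, 100)) {
    eta <- as.numeric(d$X %*% ch$draws[i, ])
    expect_equal(ch$loglik[i], sum(tv$y * eta - tv$E * exp(eta)),
                 tolerance = 1e-8)
  }
})

test_that("the intercept-only posterior matches the Gamma-Poisson closed form", {
  # one cell per sex, exposure 1000 each, shared log-rate: under an
  # effectively flat prior on the log scale the rate posterior is
  # Gamma(y_total, 2 * 1000), mean y_total / 2000
  g <- make_grid(0, 5, 1, 2000, 5, 1)
  set.seed(44)
  y <- rpois(2, 1000 * 0.5)
  tab <- lexis_table(g, array(y, c(1, 1, 2)), array(1000, c(1, 1, 2)))
  d <- build_design(g, "age")
  fit <- run_mcmc(tab, d, prior_spec(), scaled_cfg(seed = 2))
  lam <- exp(apcmort:::pooled_draws(fit, "beta")[, 1])
  closed <- sum(y) / 2000
  expect_lt(abs(mean(lam) - closed) / closed, 0.02)
  expect_lt(abs(sd(lam) - sqrt(sum(y)) / 2000) / (sqrt(sum(y)) / 2000), 0.15)
})

test_that("a null-scenario fit on a small grid converges (R-hat < 1.1)", {
  g <- small_grid()
  tab <- simulate_table(make_scenario("null", grid = g, exposure_scale = 1e5,
                                      seed = 10))
  d <- build_design(g, c("age", "period", "cohort"), "offset")
  fit <- run_mcmc(tab, d, prior_spec(), scaled_cfg(seed = 5))
  r <- rhat_all(fit)
  expect_true(all(r < 1.1, na.rm = TRUE))
  # and the posterior mean intercept sits near the flat truth
  s <- summarize_effects(fit)
  ic <- s$scalars[s$scalars$parameter == "intercept", ]
  expect_gt(ic$upper, log(2e-4))
  expect_lt(ic$lower, log(2e-4))
})

test_that("rhat follows the Gelman-Rubin formula and its limits", {
  two <- cbind(1:4, 1:4)
  expect_equal(rhat(two), sqrt(3 / 4))   # B = 0 leaves sqrt((n-1)/n)
  set.seed(12)
  m <- matrix(rnorm(40), 20, 2)
  expect_equal(rhat(m), naive_rhat(m), tolerance = 1e-12)
  # same long stream: approaches 1 from either side
  stream <- matrix(rnorm(20000), 10000, 2)
  expect_lt(abs(rhat(stream) - 1), 0.02)
  # separated chains blow up
  expect_gt(rhat(cbind(rnorm(50), rnorm(50) + 100)), 5)
  # all-constant chains are undefined, not 1
  expect_true(is.na(rhat(cbind(rep(2, 10), rep(2, 10)))))
  expect_error(rhat(matrix(1:5, 5, 1)), "2 chains")
})

test_that("effect summaries pin references at RR 1 and recover known quantiles", {
  g <- small_grid()
  d <- build_design(g, c("age", "period", "cohort"), "offset")
  set.seed(9)
  mu <- 0.4; sig <- 0.2
  draws1 <- matrix(rnorm(4000 * d$n_par, 0, 0.01), 4000, d$n_par)
  draws2 <- matrix(rnorm(4000 * d$n_par, 0, 0.01), 4000, d$n_par)
  j <- d$index_map$cohort[2]
  draws1[, j] <- rnorm(4000, mu, sig)
  draws2[, j] <- rnorm(4000, mu, sig)
  fs <- fake_samples(d, list(draws1, draws2))
  s <- summarize_effects(fs)
  refs <- s$effects[s$effects$reference & s$effects$term == "period", ]
  expect_true(all(refs$rr == 1))
  expect_true(all(refs$rr_lower == 1 & refs$rr_upper == 1))  # zero width
  row <- s$effects[s$effects$term == "cohort" & s$effects$level_index == 2 &
                     s$effects$sex == "M", ]
  expect_equal(row$mean, mu, tolerance = 0.02)
  expect_equal(row$lower, mu - 1.96 * sig, tolerance = 0.03)
  expect_equal(row$upper, mu + 1.96 * sig, tolerance = 0.03)
  # constant draws give a degenerate interval at that constant
  draws1[, j] <- 0.7; draws2[, j] <- 0.7
  s2 <- summarize_effects(fake_samples(d, list(draws1, draws2)))
  row2 <- s2$effects[s2$effects$term == "cohort" & s2$effects$level_index == 2 &
                       s2$effects$sex == "M", ]
  expect_equal(c(row2$mean, row2$lower, row2$upper), rep(0.7, 3))
})

test_that("increasing the RW2 precision never inflates curvature posteriors", {
  g <- small_grid()
  tab <- simulate_table(make_scenario("septicaemia_like", grid = g,
                                      exposure_scale = 1e5, seed = 14))
  d <- build_design(g, c("age", "period", "cohort"))
  vars <- sapply(c(1, 100, 1e4), function(tau) {
    cfg <- mcmc_config(n_chains = 2, n_burn = 500, n_keep = 2000, seed = 8,
                       fixed_precisions = c(age = tau, period = tau,
                                            cohort = tau))
    fit <- run_mcmc(tab, d, prior_spec(), cfg)
    cd <- apcmort:::curve_draws(fit, "cohort", "M")
    n <- ncol(cd)
    D <- cd[, 3:n] - 2 * cd[, 2:(n - 1)] + cd[, 1:(n - 2)]
    mean(apply(D, 2, var))
  })
  # allow a small Monte-Carlo slack on an otherwise monotone ladder
  expect_lt(vars[2], vars[1] * 1.05)
  expect_lt(vars[3], vars[2] * 1.05)
})

test_that("draws export to the long delimited format and back", {
  g <- small_grid()
  tab <- simulate_table(make_scenario("null", grid = g, exposure_scale = 1e4,
                                      seed = 4))
  d <- build_design(g, c("age", "period", "cohort"))
  cfg <- mcmc_config(n_chains = 2, n_burn = 100, n_keep = 50, seed = 11)
  fit <- run_mcmc(tab, d, prior_spec(), cfg)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_draws(fit, path)
  df <- read.csv(path)
  expect_setequal(unique(df$parameter), c(d$par_names, fit$prec_names))
  expect_equal(nrow(df), 2 * 50 * (d$n_par + length(fit$prec_names)))
  one <- df$value[df$chain == 1 & df$parameter == "intercept"]
  expect_equal(one, unname(fit$chains[[1]]$draws[, "intercept"]))
})
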