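test_that("deviance has its closed forms and matches the brute-force oracle", {
  g <- make_grid(0, 5, 1, 2000, 5, 1)
  tab <- lexis_table(g, array(c(2L, 0L), c(1, 1, 2)), array(1, c(1, 1, 2)))
  d <- build_design(g, "age")
  # mu = 1 in both cells: male cell contributes 2(2 ln 2 - 1), the empty
  # female cell contributes 2 mu
  expect_equal(deviance_poisson(tab, d, 0), 2 * (2 * log(2) - 1) + 2)
  # saturated fit on equal counts is exactly zero
  tab2 <- lexis_table(g, array(5L, c(1, 1, 2)), array(10, c(1, 1, 2)))
  expect_equal(deviance_poisson(tab2, d, log(0.5)), 0)
  expect_gt(deviance_poisson(tab2, d, log(0.4)), 0)
  # random small tables against the cell-by-cell oracle
  set.seed(23)
  gs <- small_grid()
  ds <- build_design(gs, c("age", "period", "cohort"), "offset")
  tabr <- simulate_table(make_scenario("septicaemia_like", grid = gs,
                                       exposure_scale = 2e4, seed = 7))
  for (i in 1:5) {
    beta <- rnorm(ds$n_par, 0, 0.4)
    expect_equal(deviance_poisson(tabr, ds, beta),
                 naive_deviance(tabr, ds, beta), tolerance = 1e-10)
  }
})

test_that("DIC reduces to hand arithmetic on tiny posteriors", {
  g <- make_grid(0, 5, 1, 2000, 5, 1)
  tab <- lexis_table(g, array(c(3L, 1L), c(1, 1, 2)), array(10, c(1, 1, 2)))
  d <- build_design(g, "age")
  # degenerate posterior: every draw identical -> pD = 0, DIC = Dbar
  const <- matrix(log(0.2), 40, 1)
  fs <- fake_samples(d, list(const, const))
  r <- dic(fs, tab)
  expect_equal(r$pD, 0)
  expect_equal(r$DIC, r$Dbar)
  expect_false(r$pD_negative)
  # two distinct draws, hand-computed
  b <- c(log(0.2), log(0.3))
  fs2 <- fake_samples(d, list(matrix(b[1], 1, 1), matrix(b[2], 1, 1)))
  r2 <- dic(fs2, tab)
  devs <- vapply(b, function(x) deviance_poisson(tab, d, x), numeric(1))
  Dbar <- mean(devs)
  Dhat <- deviance_poisson(tab, d, mean(b))
  expect_equal(r2$Dbar, Dbar)
  expect_equal(r2$Dhat, Dhat)
  expect_equal(r2$pD, Dbar - Dhat)
  expect_equal(r2$DIC, 2 * Dbar - Dhat)
  expect_equal(r2$DIC, r2$Dhat + 2 * r2$pD)  # algebraic identity
})

test_that("a menu of one returns that model as the winner", {
  g <- small_grid()
  tab <- simulate_table(make_scenario("null", grid = g, exposure_scale = 1e4,
                                      seed = 31))
  cfg <- mcmc_config(n_chains = 2, n_burn = 300, n_keep = 500, seed = 2)
  mr <- fit_model_menu(tab, menu = list(AP = list(terms = c("age", "period"),
                                                  sex_terms = character())),
                       config = cfg)
  expect_equal(mr$winner, "AP")
  expect_true(mr$table$winner[1])
  expect_equal(mr$table$DIC, mr$table$Dhat + 2 * mr$table$pD,
               tolerance = 1e-8)
})

test_that("a failing menu entry is recorded without sinking the menu", {
  g <- small_grid()
  tab <- simulate_table(make_scenario("null", grid = g, exposure_scale = 1e4,
                                      seed = 32))
  cfg <- mcmc_config(n_chains = 2, n_burn = 200, n_keep = 300, seed = 3)
  menu <- list(bad = list(terms = c("age", "cohort"),
                          reference_periods = c(1, 2),
                          sex_terms = character()),
               A = list(terms = "age", sex_terms = character()))
  mr <- fit_model_menu(tab, menu = menu, config = cfg)
  expect_equal(mr$winner, "A")
  expect_true(is.na(mr$table$DIC[mr$table$model == "bad"]))
  expect_match(mr$table$error[mr$table$model == "bad"], "period")
})

test_that("on curvature-free data the sex interaction is not strongly preferred", {
  # flat truth: the interaction model should not beat the offset-only model
  # by a material DIC margin in most replicates
  wins <- 0L
  for (r in 1:5) {
    tab <- simulate_table(make_scenario("null", exposure_scale = 1e5,
                                        seed = 500 + r))
    cfg <- mcmc_config(n_chains = 2, n_burn = 500, n_keep = 1500,
                       seed = 600 + r)
    menu <- list(
      off = list(terms = c("age", "period", "cohort"), sex_terms = "offset"),
      int = list(terms = c("age", "period", "cohort"),
                 sex_terms = c("offset", "age", "period", "cohort")))
    mr <- fit_model_menu(tab, menu = menu, config = cfg)
    t <- mr$table
    gap <- t$DIC[t$model == "int"] - t$DIC[t$model == "off"]
    if (gap > -10) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
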