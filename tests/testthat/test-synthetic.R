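test_that("scenarios plant the advertised curvature structure", {
  null <- make_scenario("null", exposure_scale = 1e5, seed = 7)
  for (v in c("age_eff", "period_eff", "cohort_eff", "sex_age", "sex_period",
              "sex_cohort")) {
    expect_equal(second_differences(null$effects[[v]]),
                 rep(0, length(null$effects[[v]]) - 2),
                 tolerance = 1e-12, label = v)
  }
  sep <- make_scenario("septicaemia_like", seed = 7)
  d2 <- second_differences(sep$effects$cohort_eff)
  expect_equal(sep$inflection_index, 10L)
  expect_equal(sum(abs(d2) > 1e-9), 1L)           # a single slope change
  expect_lt(d2[sep$inflection_index - 1], 0)      # and it is a downturn
  expect_equal(d2[sep$inflection_index - 1], -0.04, tolerance = 1e-9)
  d2f <- second_differences(sep$effects$sex_cohort)
  expect_equal(d2f[sep$inflection_index - 1], -0.03, tolerance = 1e-9)
  pne <- make_scenario("pneumonia_like", seed = 7)
  expect_equal(pne$effects$sex_cohort, rep(0, 19))
  expect_gt(max(second_differences(pne$effects$cohort_eff)), 0)  # upturn
  expect_error(make_scenario("plague_like"), "arg")
})

test_that("truth effects satisfy the model's reference constraints exactly", {
  sc <- make_scenario("septicaemia_like", seed = 3)
  refs <- sc$references
  eff <- sc$effects
  expect_identical(eff$age_eff[1], 0)
  expect_identical(eff$period_eff[refs$periods], c(0, 0))
  expect_identical(eff$cohort_eff[refs$cohort], 0)
  expect_identical(eff$sex_age[1], 0)
  expect_identical(eff$sex_period[refs$periods], c(0, 0))
  expect_identical(eff$sex_cohort[refs$cohort], 0)
})

test_that("constraining effects never changes the implied cell rates", {
  g <- small_grid()
  set.seed(21)
  raw <- true_effects(g, -8, rnorm(6, 0, 0.3), rnorm(4, 0, 0.2),
                      rnorm(9, 0, 0.2), sex_offset = -0.2,
                      sex_age = rnorm(6, 0, 0.1), sex_period = rnorm(4, 0, 0.1),
                      sex_cohort = rnorm(9, 0, 0.1))
  con <- constrain_effects(raw)
  expect_equal(effects_eta(con), effects_eta(raw), tolerance = 1e-12)
  refs <- default_references(g)
  expect_equal(con$period_eff[refs$periods], c(0, 0))
  expect_equal(con$cohort_eff[refs$cohort], 0)
  expect_equal(con$age_eff[1], 0)
})

test_that("simulation is deterministic in the seed and Poisson in distribution", {
  sc <- make_scenario("septicaemia_like", seed = 42)
  expect_identical(simulate_table(sc)$deaths, simulate_table(sc)$deaths)
  sc2 <- make_scenario("septicaemia_like", seed = 43)
  expect_false(identical(simulate_table(sc)$deaths, simulate_table(sc2)$deaths))

  # flat scenario at rate 1e-4 and exposure 1e6: every cell mean is 100;
  # the empirical mean over all cells must sit within 3 standard errors
  flat <- make_scenario("null", exposure_scale = 1e6, seed = 5)
  flat$effects$intercept <- log(1e-4)
  tab <- simulate_table(flat)
  n <- length(tab$deaths)
  se <- sqrt(100 / n)
  expect_lt(abs(mean(tab$deaths) - 100), 3 * se)

  # doubling the exposure doubles expected totals
  a <- make_scenario("null", exposure_scale = 1e5, seed = 8)
  b <- make_scenario("null", exposure_scale = 2e5, seed = 9)
  ratio <- sum(simulate_table(b)$deaths) / sum(simulate_table(a)$deaths)
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("single-cell draws pass a chi-square goodness-of-fit sweep", {
  # 20 seeded batches of 500 draws from one cell; the Poisson GOF test at the
  # 1% level should reject in at most 1 of 20 batches
  sc <- make_scenario("null", exposure_scale = 1e5, seed = 1)
  mu <- sc$exposure_scale * exp(sc$effects$intercept)
  rejections <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    draws <- rpois(500, mu)
    brk <- unique(quantile(qpois(seq(0.05, 0.95, by = 0.15), mu)))
    bins <- cut(draws, breaks = c(-Inf, brk, Inf))
    prob <- diff(c(0, ppois(brk, mu), 1))
    p <- suppressWarnings(chisq.test(table(bins), p = prob)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("exploding a table to records and re-tabulating is the identity", {
  sc <- make_scenario("septicaemia_like", grid = small_grid(),
                      exposure_scale = 2e4, seed = 13)
  tab <- simulate_table(sc)
  rec <- explode_to_records(tab, seed = 99)
  expect_equal(nrow(rec), sum(tab$deaths))
  back <- tabulate_records(rec, tab$grid, "septicaemia")
  expect_equal(back$deaths, unname(tab$deaths))
  expect_equal(sum(back$excluded), 0L)
  # records stay within their cell bounds: spot-check one cell
  g <- tab$grid
  cell <- rec[rec$sex == "M" & rec$age >= g$age_start &
                rec$age < g$age_start + g$age_width &
                rec$year >= g$period_start &
                rec$year < g$period_start + g$period_width, ]
  expect_equal(nrow(cell), tab$deaths[1, 1, 1])
  # empty table -> empty record list
  empty <- lexis_table(small_grid(), array(0L, c(6, 4, 2)),
                       array(1, c(6, 4, 2)))
  expect_equal(nrow(explode_to_records(empty)), 0L)
})

test_that("scenario configs round-trip through the key-value format", {
  sc <- make_scenario("pneumonia_like", grid = small_grid(),
                      exposure_scale = 5e4, seed = 17)
  path <- tempfile(fileext = ".cfg")
  on.exit(unlink(path), add = TRUE)
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$name, sc$name)
  expect_equal(back$effects, sc$effects)
  expect_equal(back$exposure_scale, sc$exposure_scale)
  expect_equal(back$seed, sc$seed)
  expect_identical(simulate_table(back)$deaths, simulate_table(sc)$deaths)
})
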