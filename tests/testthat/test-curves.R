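test_that("second differences follow their definition and kill linear terms", {
  expect_equal(second_differences(c(0, 0, 1)), 1)
  expect_equal(second_differences(2 - 0.7 * (1:9)), rep(0, 7))
  x <- c(0.2, -0.1, 0.4, 0.3, 0.9)
  expect_equal(second_differences(x + 5 * seq_along(x)),
               second_differences(x))
  expect_equal(length(second_differences(x)), 3)
  expect_error(second_differences(c(1, 2)), "length")
})

test_that("curvature reports are invariant to linear-in-index drift", {
  g <- small_grid()
  d <- build_design(g, c("age", "period", "cohort"), "offset")
  set.seed(41)
  draws <- lapply(1:2, function(i) matrix(rnorm(500 * d$n_par, 0, 0.2),
                                          500, d$n_par))
  cr0 <- curvature_report(fake_samples(d, draws), "cohort", "M")
  # drift delta * (index - reference) keeps the reference at zero, so it is
  # representable in the constrained parameterization
  delta <- 0.35
  map <- d$index_map$cohort
  drifted <- lapply(draws, function(m) {
    for (lvl in which(!is.na(map))) {
      m[, map[lvl]] <- m[, map[lvl]] + delta * (lvl - d$reference_cohort)
    }
    m
  })
  cr1 <- curvature_report(fake_samples(d, drifted), "cohort", "M")
  expect_equal(cr1$table$mean, cr0$table$mean, tolerance = 1e-12)
  expect_equal(cr1$table$p_negative, cr0$table$p_negative)
  expect_identical(cr1$downturn_indices, cr0$downturn_indices)
})

test_that("flag sets shrink monotonically in the probability threshold", {
  g <- small_grid()
  d <- build_design(g, c("age", "period", "cohort"))
  set.seed(43)
  draws <- lapply(1:2, function(i) {
    m <- matrix(rnorm(400 * d$n_par, 0, 0.05), 400, d$n_par)
    # push curvature into one cohort level so some flags appear
    m[, d$index_map$cohort[5]] <- m[, d$index_map$cohort[5]] - 0.5
    m
  })
  fs <- fake_samples(d, draws)
  for (sex in "M") {
    lo <- curvature_report(fs, "cohort", sex, prob_threshold = 0.6)
    hi <- curvature_report(fs, "cohort", sex, prob_threshold = 0.95)
    expect_true(all(hi$downturn_indices %in% lo$downturn_indices))
    expect_true(all(hi$upturn_indices %in% lo$upturn_indices))
  }
})

test_that("a degenerate linear posterior flags nothing", {
  g <- small_grid()
  d <- build_design(g, c("age", "period", "cohort"))
  base <- matrix(0, 50, d$n_par)
  map <- d$index_map$cohort
  # dyadic slope keeps the linear curve's second differences exactly zero
  for (lvl in which(!is.na(map))) {
    base[, map[lvl]] <- 0.25 * (lvl - d$reference_cohort)
  }
  cr <- curvature_report(fake_samples(d, list(base, base)), "cohort", "M")
  expect_true(all(cr$table$p_negative == 0))
  expect_true(all(cr$table$p_positive == 0))
  expect_length(cr$downturn_indices, 0)
  expect_length(cr$upturn_indices, 0)
})

test_that("sex divergence is explicit about non-estimability and exact zeros", {
  g <- small_grid()
  d <- build_design(g, c("age", "period", "cohort"), "offset")
  fs <- fake_samples(d, lapply(1:2, function(i) matrix(0.1, 20, d$n_par)))
  out <- sex_divergence(fs, "cohort")
  expect_false(out$estimable)
  expect_match(out$reason, "no sex interaction")
  # interaction present but posterior exactly zero -> zero deviation curve
  d2 <- build_design(g, c("age", "period", "cohort"),
                     c("offset", "cohort"))
  zero <- matrix(0, 20, d2$n_par)
  out2 <- sex_divergence(fake_samples(d2, list(zero, zero)), "cohort",
                         from_index = 4)
  expect_true(out2$estimable)
  expect_true(all(out2$levels$mean == 0))
  expect_equal(out2$slope$mean, 0)
  expect_false(out2$steeper_decline)
})

test_that("a planted negative deviation slope is summarized with its sign", {
  g <- small_grid()
  d <- build_design(g, c("age", "period", "cohort"), c("offset", "cohort"))
  set.seed(47)
  k <- 4L
  map <- d$index_map$sex_cohort
  draws <- lapply(1:2, function(i) {
    m <- matrix(rnorm(800 * d$n_par, 0, 0.005), 800, d$n_par)
    for (lvl in which(!is.na(map))) {
      m[, map[lvl]] <- m[, map[lvl]] - 0.05 * max(lvl - k, 0)
    }
    m
  })
  out <- sex_divergence(fake_samples(d, draws), "cohort", from_index = k)
  expect_equal(out$slope$mean, -0.05, tolerance = 0.01)
  expect_true(out$steeper_decline)
  expect_gt(out$slope$p_negative, 0.99)
})
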