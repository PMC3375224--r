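test_that("tabulate counts matching records into the right cells", {
  g <- paper_grid()
  rec <- data.frame(year = 1977, age = 22, sex = "F", icd_version = 10,
                    code = "A41.9")[rep(1, 3), ]
  tab <- tabulate_records(rec, g, "septicaemia")
  expect_equal(tab$deaths[1, 1, 2], 3L)
  expect_equal(sum(tab$deaths), 3L)
  expect_equal(tab$n_tabulated + sum(tab$excluded), tab$n_input)
})

test_that("out-of-range ages and years are excluded and reported", {
  g <- paper_grid()
  rec <- data.frame(year = c(1977, 1977, 1970, 2010, 1990),
                    age = c(19, 90, 40, 40, 40),
                    sex = "M", icd_version = 10, code = "A41.9")
  tab <- tabulate_records(rec, g, "septicaemia")
  expect_equal(tab$excluded[["age_out_of_range"]], 1L)   # age 19
  expect_equal(tab$excluded[["year_out_of_range"]], 2L)  # 1970, 2010
  expect_equal(tab$deaths[14, 1, 1], 1L)                 # age 90 -> 85+
  expect_equal(tab$n_tabulated, 2L)
})

test_that("tabulation is permutation-invariant and matches a brute-force recount", {
  g <- paper_grid()
  rec <- random_records(1000, seed = 11)
  t1 <- tabulate_records(rec, g, "septicaemia")
  t2 <- tabulate_records(rec[sample(nrow(rec)), ], g, "septicaemia")
  expect_identical(t1$deaths, t2$deaths)
  expect_equal(t1$n_tabulated + sum(t1$excluded), 1000L)
  # independent filter: recount one arbitrary cell by subsetting the frame
  cls <- classify_cause(rec$code, rec$icd_version)
  in_cell <- cls == "septicaemia" & rec$sex == "M" &
    rec$age >= 40 & rec$age < 45 & rec$year >= 1986 & rec$year < 1991
  expect_equal(t1$deaths[5, 3, 1], sum(in_cell))
  # and the grand total by an independent filter
  in_grid <- cls == "septicaemia" & rec$age >= 20 &
    rec$year >= 1976 & rec$year <= 2005
  expect_equal(t1$n_tabulated, sum(in_grid))
})

test_that("age-standardized rates behave like a weighted mean of rates", {
  g <- small_grid()
  E <- array(1000, c(6, 4, 2))
  # identical cell rates: standardization returns that rate regardless of weights
  d <- array(5L, c(6, 4, 2))
  tab <- lexis_table(g, d, E)
  expect_equal(unname(age_standardized_rate(tab, "M", 1)), 5 / 1000 * 1e5)
  expect_equal(unname(age_standardized_rate(tab, "M", 2, std = c(9, 1, 1, 1, 1, 1))),
               5 / 1000 * 1e5)
  # two effective age groups with rates 1/1000 and 3/1000, equal weights -> 200
  d2 <- array(0L, c(6, 4, 2)); d2[1, 1, 1] <- 1L; d2[2, 1, 1] <- 3L
  tab2 <- lexis_table(g, d2, E)
  expect_equal(unname(age_standardized_rate(tab2, "M", 1,
                                            std = c(1, 1, 0, 0, 0, 0))), 200)
  # invariance to positive scaling of the weights
  r1 <- age_standardized_rate(tab2, "M", 1, std = c(1, 2, 1, 1, 2, 1))
  r2 <- age_standardized_rate(tab2, "M", 1, std = 2 * c(1, 2, 1, 1, 2, 1))
  expect_equal(r1, r2)
  # weights proportional to exposure reproduce the crude rate
  set.seed(4)
  d3 <- array(rpois(48, 20), c(6, 4, 2))
  E3 <- array(runif(48, 500, 2000), c(6, 4, 2))
  tab3 <- lexis_table(g, d3, E3)
  crude <- sum(d3[, 2, 2]) / sum(E3[, 2, 2]) * 1e5
  expect_equal(unname(age_standardized_rate(tab3, "F", 2, std = E3[, 2, 2])),
               crude)
  expect_error(age_standardized_rate(tab3, "F", 1, std = rep(0, 6)), "zero")
})

test_that("counts files round-trip and malformed files are rejected with cell names", {
  g <- small_grid()
  set.seed(9)
  tab <- lexis_table(g, array(rpois(48, 7), c(6, 4, 2)),
                     array(runif(48, 100, 900), c(6, 4, 2)),
                     cause_label = "septicaemia_like")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_counts(tab, path)
  back <- read_counts(path)
  expect_equal(back$deaths, tab$deaths)
  expect_equal(back$exposure, tab$exposure, tolerance = 1e-12)
  expect_equal(back$cause_label, "septicaemia_like")
  expect_equal(back$grid$n_cohort, g$n_cohort)

  # drop one cell -> error naming it
  lines <- readLines(path)
  drop <- grep("^70-74,1985-1989,F", lines)
  writeLines(lines[-drop], path)
  expect_error(read_counts(path), "70-74 / 1985-1989 / F")

  # negative count -> rejected
  write_counts(tab, path)
  lines <- readLines(path)
  i <- grep("^60-64,1980-1984,M", lines)
  lines[i] <- sub(",[0-9]+,", ",-1,", lines[i])
  writeLines(lines, path)
  expect_error(read_counts(path), "deaths")
})

test_that("lexis_table enforces its invariants", {
  g <- small_grid()
  E <- array(100, c(6, 4, 2))
  expect_error(lexis_table(g, array(-1L, c(6, 4, 2)), E), "non-negative")
  expect_error(lexis_table(g, array(0.5, c(6, 4, 2)), E), "integer")
  expect_error(lexis_table(g, array(0L, c(6, 4, 2)), array(0, c(6, 4, 2))),
               "positive")
  expect_error(lexis_table(g, array(0L, c(6, 5, 2)), E), "arrays")
})
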