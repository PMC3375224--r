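# Synthetic mortality registry with known log-linear APC structure.
#
# The generator realizes the Poisson APC model's own data-generating process:
# deaths_{a,p,s} ~ Poisson(E_{a,p,s} * exp(eta_{a,p,s})) with
# eta = intercept + age_a + period_p + cohort_{c(a,p)}
#       + 1[female] * (sex_offset + sex_age_a + sex_period_p + sex_cohort_c).
# Truth vectors are stored in the same constrained parameterization the
# fitted model uses (zeros at the reference cells), so recovery comparisons
# are direct subtractions.

#' Construct a set of true APC effects
#'
#' @param grid A [make_grid()] object.
#' @param intercept Baseline log-rate (log deaths per person-year).
#' @param age_eff,period_eff,cohort_eff Log-scale effect vectors of lengths
#'   `n_age`, `n_period`, `n_cohort` (defaults: zeros).
#' @param sex_offset Female-vs-male log-rate difference.
#' @param sex_age,sex_period,sex_cohort Optional female deviation vectors
#'   (defaults: zeros).
#' @return An object of class `true_effects`.
#' @export
true_effects <- function(grid, intercept, age_eff = NULL, period_eff = NULL,
                         cohort_eff = NULL, sex_offset = 0,
                         sex_age = NULL, sex_period = NULL,
                         sex_cohort = NULL) {
  stopifnot(is_lexis_grid(grid), is.finite(intercept))
  zero <- function(x, n, what) {
    if (is.null(x)) return(numeric(n))
    x <- as.numeric(x)
    if (length(x) != n || any(!is.finite(x))) {
      stop(what, " must be a finite vector of length ", n)
    }
    x
  }
  structure(list(
    grid = grid,
    intercept = as.numeric(intercept),
    age_eff = zero(age_eff, grid$n_age, "age_eff"),
    period_eff = zero(period_eff, grid$n_period, "period_eff"),
    cohort_eff = zero(cohort_eff, grid$n_cohort, "cohort_eff"),
    sex_offset = as.numeric(sex_offset),
    sex_age = zero(sex_age, grid$n_age, "sex_age"),
    sex_period = zero(sex_period, grid$n_period, "sex_period"),
    sex_cohort = zero(sex_cohort, grid$n_cohort, "sex_cohort")),
    class = "true_effects")
}

#' Project effects onto the constrained APC parameterization
#'
#' Rewrites an equivalent set of effects with zeros at the reference cells
#' (first age group, the two reference periods, the reference cohort, and the
#' same pattern on the female deviation vectors) without changing any cell's
#' linear predictor. The linear component removed from the period curve is
#' reallocated along the APC identity `period = cohort + age - n_age` into
#' the cohort and age curves; constants are absorbed by the intercept (or the
#' sex offset, for deviation vectors).
#'
#' @param effects A [true_effects()] object.
#' @param references List with `periods` (two indices) and `cohort`, as from
#'   [default_references()].
#' @return A [true_effects()] object with reference cells exactly zero.
#' @export
constrain_effects <- function(effects, references = NULL) {
  stopifnot(inherits(effects, "true_effects"))
  g <- effects$grid
  if (is.null(references)) references <- default_references(g)
  r1 <- references$periods[1]; r2 <- references$periods[2]
  rc <- references$cohort
  A <- g$n_age
  project <- function(alpha, pi, gamma, const) {
    # remove the line through the two period references from pi
    if (!is.na(r2) && r2 != r1) {
      s <- (pi[r2] - pi[r1]) / (r2 - r1)
      u <- pi[r1] - s * r1
      p_idx <- seq_along(pi)
      pi <- pi - (u + s * p_idx)
      gamma <- gamma + s * seq_along(gamma)
      alpha <- alpha + s * seq_along(alpha)
      const <- const + u - s * A
    } else {
      const <- const + pi[r1]
      pi <- pi - pi[r1]
    }
    const <- const + gamma[rc]
    gamma <- gamma - gamma[rc]
    const <- const + alpha[1]
    alpha <- alpha - alpha[1]
    # clear the ~1e-18 rounding residue so reference cells are exactly zero
    pi[c(r1, r2)] <- 0
    gamma[rc] <- 0
    alpha[1] <- 0
    list(alpha = alpha, pi = pi, gamma = gamma, const = const)
  }
  m <- project(effects$age_eff, effects$period_eff, effects$cohort_eff,
               effects$intercept)
  f <- project(effects$sex_age, effects$sex_period, effects$sex_cohort,
               effects$sex_offset)
  true_effects(g, m$const, m$alpha, m$pi, m$gamma,
               sex_offset = f$const, sex_age = f$alpha,
               sex_period = f$pi, sex_cohort = f$gamma)
}

#' Linear predictor array implied by a set of effects
#'
#' @param effects A [true_effects()] object.
#' @return Numeric array `n_age x n_period x 2` of log-rates; third dimension
#'   is sex `c("M", "F")`.
#' @export
effects_eta <- function(effects) {
  stopifnot(inherits(effects, "true_effects"))
  g <- effects$grid
  eta <- array(0, c(g$n_age, g$n_period, 2L))
  for (p in seq_len(g$n_period)) {
    cidx <- cohort_index(g, seq_len(g$n_age), p)
    male <- effects$intercept + effects$age_eff + effects$period_eff[p] +
      effects$cohort_eff[cidx]
    dev <- effects$sex_offset + effects$sex_age + effects$sex_period[p] +
      effects$sex_cohort[cidx]
    eta[, p, 1L] <- male
    eta[, p, 2L] <- male + dev
  }
  eta
}

#' Construct a named synthetic-registry scenario
#'
#' Three scenarios are available, differing in the curvature planted in the
#' cohort curve:
#' * `"septicaemia_like"`: cohort slope changes by `-0.04` per index at a
#'   mid-grid inflection (default: cohort 10 of 19, labelled 1941), with an
#'   additional `-0.03` post-inflection slope for women (`sex_cohort`), a
#'   female log-rate offset of `-0.3`, and a mild period downturn.
#' * `"pneumonia_like"`: a positive cohort slope change (`+0.03`) somewhat
#'   later in the grid and no sex-cohort interaction.
#' * `"null"`: flat effects (all second differences zero, no sex
#'   differences) at the baseline rate.
#'
#' Age effects rise linearly on the log scale (`+0.09` per age index), i.e.
#' mortality increases exponentially with age. The paper-style grid defaults
#' and an exposure of 1e5 person-years per cell give counts in the tens per
#' cell. Effects are stored pre-constrained ([constrain_effects()]) so the
#' reference cells are exactly zero.
#'
#' @param name One of `"septicaemia_like"`, `"pneumonia_like"`, `"null"`.
#' @param grid A [make_grid()] object (default: the 20+/1976-2005 study grid).
#' @param exposure_scale Person-years per cell (> 0).
#' @param seed Integer seed driving all of the scenario's randomness.
#' @param inflection_index Cohort index at which the slope change is planted
#'   (default: 10 of 19 for `septicaemia_like`; a later index, label 1951 on
#'   the study grid, for `pneumonia_like`).
#' @param references Identifiability references (default
#'   [default_references()]).
#' @return An object of class `apc_scenario`.
#' @export
make_scenario <- function(name, grid = make_grid(20, 5, 14, 1976, 5, 6),
                          exposure_scale = 1e5, seed = 1L,
                          inflection_index = NULL, references = NULL) {
  name <- match.arg(name, c("septicaemia_like", "pneumonia_like", "null"))
  stopifnot(is_lexis_grid(grid))
  if (!is.numeric(exposure_scale) || exposure_scale <= 0) {
    stop("exposure_scale must be > 0")
  }
  if (is.null(references)) references <- default_references(grid)
  A <- grid$n_age; P <- grid$n_period; C <- grid$n_cohort
  intercept <- log(2e-4)
  age_eff <- 0.09 * (seq_len(A) - 1)
  # smooth period curve with one mild downturn after the middle
  pk <- max(2L, ceiling(P / 2))
  period_eff <- 0.02 * (seq_len(P) - 1) - 0.05 * pmax(seq_len(P) - pk, 0)
  sex_offset <- -0.3
  cohort_eff <- numeric(C)
  sex_cohort <- numeric(C)
  k <- inflection_index
  if (name == "septicaemia_like") {
    if (is.null(k)) k <- min(C, max(2L, (C + 1L) %/% 2L))  # 10 of 19
    cohort_eff <- 0.01 * (seq_len(C) - 1) - 0.04 * pmax(seq_len(C) - k, 0)
    sex_cohort <- -0.03 * pmax(seq_len(C) - k, 0)
  } else if (name == "pneumonia_like") {
    if (is.null(k)) k <- min(C, max(2L, (C + 1L) %/% 2L + 2L))  # 12 of 19
    cohort_eff <- -0.01 * (seq_len(C) - 1) + 0.03 * pmax(seq_len(C) - k, 0)
  } else {
    # null: flat log-rates, no sex differences
    age_eff <- numeric(A)
    period_eff <- numeric(P)
    sex_offset <- 0
    k <- NA_integer_
  }
  eff <- true_effects(grid, intercept, age_eff, period_eff, cohort_eff,
                      sex_offset = sex_offset, sex_cohort = sex_cohort)
  eff <- constrain_effects(eff, references)
  structure(list(name = name, grid = grid, effects = eff,
                 exposure_scale = as.numeric(exposure_scale),
                 seed = as.integer(seed),
                 inflection_index = if (is.na(k)) NA_integer_ else
                   as.integer(k),
                 references = references),
            class = "apc_scenario")
}

#' @export
print.apc_scenario <- function(x, ...) {
  cat("Synthetic registry scenario '", x$name, "': ", x$grid$n_age, "x",
      x$grid$n_period, " grid, exposure ", format(x$exposure_scale),
      " person-years/cell, seed ", x$seed,
      if (!is.na(x$inflection_index))
        paste0(", cohort inflection at index ", x$inflection_index),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a Lexis table from a scenario
#'
#' Draws independent Poisson counts with means
#' `exposure * exp(eta)` from the scenario's true effects. The same scenario
#' (including its seed) always produces the identical table.
#'
#' @param scenario An [make_scenario()] object.
#' @return A [lexis_table()] with `cause_label = scenario$name`.
#' @export
simulate_table <- function(scenario) {
  stopifnot(inherits(scenario, "apc_scenario"))
  g <- scenario$grid
  eta <- effects_eta(scenario$effects)
  rate <- exp(eta)
  if (any(!is.finite(rate))) {
    stop("non-finite cell rates implied by the scenario's effects")
  }
  exposure <- array(scenario$exposure_scale, dim(eta))
  set.seed(scenario$seed)
  deaths <- array(stats::rpois(length(eta), exposure * rate), dim(eta))
  lexis_table(g, deaths, exposure, cause_label = scenario$name)
}

scenario_code <- function(cause_label) {
  if (grepl("septic", cause_label, ignore.case = TRUE)) "A41.9"
  else if (grepl("pneumonia", cause_label, ignore.case = TRUE)) "J18.9"
  else "R99"
}

#' Explode a Lexis table into record-level deaths
#'
#' Emits one `DeathRecord` row per death: year drawn uniformly within the
#' cell's period, age uniformly within the cell's age group (85-99 for the
#' open-ended top group), with an ICD-10 code representative of the table's
#' cause label. Tabulating the records back
#' ([tabulate_records()]) reproduces the table's counts exactly.
#'
#' @param table A [lexis_table()].
#' @param seed Integer seed for the within-cell year/age draws.
#' @return Data frame with columns `year`, `age`, `sex`, `icd_version`,
#'   `code` (zero rows for an empty table).
#' @export
explode_to_records <- function(table, seed = 1L) {
  stopifnot(is_lexis_table(table))
  g <- table$grid
  n <- sum(table$deaths)
  if (n == 0L) {
    return(data.frame(year = integer(0), age = integer(0),
                      sex = character(0), icd_version = integer(0),
                      code = character(0)))
  }
  set.seed(seed)
  cells <- which(table$deaths > 0, arr.ind = TRUE)
  code <- scenario_code(table$cause_label)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- cells[i, 1]; p <- cells[i, 2]; s <- cells[i, 3]
    d <- table$deaths[a, p, s]
    ylo <- g$period_start + (p - 1) * g$period_width
    alo <- g$age_start + (a - 1) * g$age_width
    ahi <- if (g$open_ended_top && a == g$n_age) alo + 14 else
      alo + g$age_width - 1
    out[[i]] <- data.frame(
      year = ylo + sample.int(g$period_width, d, replace = TRUE) - 1L,
      age = alo + sample.int(ahi - alo + 1, d, replace = TRUE) - 1L,
      sex = c("M", "F")[s],
      icd_version = 10L,
      code = code)
  }
  do.call(rbind, out)
}

#' Write / read a scenario configuration file
#'
#' Flat `key = value` text naming the scenario, the grid parameters, the
#' exposure scale and the seed; [read_scenario()] rebuilds the scenario with
#' [make_scenario()].
#'
#' @param scenario An [make_scenario()] object.
#' @param path File path.
#' @return `read_scenario()` returns an `apc_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "apc_scenario"))
  g <- scenario$grid
  lines <- c(
    paste("name =", scenario$name),
    paste("age_start =", g$age_start),
    paste("age_width =", g$age_width),
    paste("n_age =", g$n_age),
    paste("period_start =", g$period_start),
    paste("period_width =", g$period_width),
    paste("n_period =", g$n_period),
    paste("open_ended_top =", g$open_ended_top),
    paste("exposure_scale =", format(scenario$exposure_scale,
                                     scientific = FALSE)),
    paste("seed =", scenario$seed),
    paste("inflection_index =", scenario$inflection_index))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) {
    stop("malformed scenario config at line ", bad[1], ": ", lines[bad[1]])
  }
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  conf <- stats::setNames(as.list(vals), keys)
  need <- c("name", "age_start", "age_width", "n_age", "period_start",
            "period_width", "n_period", "exposure_scale", "seed")
  miss <- setdiff(need, keys)
  if (length(miss)) stop("scenario config missing key(s): ",
                         paste(miss, collapse = ", "))
  grid <- make_grid(as.numeric(conf$age_start), as.numeric(conf$age_width),
                    as.integer(conf$n_age), as.numeric(conf$period_start),
                    as.numeric(conf$period_width), as.integer(conf$n_period),
                    open_ended_top = !identical(conf$open_ended_top, "FALSE"))
  ki <- if (!is.null(conf$inflection_index) &&
            !conf$inflection_index %in% c("NA", "")) {
    as.integer(conf$inflection_index)
  } else NULL
  make_scenario(conf$name, grid = grid,
                exposure_scale = as.numeric(conf$exposure_scale),
                seed = as.integer(conf$seed), inflection_index = ki)
}
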