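# Parameter layout and identifiability constraints for one APC model.
#
# The age, period and cohort index variables are exactly collinear
# (cohort = period - age + n_age), so a Poisson log-linear model in all three
# is rank-deficient by one: linear trends can be shifted between the curves
# without changing any fitted rate. The layout used here resolves this with
# hard zeros: the first age group (corner), TWO reference periods and one
# reference cohort are pinned at zero; the second period reference absorbs
# the remaining linear-trend indeterminacy. Female deviation vectors (sex
# interactions) carry the same zero pattern, and the male stratum is the
# reference sex throughout.

#' Default identifiability references for a grid
#'
#' Periods: the second and the penultimate period (for grids with at least 4
#' periods; smaller grids fall back to the first and last so the two
#' references stay distinct). Cohort: the near-central cohort
#' `floor(n_cohort/2)` — on the 1976-2005 study grid this is the cohort
#' labelled 1936 (5-year core 1936-1940).
#'
#' @param grid A [make_grid()] object.
#' @return List with elements `periods` (two indices) and `cohort`.
#' @export
default_references <- function(grid) {
  stopifnot(is_lexis_grid(grid))
  P <- grid$n_period
  periods <- if (P >= 4L) c(2L, P - 1L) else if (P >= 2L) c(1L, P) else 1L
  list(periods = periods, cohort = max(1L, grid$n_cohort %/% 2L))
}

#' Build an APC model design
#'
#' Lays out the free parameter vector for one model in the menu: intercept,
#' then the non-reference levels of each included effect, then the female
#' deviation terms. Both sexes are always stacked in one likelihood; the sex
#' terms are female deviations from the male curves, so joint estimates are
#' relative to a common male reference point.
#'
#' @param grid A [make_grid()] object.
#' @param terms Character subset of `c("age", "period", "cohort")`; `"age"`
#'   is always required.
#' @param sex_terms Character subset of `c("offset", "age", "period",
#'   "cohort")`; interactions require the corresponding main term.
#' @param reference_periods Two distinct period indices fixed at zero
#'   (default: second and penultimate). Only allowed when `"period"` is in
#'   `terms`.
#' @param reference_cohort Cohort index fixed at zero (default: near-central).
#'   Only allowed when `"cohort"` is in `terms`.
#' @return An object of class `apc_design` with the cell frame (`cells`), the
#'   model matrix (`X`), parameter names (`par_names`), the level-to-column
#'   `index_map` per term (NA at reference levels) and RW2 term metadata.
#' @examples
#' g <- make_grid(20, 5, 14, 1976, 5, 6)
#' d <- build_design(g, c("age", "period", "cohort"),
#'                   c("offset", "age", "period", "cohort"))
#' d$n_par  # 72
#' @export
build_design <- function(grid, terms = c("age", "period", "cohort"),
                         sex_terms = character(),
                         reference_periods = NULL,
                         reference_cohort = NULL) {
  stopifnot(is_lexis_grid(grid))
  terms <- match.arg(terms, c("age", "period", "cohort"), several.ok = TRUE)
  if (!"age" %in% terms) stop('terms must include "age"')
  if (length(sex_terms)) {
    sex_terms <- match.arg(sex_terms, c("offset", "age", "period", "cohort"),
                           several.ok = TRUE)
  }
  for (t in setdiff(sex_terms, "offset")) {
    if (!t %in% terms) {
      stop("sex interaction with '", t, "' requires the '", t, "' main term")
    }
  }
  defs <- default_references(grid)
  if (!is.null(reference_periods) && !"period" %in% terms) {
    stop("reference_periods given but 'period' is not in terms")
  }
  if (!is.null(reference_cohort) && !"cohort" %in% terms) {
    stop("reference_cohort given but 'cohort' is not in terms")
  }
  ref_p <- if ("period" %in% terms) {
    rp <- if (is.null(reference_periods)) defs$periods else
      sort(as.integer(reference_periods))
    if (length(rp) != length(unique(rp))) stop("reference periods must differ")
    if (any(rp < 1L | rp > grid$n_period)) stop("reference period out of range")
    rp
  } else integer(0)
  ref_c <- if ("cohort" %in% terms) {
    rc <- if (is.null(reference_cohort)) defs$cohort else
      as.integer(reference_cohort)
    if (length(rc) != 1L || rc < 1L || rc > grid$n_cohort) {
      stop("reference cohort out of range")
    }
    rc
  } else integer(0)

  lev <- list(age = grid$n_age, period = grid$n_period, cohort = grid$n_cohort)
  refs <- list(age = 1L, period = ref_p, cohort = ref_c)

  cells <- expand.grid(age_idx = seq_len(grid$n_age),
                       period_idx = seq_len(grid$n_period),
                       sex = c("M", "F"), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells$cohort_idx <- cohort_index(grid, cells$age_idx, cells$period_idx)
  cells$female <- as.integer(cells$sex == "F")
  n_cells <- nrow(cells)

  par_names <- "intercept"
  index_map <- list()
  col <- 1L
  add_term <- function(name, n_levels, ref_levels) {
    map <- rep(NA_integer_, n_levels)
    free <- setdiff(seq_len(n_levels), ref_levels)
    map[free] <- col + seq_along(free)
    index_map[[name]] <<- map
    if (length(free)) {
      par_names <<- c(par_names, paste0(name, "[", free, "]"))
    }
    col <<- col + length(free)
  }
  for (t in c("age", "period", "cohort")) {
    if (t %in% terms) add_term(t, lev[[t]], refs[[t]])
  }
  if ("offset" %in% sex_terms) {
    index_map[["sex"]] <- col + 1L
    par_names <- c(par_names, "sex")
    col <- col + 1L
  }
  for (t in c("age", "period", "cohort")) {
    if (t %in% setdiff(sex_terms, "offset")) {
      add_term(paste0("sex_", t), lev[[t]], refs[[t]])
    }
  }
  n_par <- col

  X <- matrix(0, n_cells, n_par)
  X[, 1L] <- 1
  cell_level <- list(age = cells$age_idx, period = cells$period_idx,
                     cohort = cells$cohort_idx)
  for (t in intersect(c("age", "period", "cohort"), terms)) {
    map <- index_map[[t]]
    j <- map[cell_level[[t]]]
    ok <- !is.na(j)
    X[cbind(which(ok), j[ok])] <- 1
  }
  if ("offset" %in% sex_terms) X[, index_map[["sex"]]] <- cells$female
  for (t in setdiff(sex_terms, "offset")) {
    map <- index_map[[paste0("sex_", t)]]
    j <- map[cell_level[[t]]]
    ok <- !is.na(j) & cells$female == 1L
    X[cbind(which(ok), j[ok])] <- 1
  }
  colnames(X) <- par_names

  rw2_terms <- intersect(c("age", "period", "cohort"), terms)
  sex_int <- setdiff(sex_terms, "offset")
  if (length(sex_int)) rw2_terms <- c(rw2_terms, paste0("sex_", sex_int))

  structure(list(grid = grid, terms = terms, sex_terms = sex_terms,
                 reference_periods = ref_p, reference_cohort = ref_c,
                 cells = cells, X = X, par_names = par_names, n_par = n_par,
                 index_map = index_map, rw2_terms = rw2_terms),
            class = "apc_design")
}

#' @export
print.apc_design <- function(x, ...) {
  cat("APC design: terms {", paste(x$terms, collapse = ", "), "}",
      if (length(x$sex_terms)) paste0(", sex terms {",
                                      paste(x$sex_terms, collapse = ", "), "}"),
      "; ", x$n_par, " free parameters on a ", x$grid$n_age, "x",
      x$grid$n_period, " grid\n", sep = "")
  invisible(x)
}

is_apc_design <- function(x) inherits(x, "apc_design")

# full effect vector (zeros at references) for one RW2 term
reconstruct_full <- function(design, beta, term) {
  map <- design$index_map[[term]]
  if (is.null(map)) stop("term '", term, "' not in design")
  x <- numeric(length(map))
  ok <- !is.na(map)
  x[ok] <- beta[map[ok]]
  x
}

# y and exposure vectors in the design's cell order (age fastest, then
# period, then sex) — matches as.vector() of the [age, period, sex] arrays
table_vectors <- function(table, design) {
  stopifnot(is_lexis_table(table), is_apc_design(design))
  g <- table$grid
  dg <- design$grid
  if (g$n_age != dg$n_age || g$n_period != dg$n_period) {
    stop("table grid does not match design grid")
  }
  list(y = as.numeric(table$deaths), E = as.numeric(table$exposure))
}

#' Short label for a design's model structure ("APC+sex(o,a,p,c)" style)
#' @param design An [build_design()] object.
#' @return Character scalar.
#' @export
design_label <- function(design) {
  stopifnot(is_apc_design(design))
  main <- paste(toupper(substr(design$terms, 1, 1)), collapse = "")
  if (length(design$sex_terms)) {
    paste0(main, "+sex(", paste(substr(design$sex_terms, 1, 1), collapse = ","),
           ")")
  } else main
}
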