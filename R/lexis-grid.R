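#' Construct a Lexis grid
#'
#' A Lexis grid is the age x calendar-period lattice on which demographic
#' events are tabulated. Birth cohorts run along its diagonals, so a grid with
#' `n_age` age groups and `n_period` periods indexes
#' `n_age + n_period - 1` cohorts. Age and period widths must be equal for the
#' one-step cohort diagonals to be well defined.
#'
#' The registry analysis this package was built around uses fourteen 5-year
#' age groups (20-24 up to 85+) and six 5-year periods (1976-1980 up to
#' 2001-2005), giving nineteen birth cohorts whose first label is 1896.
#'
#' @param age_start Lower bound (in years) of the first age group.
#' @param age_width Width of each age group, in years.
#' @param n_age Number of age groups (>= 1).
#' @param period_start First calendar year of the first period.
#' @param period_width Width of each period, in years; must equal `age_width`.
#' @param n_period Number of periods (>= 1).
#' @param open_ended_top If `TRUE` (default) the last age group is open-ended
#'   ("85+" style) and absorbs all ages at or above its lower bound.
#'
#' @return An object of class `lexis_grid`.
#' @examples
#' g <- make_grid(20, 5, 14, 1976, 5, 6)
#' g$n_cohort            # 19
#' cohort_labels(g)$label[1]  # 1896
#' @export
make_grid <- function(age_start, age_width, n_age, period_start, period_width,
                      n_period, open_ended_top = TRUE) {
  stopifnot(is.numeric(age_start), is.numeric(period_start),
            length(age_start) == 1L, length(period_start) == 1L)
  if (!is.numeric(age_width) || !is.numeric(period_width) ||
      age_width < 1 || period_width < 1) {
    stop("age_width and period_width must be positive")
  }
  if (age_width != period_width) {
    stop("age_width must equal period_width: unequal widths break the ",
         "one-step cohort diagonals of the Lexis grid")
  }
  n_age <- as.integer(n_age)
  n_period <- as.integer(n_period)
  if (is.na(n_age) || n_age < 1L || is.na(n_period) || n_period < 1L) {
    stop("n_age and n_period must be integers >= 1")
  }
  grid <- structure(
    list(age_start = as.numeric(age_start),
         age_width = as.numeric(age_width),
         n_age = n_age,
         open_ended_top = isTRUE(open_ended_top),
         period_start = as.numeric(period_start),
         period_width = as.numeric(period_width),
         n_period = n_period,
         n_cohort = n_age + n_period - 1L),
    class = "lexis_grid")
  grid
}

#' @export
print.lexis_grid <- function(x, ...) {
  al <- age_labels(x)
  pl <- period_labels(x)
  cat("Lexis grid: ", x$n_age, " age groups (", al[1], " .. ", al[x$n_age],
      "), ", x$n_period, " periods (", pl[1], " .. ", pl[x$n_period], "), ",
      x$n_cohort, " cohorts (labels ", cohort_labels(x)$label[1], " .. ",
      cohort_labels(x)$label[x$n_cohort], ")\n", sep = "")
  invisible(x)
}

is_lexis_grid <- function(x) inherits(x, "lexis_grid")

#' Cohort index of a Lexis cell
#'
#' Cohort indices are constant along Lexis diagonals: the oldest age group in
#' the first period belongs to cohort 1 and the youngest age group in the
#' last period to cohort `n_age + n_period - 1`. With 1-based indices,
#' `cohort_idx = period_idx - age_idx + n_age`.
#'
#' @param grid A [make_grid()] object.
#' @param age_idx,period_idx 1-based cell indices (vectorized, recycled).
#' @return Integer cohort indices in `1:grid$n_cohort`.
#' @export
cohort_index <- function(grid, age_idx, period_idx) {
  stopifnot(is_lexis_grid(grid))
  age_idx <- as.integer(age_idx)
  period_idx <- as.integer(period_idx)
  if (any(is.na(age_idx)) || any(age_idx < 1L) || any(age_idx > grid$n_age)) {
    stop("age_idx out of range 1..", grid$n_age)
  }
  if (any(is.na(period_idx)) || any(period_idx < 1L) ||
      any(period_idx > grid$n_period)) {
    stop("period_idx out of range 1..", grid$n_period)
  }
  period_idx - age_idx + grid$n_age
}

#' Cohort labels of a Lexis grid
#'
#' The label of cohort `c` is the first calendar year of the 5-year (or
#' `width`-year) band conventionally attached to the diagonal: evaluated along
#' the diagonal it equals (last calendar year of the period) minus (lower age
#' bound) plus 1. On the 1976-2005 / ages-20+ grid this yields labels
#' 1896, 1901, ..., 1986. The band's centre year is `label + 2` for 5-year
#' widths (more generally `label + floor(width/2)`).
#'
#' @param grid A [make_grid()] object.
#' @return A data frame with columns `index`, `label` and `center`.
#' @export
cohort_labels <- function(grid) {
  stopifnot(is_lexis_grid(grid))
  idx <- seq_len(grid$n_cohort)
  label <- grid$period_start - grid$age_start +
    grid$age_width * (idx + 1L - grid$n_age)
  data.frame(index = idx, label = label,
             center = label + floor(grid$age_width / 2))
}

#' Age-group labels ("20-24", ..., "85+")
#' @param grid A [make_grid()] object.
#' @return Character vector of length `grid$n_age`.
#' @export
age_labels <- function(grid) {
  stopifnot(is_lexis_grid(grid))
  lo <- grid$age_start + (seq_len(grid$n_age) - 1L) * grid$age_width
  lab <- paste0(lo, "-", lo + grid$age_width - 1)
  if (grid$open_ended_top) lab[grid$n_age] <- paste0(lo[grid$n_age], "+")
  lab
}

#' Period labels ("1976-1980", ...)
#' @param grid A [make_grid()] object.
#' @return Character vector of length `grid$n_period`.
#' @export
period_labels <- function(grid) {
  stopifnot(is_lexis_grid(grid))
  lo <- grid$period_start + (seq_len(grid$n_period) - 1L) * grid$period_width
  paste0(lo, "-", lo + grid$period_width - 1)
}
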