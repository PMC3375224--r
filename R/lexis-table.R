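#' Construct a Lexis table of deaths and exposures
#'
#' A `lexis_table` holds, for one cause of death, the death counts and
#' person-year exposures for every (age group, period, sex) cell of a Lexis
#' grid. Counts must be non-negative integers; exposures strictly positive
#' (cells with zero exposure are disallowed rather than imputed).
#'
#' @param grid A [make_grid()] object.
#' @param deaths Numeric array `n_age x n_period x 2` of non-negative integer
#'   counts; third dimension is sex, ordered `c("M", "F")`.
#' @param exposure Numeric array of the same shape with positive person-years.
#' @param cause_label Free-text label of the tabulated cause.
#' @return An object of class `lexis_table`.
#' @export
lexis_table <- function(grid, deaths, exposure, cause_label = "") {
  stopifnot(is_lexis_grid(grid))
  dm <- c(grid$n_age, grid$n_period, 2L)
  deaths <- as.array(deaths)
  exposure <- as.array(exposure)
  if (!identical(dim(deaths), dm) || !identical(dim(exposure), dm)) {
    stop("deaths and exposure must both be n_age x n_period x 2 arrays (",
         paste(dm, collapse = " x "), ")")
  }
  if (any(!is.finite(deaths)) || any(deaths < 0) ||
      any(deaths != round(deaths))) {
    stop("deaths must be non-negative integers")
  }
  if (any(!is.finite(exposure)) || any(exposure <= 0)) {
    stop("exposure must be positive in every cell")
  }
  dn <- list(age = age_labels(grid), period = period_labels(grid),
             sex = c("M", "F"))
  dimnames(deaths) <- dn
  dimnames(exposure) <- dn
  structure(list(grid = grid, deaths = deaths, exposure = exposure,
                 cause_label = as.character(cause_label)),
            class = "lexis_table")
}

#' @export
print.lexis_table <- function(x, ...) {
  cat("Lexis table", if (nzchar(x$cause_label)) paste0(" [", x$cause_label, "]"),
      ": ", x$grid$n_age, " x ", x$grid$n_period, " x 2 cells, ",
      sum(x$deaths), " deaths, ", format(sum(x$exposure), big.mark = ","),
      " person-years\n", sep = "")
  invisible(x)
}

is_lexis_table <- function(x) inherits(x, "lexis_table")

# map ages / years to grid indices; NA for out-of-range
age_to_index <- function(grid, age) {
  idx <- floor((age - grid$age_start) / grid$age_width) + 1
  idx[age < grid$age_start] <- NA
  if (grid$open_ended_top) {
    idx[idx > grid$n_age] <- grid$n_age
  } else {
    idx[idx > grid$n_age] <- NA
  }
  as.integer(idx)
}

year_to_index <- function(grid, year) {
  idx <- floor((year - grid$period_start) / grid$period_width) + 1
  idx[idx < 1 | idx > grid$n_period] <- NA
  as.integer(idx)
}

#' Tabulate death records on a Lexis grid
#'
#' Classifies record-level deaths by cause ([classify_cause()]) and counts the
#' records of the requested cause into the cells of the grid. Records with a
#' different cause, an age below the grid's first group (or above a closed top
#' group), or a year of death outside the grid's periods are excluded and
#' reported, so that tabulated + excluded always equals the input size.
#'
#' @param records Data frame with columns `year`, `age`, `sex` (`"M"`/`"F"`),
#'   `icd_version` (9/10) and `code`.
#' @param grid A [make_grid()] object.
#' @param cause One of `"septicaemia"`, `"pneumonia"`, `"other"`.
#' @param include_icd9_480 Passed to [classify_cause()].
#' @return A list with `deaths` (the `n_age x n_period x 2` count array),
#'   `n_input`, `n_tabulated`, and `excluded`, a named count vector by reason
#'   (`cause_mismatch`, `age_out_of_range`, `year_out_of_range`).
#' @export
tabulate_records <- function(records, grid, cause,
                             include_icd9_480 = TRUE) {
  stopifnot(is_lexis_grid(grid), is.data.frame(records))
  need <- c("year", "age", "sex", "icd_version", "code")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  cause <- match.arg(cause, c("septicaemia", "pneumonia", "other"))
  if (!all(records$sex %in% c("M", "F"))) {
    stop('records$sex must be "M" or "F"')
  }
  if (any(records$age < 0)) stop("negative age in records")
  n <- nrow(records)
  deaths <- array(0L, dim = c(grid$n_age, grid$n_period, 2L))
  excluded <- c(cause_mismatch = 0L, age_out_of_range = 0L,
                year_out_of_range = 0L)
  if (n > 0L) {
    cl <- classify_cause(records$code, records$icd_version,
                         include_icd9_480 = include_icd9_480)
    keep <- cl == cause
    excluded["cause_mismatch"] <- sum(!keep)
    a <- age_to_index(grid, records$age)
    p <- year_to_index(grid, records$year)
    bad_age <- keep & is.na(a)
    excluded["age_out_of_range"] <- sum(bad_age)
    bad_year <- keep & !is.na(a) & is.na(p)
    excluded["year_out_of_range"] <- sum(bad_year)
    keep <- keep & !is.na(a) & !is.na(p)
    if (any(keep)) {
      s <- ifelse(records$sex == "M", 1L, 2L)
      tab <- table(factor(a[keep], levels = seq_len(grid$n_age)),
                   factor(p[keep], levels = seq_len(grid$n_period)),
                   factor(s[keep], levels = 1:2))
      deaths <- array(as.integer(tab), dim = dim(deaths))
    }
  }
  list(deaths = deaths, n_input = n, n_tabulated = sum(deaths),
       excluded = excluded)
}

#' Directly age-standardized mortality rate
#'
#' Computes the weighted average of age-specific rates,
#' \eqn{\sum_a w_a (d_{a,p,s}/E_{a,p,s}) \times 100{,}000}, with the weights
#' renormalized to sum to one. When `std` is omitted the table's own pooled
#' all-period, both-sex exposure distribution is used as the internal
#' standard, which reproduces the shape of the trend without importing an
#' external reference population.
#'
#' @param table A [lexis_table()].
#' @param sex `"M"` or `"F"`.
#' @param period_idx Periods to evaluate (default all).
#' @param std Optional numeric vector of `n_age` non-negative weights with a
#'   positive sum; any positive scaling gives the same result.
#' @return Named numeric vector of rates per 100,000, one per period.
#' @export
age_standardized_rate <- function(table, sex, period_idx = NULL, std = NULL) {
  stopifnot(is_lexis_table(table))
  sex <- match.arg(sex, c("M", "F"))
  g <- table$grid
  if (is.null(period_idx)) period_idx <- seq_len(g$n_period)
  period_idx <- as.integer(period_idx)
  if (any(period_idx < 1L | period_idx > g$n_period)) {
    stop("period_idx out of range")
  }
  if (is.null(std)) {
    std <- rowSums(table$exposure)  # pooled over periods and sexes
  }
  std <- as.numeric(std)
  if (length(std) != g$n_age || any(!is.finite(std)) || any(std < 0)) {
    stop("std must be ", g$n_age, " finite non-negative weights")
  }
  if (sum(std) <= 0) stop("standard population weights sum to zero")
  w <- std / sum(std)
  si <- if (sex == "M") 1L else 2L
  rates <- vapply(period_idx, function(p) {
    r <- table$deaths[, p, si] / table$exposure[, p, si]
    sum(w * r) * 1e5
  }, numeric(1))
  names(rates) <- period_labels(g)[period_idx]
  rates
}

#' Write / read a Lexis counts file
#'
#' The on-disk format is comma-delimited text with a header and one row per
#' cell: columns `age_group` (e.g. `"20-24"`, `"85+"`), `period`
#' (e.g. `"1976-1980"`), `sex` (`M`/`F`), `deaths` (integer) and `exposure`
#' (person-years, `"."` decimal separator). A leading `# cause:` comment line
#' carries the cause label. `read_counts()` reconstructs the grid from the
#' labels and validates completeness (every cell exactly once), integer
#' non-negative counts and positive exposures, reporting the offending cell or
#' row on failure.
#'
#' @param table A [lexis_table()].
#' @param path File path.
#' @return `read_counts()` returns a [lexis_table()]; `write_counts()` returns
#'   `path` invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(is_lexis_table(table))
  g <- table$grid
  cells <- expand.grid(age_idx = seq_len(g$n_age),
                       period_idx = seq_len(g$n_period),
                       sex = c("M", "F"), stringsAsFactors = FALSE)
  df <- data.frame(
    age_group = age_labels(g)[cells$age_idx],
    period = period_labels(g)[cells$period_idx],
    sex = cells$sex,
    deaths = as.integer(table$deaths),
    exposure = as.numeric(table$exposure))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cause: ", table$cause_label), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_age_groups <- function(labels) {
  open <- grepl("\\+$", labels)
  lo <- as.numeric(sub("[-+].*$", "", labels))
  hi <- rep(NA_real_, length(labels))
  hi[!open] <- as.numeric(sub("^[0-9]+-", "", labels[!open]))
  if (any(is.na(lo))) stop("unparseable age_group label: ",
                           labels[which(is.na(lo))[1]])
  data.frame(label = labels, lo = lo, hi = hi, open = open)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  cause_label <- if (startsWith(first, "# cause:")) {
    trimws(sub("^# cause:", "", first))
  } else ""
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(age_group = "character",
                                       period = "character",
                                       sex = "character"))
  need <- c("age_group", "period", "sex", "deaths", "exposure")
  if (!all(need %in% names(df))) {
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  }
  ag <- parse_age_groups(unique(df$age_group))
  ag <- ag[order(ag$lo), ]
  widths <- diff(ag$lo)
  if (nrow(ag) > 1L && length(unique(widths)) != 1L) {
    stop("age groups are not equally spaced")
  }
  width <- if (nrow(ag) > 1L) widths[1] else if (!ag$open[1]) {
    ag$hi[1] - ag$lo[1] + 1
  } else 5
  pl <- unique(df$period)
  plo <- as.numeric(sub("-.*$", "", pl))
  if (any(is.na(plo))) stop("unparseable period label: ", pl[which(is.na(plo))[1]])
  pl <- pl[order(plo)]
  plo <- sort(plo)
  if (length(plo) > 1L && length(unique(diff(plo))) != 1L) {
    stop("periods are not equally spaced")
  }
  if (length(plo) > 1L && diff(plo)[1] != width) {
    stop("period width (", diff(plo)[1], ") does not match age-group width (",
         width, ")")
  }
  grid <- make_grid(ag$lo[1], width, nrow(ag), plo[1], width, length(pl),
                    open_ended_top = ag$open[nrow(ag)])
  # completeness: every (age, period, sex) cell exactly once
  key <- paste(df$age_group, df$period, df$sex, sep = "|")
  expect <- as.vector(outer(outer(ag$label, pl, paste, sep = "|"),
                            c("M", "F"), paste, sep = "|"))
  missing <- setdiff(expect, key)
  if (length(missing)) {
    stop("counts file is missing cell(s): ",
         paste(utils::head(gsub("\\|", " / ", missing), 3), collapse = "; "))
  }
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("counts file has duplicated cell(s): ",
         gsub("\\|", " / ", dup[1]))
  }
  bad <- which(!is.finite(df$deaths) | df$deaths < 0 |
                 df$deaths != round(df$deaths))
  if (length(bad)) {
    stop("invalid deaths value at data row ", bad[1], " (",
         gsub("\\|", " / ", key[bad[1]]), "): ", df$deaths[bad[1]])
  }
  bad <- which(!is.finite(df$exposure) | df$exposure <= 0)
  if (length(bad)) {
    stop("invalid exposure value at data row ", bad[1], " (",
         gsub("\\|", " / ", key[bad[1]]), "): ", df$exposure[bad[1]])
  }
  ai <- match(df$age_group, ag$label)
  pi <- match(df$period, pl)
  si <- match(df$sex, c("M", "F"))
  if (any(is.na(si))) stop('sex must be "M" or "F"')
  deaths <- array(0L, c(grid$n_age, grid$n_period, 2L))
  exposure <- array(0, c(grid$n_age, grid$n_period, 2L))
  deaths[cbind(ai, pi, si)] <- as.integer(df$deaths)
  exposure[cbind(ai, pi, si)] <- df$exposure
  lexis_table(grid, deaths, exposure, cause_label)
}
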