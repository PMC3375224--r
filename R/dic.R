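# Deviance and DIC. The deviance uses the saturated-model (scale-free) form,
# which is zero for a perfect fit and handles empty cells; DIC differences
# between models on the same data are identical under the saturated and the
# raw -2logL conventions, and differences are all the menu comparison uses.

#' Poisson deviance of an APC model fit
#'
#' Saturated-form deviance
#' \deqn{D = 2 \sum_{cells} [y \log(y/\mu) - (y - \mu)]}
#' with \eqn{\mu = E e^{\eta}} and the convention `y log(y/mu) = 0` at
#' `y = 0`. Non-negative, and zero iff the fit is saturated.
#'
#' @param table A [lexis_table()].
#' @param design A [build_design()] object.
#' @param beta Free parameter vector (or a matrix of draws, one per row, in
#'   which case a vector of deviances is returned).
#' @return Scalar deviance (or vector, for a matrix of draws).
#' @export
deviance_poisson <- function(table, design, beta) {
  tv <- table_vectors(table, design)
  beta <- if (is.matrix(beta)) beta else matrix(beta, nrow = 1)
  if (ncol(beta) != design$n_par) stop("beta must have ", design$n_par,
                                       " columns")
  if (any(!is.finite(beta))) stop("non-finite parameter values")
  eta <- design$X %*% t(beta)            # n_cells x n_draws
  mu <- tv$E * exp(eta)
  ylt <- tv$y * log(tv$y / mu)           # y log(y/mu), rows recycle y
  ylt[tv$y == 0, ] <- 0                  # convention: 0 log 0 = 0
  dev <- 2 * colSums(ylt - (tv$y - mu))
  if (length(dev) == 1L) dev[[1]] else as.numeric(dev)
}

#' Deviance information criterion of a fitted model
#'
#' `Dbar` is the posterior mean deviance, `Dhat` the deviance at the
#' posterior mean of the parameters (the original mean-parameterization
#' plug-in), `pD = Dbar - Dhat` the effective number of parameters, and
#' `DIC = Dbar + pD = Dhat + 2 pD`. A smaller DIC implies a better fit.
#' Negative `pD` (possible when the posterior mean is a poor plug-in) is
#' reported and flagged, never hidden.
#'
#' @param samples An `apc_samples` object.
#' @param table The [lexis_table()] the model was fitted to.
#' @param model_label Optional label (default: the design's structure label).
#' @return An object of class `dic_result` with fields `model_label`, `Dbar`,
#'   `Dhat`, `pD`, `DIC` and `pD_negative`.
#' @export
dic <- function(samples, table, model_label = NULL) {
  stopifnot(is_apc_samples(samples))
  beta <- pooled_draws(samples, "beta")
  if (nrow(beta) == 0L) stop("empty posterior samples")
  devs <- deviance_poisson(table, samples$design, beta)
  Dbar <- mean(devs)
  Dhat <- deviance_poisson(table, samples$design, colMeans(beta))
  pD <- Dbar - Dhat
  structure(list(model_label = if (is.null(model_label))
                   design_label(samples$design) else model_label,
                 Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD,
                 pD_negative = pD < 0),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("%s: DIC = %.1f (Dbar %.1f, Dhat %.1f, pD %.1f%s)\n",
              x$model_label, x$DIC, x$Dbar, x$Dhat, x$pD,
              if (x$pD_negative) ", pD < 0 flagged" else ""))
  invisible(x)
}

#' Default model menu for DIC comparison
#'
#' The classical ladder of partial APC models: age only, age-period,
#' age-cohort, the full age-period-cohort model, the full model with a sex
#' offset, and the full model with all sex interactions.
#'
#' @return Named list of `list(terms, sex_terms)` entries.
#' @export
default_model_menu <- function() {
  list(
    A = list(terms = "age", sex_terms = character()),
    AP = list(terms = c("age", "period"), sex_terms = character()),
    AC = list(terms = c("age", "cohort"), sex_terms = character()),
    APC = list(terms = c("age", "period", "cohort"),
               sex_terms = character()),
    `APC+sexoff` = list(terms = c("age", "period", "cohort"),
                        sex_terms = "offset"),
    `APC+sexint` = list(terms = c("age", "period", "cohort"),
                        sex_terms = c("offset", "age", "period", "cohort")))
}

#' Fit a menu of APC models and compare them by DIC
#'
#' Fits every menu entry to the same table with a shared prior and MCMC
#' configuration (both sexes always stacked in one likelihood), computes each
#' model's DIC, and returns the results sorted ascending with the winner
#' flagged. A single model's failure is recorded in its row, not fatal to the
#' menu. Deterministic given the configuration seed.
#'
#' @param table A [lexis_table()].
#' @param menu Named list of `list(terms, sex_terms)` entries (default
#'   [default_model_menu()]).
#' @param priors A [prior_spec()] object.
#' @param config An [mcmc_config()] object.
#' @param keep_fits Keep the full `apc_samples` of every model in the result
#'   (`FALSE` by default: the fits are large).
#' @return An object of class `apc_menu_result`; `$table` is a data frame
#'   (model, Dbar, Dhat, pD, DIC, max_rhat, winner, error), sorted by DIC
#'   with failed fits last.
#' @export
fit_model_menu <- function(table, menu = default_model_menu(),
                           priors = prior_spec(), config = mcmc_config(),
                           keep_fits = FALSE) {
  stopifnot(is_lexis_table(table), length(menu) >= 1L)
  if (is.null(names(menu))) names(menu) <- paste0("model", seq_along(menu))
  rows <- vector("list", length(menu))
  fits <- if (keep_fits) vector("list", length(menu)) else NULL
  for (i in seq_along(menu)) {
    m <- menu[[i]]
    rows[[i]] <- tryCatch({
      design <- build_design(table$grid, m$terms, m$sex_terms,
                             reference_periods = m$reference_periods,
                             reference_cohort = m$reference_cohort)
      fit <- run_mcmc(table, design, priors, config)
      d <- dic(fit, table, model_label = names(menu)[i])
      if (keep_fits) fits[[i]] <<- fit
      data.frame(model = names(menu)[i], Dbar = d$Dbar, Dhat = d$Dhat,
                 pD = d$pD, DIC = d$DIC,
                 max_rhat = max(rhat_all(fit), na.rm = TRUE),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(model = names(menu)[i], Dbar = NA_real_, Dhat = NA_real_,
                 pD = NA_real_, DIC = NA_real_, max_rhat = NA_real_,
                 error = conditionMessage(e))
    })
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$DIC, na.last = TRUE), ]
  rownames(res) <- NULL
  res$winner <- FALSE
  if (any(!is.na(res$DIC))) res$winner[1] <- TRUE
  structure(list(table = res, fits = fits,
                 winner = if (any(res$winner)) res$model[res$winner] else
                   NA_character_),
            class = "apc_menu_result")
}

#' @export
print.apc_menu_result <- function(x, ...) {
  cat("DIC model menu (winner: ", x$winner, ")\n", sep = "")
  print(x$table, digits = 5)
  invisible(x)
}

#' Write a DIC menu result as delimited text
#' @param result An `apc_menu_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_menu <- function(result, path) {
  stopifnot(inherits(result, "apc_menu_result"))
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
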