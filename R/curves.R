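# Second-order analysis of estimated effect curves. Because the APC linear
# trends are not identified, only changes of slope (second differences) of
# the age/period/cohort curves are interpretable; everything here is built
# from second differences and is therefore invariant to adding any
# linear-in-index drift to the curves.

#' Second differences of an effect curve
#'
#' \eqn{d_i = x_{i+1} - 2 x_i + x_{i-1}} for the interior indices
#' `i = 2 .. length(x) - 1`. Linear vectors map to zeros, and adding
#' `delta * index` to the curve leaves the result unchanged.
#'
#' @param curve Numeric vector of length >= 3.
#' @return Numeric vector of length `length(curve) - 2`.
#' @export
second_differences <- function(curve) {
  curve <- as.numeric(curve)
  if (length(curve) < 3L) stop("curve must have length >= 3")
  diff(curve, differences = 2)
}

#' Posterior curvature report for one effect curve
#'
#' Computes the second differences of the curve in every posterior draw and
#' summarizes, per interior index: posterior mean, equal-tailed 95% interval,
#' and the posterior probability that the second difference is negative. An
#' index is flagged as a downturn when `P(d < 0) > prob_threshold` and as an
#' upturn when `P(d > 0) > prob_threshold`; with a degenerate linear curve
#' both probabilities are zero and nothing is flagged. Raising the threshold
#' never adds flags.
#'
#' @param samples An `apc_samples` object.
#' @param term `"age"`, `"period"` or `"cohort"` (must be in the design).
#' @param sex `"M"` or `"F"` (female curve = male + deviation).
#' @param prob_threshold Flagging probability (default 0.9).
#' @param level Credible level for the intervals (default 0.95).
#' @return An object of class `curvature_report`; `$table` has one row per
#'   interior index with columns `index` (position in the curve), `label`,
#'   `mean`, `lower`, `upper`, `p_negative`, `p_positive`, `downturn`,
#'   `upturn`.
#' @export
curvature_report <- function(samples, term, sex = "M", prob_threshold = 0.9,
                             level = 0.95) {
  stopifnot(is_apc_samples(samples))
  term <- match.arg(term, c("age", "period", "cohort"))
  if (!term %in% samples$design$terms) {
    stop("term '", term, "' not in the fitted design")
  }
  if (prob_threshold < 0 || prob_threshold > 1) {
    stop("prob_threshold must be in [0, 1]")
  }
  cd <- curve_draws(samples, term, sex)
  n <- ncol(cd)
  if (n < 3L) stop("curve too short for second differences")
  D <- cd[, 3:n, drop = FALSE] - 2 * cd[, 2:(n - 1), drop = FALSE] +
    cd[, 1:(n - 2), drop = FALSE]
  a <- (1 - level) / 2
  qs <- apply(D, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  p_neg <- colMeans(D < 0)
  p_pos <- colMeans(D > 0)
  labs <- level_labels(samples$design, term)
  tab <- data.frame(index = 2:(n - 1), label = labs[2:(n - 1)],
                    mean = colMeans(D), lower = qs[1, ], upper = qs[2, ],
                    p_negative = p_neg, p_positive = p_pos,
                    downturn = p_neg > prob_threshold,
                    upturn = p_pos > prob_threshold)
  rownames(tab) <- NULL
  structure(list(table = tab, term = term, sex = sex,
                 prob_threshold = prob_threshold,
                 downturn_indices = tab$index[tab$downturn],
                 upturn_indices = tab$index[tab$upturn]),
            class = "curvature_report")
}

#' @export
print.curvature_report <- function(x, ...) {
  cat("Curvature report: ", x$term, " curve, sex ", x$sex,
      ", threshold ", x$prob_threshold, "\n", sep = "")
  if (length(x$downturn_indices)) {
    cat("  downturns at index ", paste(x$downturn_indices, collapse = ", "),
        " (label ", paste(x$table$label[x$table$downturn], collapse = ", "),
        ")\n", sep = "")
  }
  if (length(x$upturn_indices)) {
    cat("  upturns at index ", paste(x$upturn_indices, collapse = ", "),
        "\n", sep = "")
  }
  if (!length(x$downturn_indices) && !length(x$upturn_indices)) {
    cat("  no flags\n")
  }
  invisible(x)
}

#' Sex-divergence summary of one effect curve
#'
#' Summarizes the female-minus-male deviation curve of a term (posterior mean
#' and 95% interval per level) and the post-inflection slope difference: the
#' least-squares slope of the deviation curve over the indices at and after
#' the flagged inflection, computed per draw. The inflection defaults to the
#' strongest flagged downturn of the female curve (falling back to the male
#' curve, then to the most negative posterior-mean second difference); it can
#' be overridden with `from_index`. If the corresponding sex interaction was
#' not in the model, the result is explicitly "not estimable", never a row of
#' zeros.
#'
#' @param samples An `apc_samples` object.
#' @param term `"age"`, `"period"` or `"cohort"`.
#' @param from_index Optional 1-based curve index from which the slope is
#'   computed.
#' @param prob_threshold Flagging threshold used for the default inflection
#'   (default 0.9).
#' @param level Credible level (default 0.95).
#' @return An object of class `sex_divergence`. When estimable: `$levels`
#'   (per-level deviation summaries), `$slope` (mean, lower, upper,
#'   p_negative), `$from_index`, and `$steeper_decline` (`TRUE` when the
#'   slope-difference interval lies below zero).
#' @export
sex_divergence <- function(samples, term, from_index = NULL,
                           prob_threshold = 0.9, level = 0.95) {
  stopifnot(is_apc_samples(samples))
  term <- match.arg(term, c("age", "period", "cohort"))
  design <- samples$design
  dmap <- design$index_map[[paste0("sex_", term)]]
  if (is.null(dmap)) {
    return(structure(list(estimable = FALSE, term = term,
                          reason = paste0("no sex interaction with '", term,
                                          "' in the fitted model")),
                     class = "sex_divergence"))
  }
  beta <- pooled_draws(samples, "beta")
  n <- length(dmap)
  dev <- matrix(0, nrow(beta), n)
  ok <- !is.na(dmap)
  dev[, ok] <- beta[, dmap[ok], drop = FALSE]
  a <- (1 - level) / 2
  qs <- apply(dev, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  levels <- data.frame(index = seq_len(n),
                       label = level_labels(design, term),
                       mean = colMeans(dev), lower = qs[1, ], upper = qs[2, ],
                       reference = is.na(dmap))
  if (is.null(from_index)) {
    pick <- function(cr) {
      if (length(cr$downturn_indices)) {
        dt <- cr$table[cr$table$downturn, ]
        dt$index[which.min(dt$mean)]
      } else NA_integer_
    }
    from_index <- pick(curvature_report(samples, term, "F", prob_threshold))
    if (is.na(from_index)) {
      from_index <- pick(curvature_report(samples, term, "M", prob_threshold))
    }
    if (is.na(from_index)) {
      crF <- curvature_report(samples, term, "F", prob_threshold)
      from_index <- crF$table$index[which.min(crF$table$mean)]
    }
  }
  from_index <- as.integer(from_index)
  if (from_index < 1L || from_index > n - 1L) {
    stop("from_index must leave at least two levels for the slope")
  }
  idx <- from_index:n
  cidx <- idx - mean(idx)
  slope_draws <- as.numeric(dev[, idx, drop = FALSE] %*% cidx) / sum(cidx^2)
  slope <- list(mean = mean(slope_draws),
                lower = stats::quantile(slope_draws, a, names = FALSE),
                upper = stats::quantile(slope_draws, 1 - a, names = FALSE),
                p_negative = mean(slope_draws < 0))
  structure(list(estimable = TRUE, term = term, levels = levels,
                 slope = slope, from_index = from_index,
                 steeper_decline = slope$upper < 0),
            class = "sex_divergence")
}

#' @export
print.sex_divergence <- function(x, ...) {
  if (!x$estimable) {
    cat("Sex divergence (", x$term, "): not estimable - ", x$reason, "\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("Sex divergence (%s): post-inflection slope difference ",
                     "%.4f [%.4f, %.4f] from index %d%s\n"),
              x$term, x$slope$mean, x$slope$lower, x$slope$upper,
              x$from_index,
              if (x$steeper_decline) " (steeper decline in women)" else ""))
  invisible(x)
}
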