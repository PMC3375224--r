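#!/usr/bin/env Rscript
# Step 2: fit the full Bayesian APC model (age + period + cohort, sex offset
# and all sex interactions) to the septicaemia-like and pneumonia-like
# registries, check convergence, and write the posterior effect summaries.
#
# Usage: Rscript analysis/02_fit.R [--seed 1] [--out-dir results]
#                                  [--scale test|paper]

source(file.path(dirname(sub("^--file=", "",
  grep("^--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

flags <- parse_flags(list(seed = "1", `out-dir` = "results", scale = "test"))
out <- flags$`out-dir`

for (name in c("septicaemia_like", "pneumonia_like")) {
  counts <- file.path(out, "data", paste0(name, ".csv"))
  if (!file.exists(counts)) {
    stop("counts file missing: ", counts, " (run 01_simulate.R first)")
  }
  tab <- read_counts(counts)
  design <- build_design(tab$grid, c("age", "period", "cohort"),
                         c("offset", "age", "period", "cohort"))
  cfg <- fit_config(flags$scale, flags$seed)
  msg("fitting %s: %d free parameters, %d chains x (%d burn + %d kept)",
      name, design$n_par, cfg$n_chains, cfg$n_burn, cfg$n_keep)
  fit <- run_mcmc(tab, design, prior_spec(), cfg)
  r <- rhat_all(fit)
  write.csv(data.frame(parameter = names(r), rhat = unname(r)),
            file.path(out, paste0("rhat_", name, ".csv")), row.names = FALSE)
  if (any(r >= 1.1, na.rm = TRUE)) {
    msg("WARNING: %d parameter(s) above R-hat 1.1 in %s (max %.3f)",
        sum(r >= 1.1, na.rm = TRUE), name, max(r, na.rm = TRUE))
  } else {
    msg("converged: all %d R-hat values below 1.1 (max %.3f)",
        length(r), max(r, na.rm = TRUE))
  }
  s <- summarize_effects(fit)
  write.csv(s$effects, file.path(out, paste0("effects_", name, ".csv")),
            row.names = FALSE)
  write.csv(s$scalars, file.path(out, paste0("scalars_", name, ".csv")),
            row.names = FALSE)
  write_draws(fit, file.path(out, paste0("draws_", name, ".csv")),
              thin = 40L)
  d <- dic(fit, tab)
  msg("%s: Dbar %.1f, pD %.1f, DIC %.1f", name, d$Dbar, d$pD, d$DIC)
}
write_manifest(out, "02_fit",
               c("data/septicaemia_like.csv", "data/pneumonia_like.csv"),
               flags$seed)
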