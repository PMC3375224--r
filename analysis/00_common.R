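# Shared helpers for the analysis drivers: flag parsing, output locations,
# and the run manifest. Each numbered script is a thin narrative layer over
# the apcmort package; all computation lives in the package itself.

suppressPackageStartupMessages(library(apcmort))

parse_flags <- function(defaults) {
  args <- commandArgs(trailingOnly = TRUE)
  flags <- defaults
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(flags)) stop("unknown flag: --", key)
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags$seed <- as.integer(flags$seed)
  flags
}

msg <- function(...) cat(sprintf(...), "\n", sep = "", file = stderr())

# scaled-down settings keep a full run in seconds; "paper" mirrors the
# reporting scale (5 chains, 10,000 burn-in, 40,000 kept)
fit_config <- function(scale, seed) {
  if (identical(scale, "paper")) {
    mcmc_config(n_chains = 5, n_burn = 10000, n_keep = 40000, seed = seed)
  } else {
    mcmc_config(n_chains = 4, n_burn = 1000, n_keep = 4000, seed = seed)
  }
}

write_manifest <- function(dir, step, inputs, seed) {
  lines <- c(paste0("step = ", step),
             paste0("package_version = ",
                    as.character(utils::packageVersion("apcmort"))),
             paste0("seed = ", seed),
             paste0("inputs = ", paste(inputs, collapse = "; ")),
             paste0("written = ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(lines, file.path(dir, paste0("manifest_", step, ".txt")))
}
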