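#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's pipeline functions.
#
#   Rscript scripts/enviro-gs.R simulate --preset usp|indica|custom --seed N --out DIR
#   Rscript scripts/enviro-gs.R run --config CONFIG.yaml
#   Rscript scripts/enviro-gs.R report --in DIR

suppressPackageStartupMessages(library(enviroGS))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: enviro-gs.R <simulate|run|report> [options]", call. = FALSE)
}
cmd <- args[1]
opts <- args[-1]
get_opt <- function(flag, default = NULL) {
  i <- which(opts == flag)
  if (length(i) == 1 && i < length(opts)) opts[i + 1] else default
}

if (cmd == "simulate") {
  dir <- get_opt("--out", "simulated_trial")
  preset <- get_opt("--preset", "usp")
  seed <- as.integer(get_opt("--seed", "1"))
  sim <- simulate_to_dir(dir, preset = preset, seed = seed)
  cat("wrote trial to", dir, "\n")
  print(sim$trial)
} else if (cmd == "run") {
  cfg <- get_opt("--config")
  if (is.null(cfg)) stop("run needs --config CONFIG.yaml", call. = FALSE)
  report <- run_pipeline(cfg)
  print(report)
} else if (cmd == "report") {
  dir <- get_opt("--in")
  if (is.null(dir)) stop("report needs --in DIR", call. = FALSE)
  cells <- utils::read.csv(file.path(dir, "metrics_cells.csv"),
                           stringsAsFactors = FALSE)
  print(comparison_report(cells))
} else {
  stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
}
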