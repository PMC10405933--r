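# File-based pipeline: CSV readers/writers for the three inputs, a simulate
# stage, a run stage (LOEO benchmark) and a manifest for reproducibility.

#' Write a trial to the pipeline's three CSV files
#'
#' `phenotype.csv` (long format), `markers.csv` (rows = lines, first column
#' `genotype_id`), `env_covariates.csv` (rows = environments, first column
#' `env_id`).
#'
#' @param trial a [trial_data].
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_trial_csv <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pheno = file.path(dir, "phenotype.csv"),
             geno = file.path(dir, "markers.csv"),
             envcov = file.path(dir, "env_covariates.csv"))
  utils::write.csv(trial$observations, paths["pheno"], row.names = FALSE)
  gm <- data.frame(genotype_id = rownames(trial$markers), trial$markers,
                   check.names = FALSE)
  utils::write.csv(gm, paths["geno"], row.names = FALSE)
  em <- data.frame(env_id = rownames(trial$env_covariates),
                   trial$env_covariates, check.names = FALSE)
  utils::write.csv(em, paths["envcov"], row.names = FALSE)
  invisible(paths)
}

#' Read a trial from the pipeline's CSV files
#'
#' @param pheno,geno,envcov file paths as written by [write_trial_csv].
#' @return a [trial_data].
#' @export
read_trial_csv <- function(pheno, geno, envcov) {
  obs <- utils::read.csv(pheno, stringsAsFactors = FALSE)
  gm <- utils::read.csv(geno, check.names = FALSE, stringsAsFactors = FALSE)
  em <- utils::read.csv(envcov, check.names = FALSE, stringsAsFactors = FALSE)
  markers <- as.matrix(gm[, -1, drop = FALSE])
  rownames(markers) <- gm[[1]]
  env_cov <- as.matrix(em[, -1, drop = FALSE])
  rownames(env_cov) <- em[[1]]
  trial_data(obs, markers, env_cov)
}

#' Simulate a trial and write it (plus its truth manifest) to a directory
#'
#' @param dir output directory.
#' @param preset `"usp"` (4 environments x 100 lines, one trait),
#'   `"indica"` (3 environments x 327 lines, 18 covariates) or `"custom"`.
#' @param seed integer seed.
#' @param ... [simulate_trial] arguments (required when `preset = "custom"`,
#'   override the preset otherwise).
#' @return invisibly, the simulated `list(trial, truth)`.
#' @export
simulate_to_dir <- function(dir, preset = c("usp", "indica", "custom"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    usp = list(J = 100, I = 4, p = 300, r = 50, n_informative = 5),
    indica = list(J = 327, I = 3, p = 1000, r = 18, n_informative = 4),
    custom = list())
  dots <- list(...)
  args[names(dots)] <- dots
  args$seed <- seed
  sim <- do.call(simulate_trial, args)
  write_trial_csv(sim$trial, dir)
  truth <- sim$truth
  jsonlite::write_json(
    list(seed = seed, preset = preset,
         parameters = args[setdiff(names(args), "seed")],
         informative_covariates = truth$informative_covariates,
         beta_true = truth$beta_true,
         var_components_true = as.list(truth$var_components_true)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop_gs("config must be a list or a YAML file path",
            "enviroGS_config_error")
  }
  if (is.null(config$out)) {
    stop_gs("config key `out` (output directory) is required",
            "enviroGS_config_error")
  }
  models <- config$models %||% paste0("M", 0:14)
  bad <- setdiff(models, model_registry()$model_id)
  if (length(bad) > 0) {
    stop_gs(sprintf("config key `models` contains unknown model id(s): %s",
                    paste(bad, collapse = ", ")), "enviroGS_config_error")
  }
  config$models <- models
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop_gs("config needs either `simulate` or `inputs` (pheno/geno/envcov)",
            "enviroGS_config_error")
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulate -> benchmark -> report pipeline from a configuration
#'
#' The configuration (list or YAML path) names either input CSVs
#' (`inputs: pheno/geno/envcov`) or a `simulate:` block with
#' [simulate_trial] arguments, plus `models`, optional `traits`, `seed`,
#' `mcmc` overrides (n_iter/burn_in/thin) and the output directory `out`.
#' Writes `metrics_cells.csv`, `summary.csv`, `win_counts.csv` and a
#' `manifest.json` recording seeds, package version and input checksums.
#'
#' @param config list or YAML file path.
#' @return invisibly, the [comparison_report].
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  input_files <- NULL
  if (!is.null(config$inputs)) {
    ip <- config$inputs
    trial <- read_trial_csv(ip$pheno, ip$geno, ip$envcov)
    input_files <- unlist(ip)
  } else {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% derive_seed(seed, "simulate")
    trial <- do.call(simulate_trial, sim_args)$trial
  }

  mcmc_args <- config$mcmc %||% list()
  mc <- do.call(mcmc_config, mcmc_args)
  bcfg_args <- list(mcmc = mc, seed = derive_seed(seed, "loeo"))
  if (!is.null(config$boruta)) bcfg_args$boruta <- config$boruta
  if (!is.null(config$nrmse_normalization)) {
    bcfg_args$nrmse_normalization <- config$nrmse_normalization
  }
  bcfg <- do.call(bench_config, bcfg_args)

  cells <- loeo_run(trial, traits = config$traits, models = config$models,
                    config = bcfg, verbose = isTRUE(config$verbose))
  base <- config$baseline %||%
    (if ("M0" %in% config$models) "M0" else config$models[1])
  report <- comparison_report(cells, baseline = base)

  utils::write.csv(cells, file.path(out_dir, "metrics_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  win <- rbind(cbind(level = "environment", report$win_env),
               cbind(level = "trait", report$win_trait))
  utils::write.csv(win, file.path(out_dir, "win_counts.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "enviroGS",
    version = as.character(utils::packageVersion("enviroGS")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = seed,
    derived_seeds = list(simulate = derive_seed(seed, "simulate"),
                         loeo = derive_seed(seed, "loeo")),
    models = config$models,
    checksums = if (!is.null(input_files))
      as.list(tools::md5sum(input_files)) else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
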