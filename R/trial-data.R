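#' Multi-environment trial data container
#'
#' Bundles the three inputs of the prediction pipeline: a long-format
#' phenotype table, a line-by-marker matrix of minor-allele counts (0/1/2)
#' and an environment-by-covariate matrix. Identifiers are resolved through
#' the row names of the two matrices; unbalanced designs (a genotype absent
#' from some environments) are supported.
#'
#' @param observations data.frame with columns `env_id`, `genotype_id`,
#'   `trait_id`, `value` (one phenotypic record per row).
#' @param markers integer matrix, lines x markers, entries in \{0,1,2\},
#'   row names = genotype ids.
#' @param env_covariates numeric matrix, environments x covariates,
#'   row names = environment ids.
#' @return An object of class `trial_data`.
#' @export
trial_data <- function(observations, markers, env_covariates) {
  observations <- as.data.frame(observations)
  needed <- c("env_id", "genotype_id", "trait_id", "value")
  if (!all(needed %in% names(observations))) {
    stop_gs(paste("observations must have columns",
                  paste(needed, collapse = ", ")), "enviroGS_argument_error")
  }
  observations$env_id <- as.character(observations$env_id)
  observations$genotype_id <- as.character(observations$genotype_id)
  observations$trait_id <- as.character(observations$trait_id)
  observations$value <- as.numeric(observations$value)
  markers <- as.matrix(markers)
  env_covariates <- as.matrix(env_covariates)
  if (is.null(rownames(markers))) {
    stop_gs("markers must carry genotype ids as row names", "enviroGS_argument_error")
  }
  if (is.null(rownames(env_covariates))) {
    stop_gs("env_covariates must carry environment ids as row names",
            "enviroGS_argument_error")
  }
  bad <- markers[!is.na(markers) & !(markers %in% c(0, 1, 2))]
  if (length(bad) > 0 || anyNA(markers)) {
    stop_gs("markers must contain only values 0, 1 or 2", "enviroGS_argument_error")
  }
  miss_env <- setdiff(unique(observations$env_id), rownames(env_covariates))
  if (length(miss_env) > 0) {
    stop_gs(paste("environments without covariate rows:",
                  paste(miss_env, collapse = ", ")), "enviroGS_argument_error")
  }
  miss_g <- setdiff(unique(observations$genotype_id), rownames(markers))
  if (length(miss_g) > 0) {
    stop_gs(paste("genotypes without marker rows:",
                  paste(utils::head(miss_g, 5), collapse = ", ")),
            "enviroGS_argument_error")
  }
  if (anyDuplicated(rownames(env_covariates)) || anyDuplicated(rownames(markers))) {
    stop_gs("duplicated ids in markers or env_covariates", "enviroGS_argument_error")
  }
  structure(
    list(observations = observations, markers = markers,
         env_covariates = env_covariates),
    class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf(
    "trial_data: %d observations | %d environments | %d genotypes | %d traits\n",
    nrow(x$observations), nrow(x$env_covariates), nrow(x$markers),
    length(unique(x$observations$trait_id))))
  cat(sprintf("  markers: %d lines x %d markers (0/1/2)\n",
              nrow(x$markers), ncol(x$markers)))
  cat(sprintf("  env covariates: %d x %d\n",
              nrow(x$env_covariates), ncol(x$env_covariates)))
  invisible(x)
}

#' Traits present in a trial
#' @param trial a `trial_data` object
#' @return character vector of trait ids
#' @export
trial_traits <- function(trial) unique(trial$observations$trait_id)

#' Environments present in a trial
#' @param trial a `trial_data` object
#' @return character vector of environment ids (covariate-row order)
#' @export
trial_envs <- function(trial) rownames(trial$env_covariates)
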