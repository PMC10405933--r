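# Engineered covariate blocks for the fixed-regression term: expansion of
# environment-level covariates to observation level, the sign-aligned average
# covariate Xe.avg, and the quadratic augmentation Xe2 = [Xe | Xe^2].

#' Expand environment-level covariates to observation level
#'
#' Every observation receives the covariate row of its environment
#' (`Ze %*% Xe`); covariates are constant within an environment.
#'
#' @param env_covariates numeric matrix, environments x covariates, rows in
#'   the environment order of `design`.
#' @param design a [build_design_matrices] result.
#' @return numeric matrix, observations x covariates.
#' @export
expand_to_observations <- function(env_covariates, design) {
  env_covariates <- as.matrix(env_covariates)
  if (nrow(env_covariates) != ncol(design$Ze)) {
    stop_gs("env_covariates rows must match the design's environment count",
            "enviroGS_argument_error")
  }
  design$Ze %*% env_covariates
}

#' Sign-aligned average covariate (Xe.avg)
#'
#' Three steps, with correlations computed on training rows only:
#' (1) the training correlation of each selected covariate with the response
#' fixes its direction; (2) negatively correlated columns are multiplied by
#' -1 so every column associates positively with the response; (3) the
#' per-environment row mean of the aligned columns, over all environments
#' (training and held-out), is the single engineered covariate.
#'
#' @param env_covariates_selected I x r_s matrix of selected covariates
#'   (all environments).
#' @param y_train training responses.
#' @param design_train [build_design_matrices]-style design restricted to
#'   the training observations (its `Ze` must have I columns).
#' @return list with `xe_avg` (length-I vector), `sign_flips` (indices of
#'   flipped source columns) and `correlations`.
#' @export
signed_average <- function(env_covariates_selected, y_train, design_train) {
  Xe <- as.matrix(env_covariates_selected)
  if (ncol(Xe) < 1) {
    stop_gs("no covariates supplied to signed_average",
            "enviroGS_degenerate_error")
  }
  X_obs <- expand_to_observations(Xe, design_train)
  if (nrow(X_obs) != length(y_train)) {
    stop_gs("design_train and y_train are not row-aligned",
            "enviroGS_argument_error")
  }
  sds <- apply(X_obs, 2, stats::sd)
  cors <- rep(0, ncol(Xe))
  ok <- which(sds > 0)
  if (length(ok) > 0) {
    cors[ok] <- as.numeric(stats::cor(X_obs[, ok, drop = FALSE], y_train))
  }
  flips <- which(cors < 0)
  Xe_star <- Xe
  if (length(flips) > 0) Xe_star[, flips] <- -Xe_star[, flips]
  list(xe_avg = rowMeans(Xe_star), sign_flips = flips, correlations = cors)
}

#' Quadratic augmentation (Xe2)
#'
#' Standardizes the selected covariates, appends the elementwise square of
#' each standardized column (itself re-standardized), and returns the
#' concatenated block. Squares that come out constant (e.g. a symmetric
#' two-level column) are dropped with a warning.
#'
#' @param env_covariates_selected I x r_s matrix of selected covariates.
#' @return numeric matrix with up to 2 * r_s columns.
#' @export
quadratic_augment <- function(env_covariates_selected) {
  Xe <- as.matrix(env_covariates_selected)
  if (ncol(Xe) < 1) {
    stop_gs("no covariates supplied to quadratic_augment",
            "enviroGS_degenerate_error")
  }
  Xe_std <- standardize_columns(Xe)
  if (is.null(colnames(Xe_std))) {
    colnames(Xe_std) <- sprintf("x%d", seq_len(ncol(Xe_std)))
  }
  sq <- Xe_std^2
  sq_std <- tryCatch(standardize_columns(sq),
                     enviroGS_degenerate_error = function(e) NULL)
  if (is.null(sq_std)) {
    warning("all squared covariate columns are constant; returning Xe only")
    out <- Xe_std
  } else {
    colnames(sq_std) <- paste0(colnames(Xe_std)[attr(sq_std, "kept")], "^2")
    out <- cbind(Xe_std, sq_std)
  }
  attr(out, "kept") <- NULL
  out
}
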