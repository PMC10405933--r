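# Relationship and design matrices for the kernel mixed model.
#
# Observation-level model for trait value y_ij of genotype j in environment i:
#   y = mu + Ze E + Zg g + gE + X beta + e
# with E ~ N(0, sE2 H.e), g ~ N(0, sg2 K.g), gE ~ N(0, sgE2 K.gec).
# K.g = Me Me'/p on column-standardized markers; H.e = Xe Xe'/r on
# column-standardized environmental covariates; K.e = Ze Ze'/I;
# K.ec = Ze H.e Ze'; K.ge / K.gec = (env kernel) Hadamard (Zg K.g Zg').

#' Column standardization with degenerate-column handling
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (n-1 denominator). Zero-variance columns cannot be scaled and are
#' dropped with a warning; the indices of the retained source columns are
#' attached as attribute `"kept"`.
#'
#' @param M numeric matrix with at least two rows.
#' @return Standardized matrix (possibly fewer columns), with attribute
#'   `kept` mapping its columns back to columns of `M`.
#' @export
standardize_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) {
    stop_gs("standardization needs at least 2 rows", "enviroGS_argument_error")
  }
  mu <- colMeans(M)
  s <- apply(M, 2, stats::sd)
  keep <- which(s > 0 & is.finite(s))
  if (length(keep) == 0) {
    stop_gs("all columns are constant; nothing to standardize",
            "enviroGS_degenerate_error")
  }
  if (length(keep) < ncol(M)) {
    warning(sprintf("dropping %d zero-variance column(s) during standardization",
                    ncol(M) - length(keep)))
  }
  out <- sweep(M[, keep, drop = FALSE], 2, mu[keep], "-")
  out <- sweep(out, 2, s[keep], "/")
  attr(out, "kept") <- unname(keep)
  out
}

#' Environment and genotype incidence matrices for one trait
#'
#' Rows follow the trait's observation list; each row carries a single 1
#' marking the observation's environment (`Ze`, n x I) or genotype
#' (`Zg`, n x J).
#'
#' @param trial a [trial_data] object.
#' @param trait trait id present in the trial.
#' @return list with `Ze`, `Zg`, `env_levels`, `genotype_levels`, `obs`
#'   (the trait's observation table) of class `design_matrices`.
#' @export
build_design_matrices <- function(trial, trait) {
  if (!trait %in% trial$observations$trait_id) {
    stop_gs(sprintf("trait '%s' not present in trial", trait),
            "enviroGS_argument_error")
  }
  obs <- trial$observations[trial$observations$trait_id == trait, , drop = FALSE]
  env_levels <- rownames(trial$env_covariates)
  geno_levels <- rownames(trial$markers)
  ei <- match(obs$env_id, env_levels)
  gi <- match(obs$genotype_id, geno_levels)
  n <- nrow(obs)
  Ze <- matrix(0, n, length(env_levels), dimnames = list(NULL, env_levels))
  Zg <- matrix(0, n, length(geno_levels), dimnames = list(NULL, geno_levels))
  Ze[cbind(seq_len(n), ei)] <- 1
  Zg[cbind(seq_len(n), gi)] <- 1
  structure(list(Ze = Ze, Zg = Zg, env_levels = env_levels,
                 genotype_levels = geno_levels, obs = obs),
            class = "design_matrices")
}

#' Genomic relationship matrix K.g = Me Me' / p
#'
#' Markers are column-standardized over all lines; monomorphic markers are
#' dropped. The divisor is the number of retained marker columns.
#'
#' @param markers integer matrix, lines x markers, entries in \{0,1,2\}.
#' @return J x J symmetric PSD matrix.
#' @export
genomic_kernel <- function(markers) {
  markers <- as.matrix(markers)
  if (nrow(markers) < 2 || ncol(markers) < 1) {
    stop_gs("genomic kernel needs >= 2 lines and >= 1 marker",
            "enviroGS_argument_error")
  }
  Me <- tryCatch(standardize_columns(markers),
                 enviroGS_degenerate_error = function(e)
                   stop_gs("no polymorphic marker available",
                           "enviroGS_degenerate_error"))
  K <- tcrossprod(Me) / ncol(Me)
  dimnames(K) <- list(rownames(markers), rownames(markers))
  ensure_psd(K, label = "K.g")
}

#' Environmental relationship matrix H.e = Xe Xe' / r
#'
#' Same construction as the genomic kernel but over environments x
#' standardized environmental covariates.
#'
#' @param env_covariates numeric matrix, environments x covariates.
#' @return I x I symmetric PSD matrix.
#' @export
env_covariate_kernel <- function(env_covariates) {
  env_covariates <- as.matrix(env_covariates)
  if (ncol(env_covariates) < 1) {
    stop_gs("no environmental covariates supplied", "enviroGS_degenerate_error")
  }
  if (nrow(env_covariates) < 2) {
    stop_gs("environmental kernel needs >= 2 environments",
            "enviroGS_argument_error")
  }
  Xe <- standardize_columns(env_covariates)
  K <- tcrossprod(Xe) / ncol(Xe)
  dimnames(K) <- list(rownames(env_covariates), rownames(env_covariates))
  ensure_psd(K, label = "H.e")
}

#' Observation-level environment kernel: K.e or K.ec
#'
#' Without `H_e` returns the identity-based kernel K.e = Ze Ze' / I; with an
#' environmental relationship matrix returns the covariate-based kernel
#' K.ec = Ze H.e Ze'.
#'
#' @param design a [build_design_matrices] result.
#' @param H_e optional I x I environmental relationship matrix.
#' @return n x n symmetric PSD matrix.
#' @export
observation_env_kernel <- function(design, H_e = NULL) {
  Ze <- design$Ze
  if (is.null(H_e)) {
    K <- tcrossprod(Ze) / ncol(Ze)
  } else {
    H_e <- as.matrix(H_e)
    if (nrow(H_e) != ncol(Ze) || ncol(H_e) != ncol(Ze)) {
      stop_gs(sprintf("H_e must be %d x %d", ncol(Ze), ncol(Ze)),
              "enviroGS_argument_error")
    }
    K <- Ze %*% H_e %*% t(Ze)
  }
  ensure_psd(K, label = if (is.null(H_e)) "K.e" else "K.ec")
}

#' Hadamard-product genotype-by-environment interaction kernel
#'
#' Computes (env kernel) \eqn{\odot} (Zg K.g Zg'): with the identity-based
#' K.e this is K.ge, with the covariate-based K.ec it is K.gec.
#'
#' @param env_obs_kernel n x n observation-level environment kernel.
#' @param K_g J x J genomic relationship matrix.
#' @param design a [build_design_matrices] result.
#' @return n x n symmetric PSD matrix.
#' @export
interaction_kernel <- function(env_obs_kernel, K_g, design) {
  Zg <- design$Zg
  env_obs_kernel <- as.matrix(env_obs_kernel)
  if (nrow(env_obs_kernel) != nrow(Zg)) {
    stop_gs("env_obs_kernel and design have mismatched observation counts",
            "enviroGS_argument_error")
  }
  if (nrow(K_g) != ncol(Zg)) {
    stop_gs("K_g and design have mismatched genotype counts",
            "enviroGS_argument_error")
  }
  K <- env_obs_kernel * (Zg %*% K_g %*% t(Zg))
  ensure_psd(K, label = "interaction kernel")
}

#' Observation-level genotype main-effect kernel Zg K.g Zg'
#' @inheritParams interaction_kernel
#' @return n x n symmetric PSD matrix.
#' @export
genotype_obs_kernel <- function(K_g, design) {
  Zg <- design$Zg
  if (nrow(K_g) != ncol(Zg)) {
    stop_gs("K_g and design have mismatched genotype counts",
            "enviroGS_argument_error")
  }
  ensure_psd(Zg %*% K_g %*% t(Zg), label = "Zg K.g Zg'")
}
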