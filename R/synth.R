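# Synthetic multi-environment trial generator.
#
# Phenotypes are drawn from the same generative structure the prediction
# model assumes: environment main effects with covariance sE2 * H.e, genotype
# effects with covariance sg2 * K.g, genotype-by-environment effects with
# covariance sgE2 * K.gec, a fixed regression on a known subset of
# standardized environmental covariates, and i.i.d. Gaussian noise. The
# returned truth object records the informative covariates, their
# coefficients and the variance components, so selector and model recovery
# can be scored exactly.

#' Simulate a 0/1/2 marker matrix
#'
#' Each marker's minor-allele frequency is drawn uniformly from `maf_range`
#' and genotypes are binomial(2, f) draws. Markers that come out monomorphic
#' are redrawn a bounded number of times and dropped (with a warning) if
#' still monomorphic.
#'
#' @param J number of lines (>= 2).
#' @param p number of markers (>= 1).
#' @param maf_range length-2 numeric in (0, 0.5], lower and upper bound of
#'   the per-marker allele frequency.
#' @param seed integer seed.
#' @param max_redraws redraw attempts for monomorphic markers.
#' @return integer matrix J x p (or fewer columns if markers were dropped),
#'   row names `G001...`, column names `M1...`.
#' @export
simulate_markers <- function(J, p, maf_range = c(0.05, 0.5), seed = NULL,
                             max_redraws = 20L) {
  if (!is_count(J, 2) || !is_count(p, 1)) {
    stop_gs("J must be >= 2 and p >= 1", "enviroGS_argument_error")
  }
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_gs("maf_range must be an interval within (0, 0.5]",
            "enviroGS_argument_error")
  }
  with_seed(seed, {
    f <- stats::runif(p, maf_range[1], maf_range[2])
    M <- matrix(stats::rbinom(J * p, 2L, rep(f, each = J)), nrow = J, ncol = p)
    mono <- which(apply(M, 2, function(x) length(unique(x)) == 1L))
    attempts <- 0L
    while (length(mono) > 0 && attempts < max_redraws) {
      M[, mono] <- matrix(stats::rbinom(J * length(mono), 2L,
                                        rep(f[mono], each = J)),
                          nrow = J)
      mono <- mono[apply(M[, mono, drop = FALSE], 2,
                         function(x) length(unique(x)) == 1L)]
      attempts <- attempts + 1L
    }
    if (length(mono) > 0) {
      warning(sprintf("dropping %d marker(s) that stayed monomorphic",
                      length(mono)))
      M <- M[, -mono, drop = FALSE]
    }
    dimnames(M) <- list(sprintf("G%03d", seq_len(J)),
                        sprintf("M%d", seq_len(ncol(M))))
    storage.mode(M) <- "integer"
    M
  })
}

#' Simulate environment-level covariates with a designated informative subset
#'
#' Covariates are i.i.d. standard normal across environments; the returned
#' index set marks the columns that [simulate_trial] wires to the phenotype.
#'
#' @param I number of environments (>= 2).
#' @param r number of covariates (>= 1).
#' @param n_informative how many covariates carry signal (0 <= n <= r).
#' @param seed integer seed.
#' @return list with `env_covariates` (I x r matrix, row names `Env1...`)
#'   and `informative` (integer index set, possibly empty).
#' @export
simulate_env_covariates <- function(I, r, n_informative, seed = NULL) {
  if (!is_count(I, 2) || !is_count(r, 1)) {
    stop_gs("I must be >= 2 and r >= 1", "enviroGS_argument_error")
  }
  if (!is_count(n_informative, 0) || n_informative > r) {
    stop_gs("n_informative must satisfy 0 <= n_informative <= r",
            "enviroGS_argument_error")
  }
  with_seed(seed, {
    X <- matrix(stats::rnorm(I * r), nrow = I, ncol = r,
                dimnames = list(sprintf("Env%d", seq_len(I)),
                                sprintf("EC%d", seq_len(r))))
    informative <- sort(sample.int(r, n_informative))
    list(env_covariates = X, informative = informative)
  })
}

#' Simulate a complete multi-environment trial with known truth
#'
#' @param J,I,p,r lines, environments, markers, covariates.
#' @param n_informative covariates wired to the phenotype.
#' @param var_components length-4 non-negative vector
#'   `(env, genotype, gxe, residual)` variances
#'   \eqn{(\sigma_E^2, \sigma_g^2, \sigma_{gE}^2, \sigma^2)}.
#' @param beta_scale magnitude of each informative coefficient; signs are
#'   drawn at random (phenotype units per standardized covariate unit).
#' @param n_traits number of independently simulated traits.
#' @param balance fraction of genotype x environment cells retained
#'   (1 = fully balanced).
#' @param mu grand mean.
#' @param maf_range passed to [simulate_markers].
#' @param seed integer seed; fixes the whole draw.
#' @return list with `trial` ([trial_data]) and `truth` (class
#'   `synthetic_truth`: `informative_covariates`, `beta_true`,
#'   `var_components_true`, `seed`).
#' @export
simulate_trial <- function(J, I, p, r, n_informative,
                           var_components = c(env = 0.25, g = 0.75,
                                              ge = 0.25, resid = 0.75),
                           beta_scale = 2, n_traits = 1, balance = 1,
                           mu = 0, maf_range = c(0.05, 0.5), seed = NULL) {
  var_components <- as.numeric(var_components)
  if (length(var_components) != 4 || any(!is.finite(var_components)) ||
      any(var_components < 0)) {
    stop_gs("var_components must be 4 non-negative numbers",
            "enviroGS_argument_error")
  }
  if (!is.numeric(balance) || balance <= 0 || balance > 1) {
    stop_gs("balance must lie in (0, 1]", "enviroGS_argument_error")
  }
  if (!is_count(p, 1)) {
    stop_gs("p must be a positive count (a genomic kernel is required)",
            "enviroGS_degenerate_error")
  }
  with_seed(seed, {
    markers <- simulate_markers(J, p, maf_range, seed = NULL)
    covs <- simulate_env_covariates(I, r, n_informative, seed = NULL)
    Xe_raw <- covs$env_covariates
    informative <- covs$informative

    K_g <- genomic_kernel(markers)
    H_e <- env_covariate_kernel(Xe_raw)
    Xe_std <- standardize_columns(Xe_raw)

    # full I x J grid, thinned to emulate unbalance (uniform cell deletion;
    # every environment keeps at least 2 cells so folds stay scoreable)
    grid <- expand.grid(genotype_id = rownames(markers),
                        env_id = rownames(Xe_raw),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$env_id, grid$genotype_id), , drop = FALSE]
    keep <- rep(TRUE, nrow(grid))
    if (balance < 1) {
      keep <- stats::runif(nrow(grid)) <= balance
      for (e in rownames(Xe_raw)) {
        idx <- which(grid$env_id == e)
        if (sum(keep[idx]) < 2) keep[idx[seq_len(min(2, length(idx)))]] <- TRUE
      }
    }
    grid <- grid[keep, , drop = FALSE]
    n <- nrow(grid)

    ei <- match(grid$env_id, rownames(Xe_raw))
    gi <- match(grid$genotype_id, rownames(markers))
    Ze <- matrix(0, n, I); Ze[cbind(seq_len(n), ei)] <- 1
    Zg <- matrix(0, n, J); Zg[cbind(seq_len(n), gi)] <- 1
    K_ec <- Ze %*% H_e %*% t(Ze)
    K_gec <- K_ec * (Zg %*% K_g %*% t(Zg))

    sE2 <- var_components[1]; sg2 <- var_components[2]
    sgE2 <- var_components[3]; s2 <- var_components[4]

    # eigen factors reused across traits
    rt_He <- mvn_factor(H_e)
    rt_Kg <- mvn_factor(K_g)
    rt_gec <- mvn_factor(K_gec)

    beta_true <- numeric(r)
    if (length(informative) > 0) {
      beta_true[informative] <- beta_scale * sample(c(-1, 1),
                                                    length(informative),
                                                    replace = TRUE)
    }
    # regression acts on standardized covariates; columns dropped during
    # standardization (if any) contribute nothing
    kept <- attr(Xe_std, "kept")
    Xb_env <- as.numeric(Xe_std %*% beta_true[kept])

    obs_list <- vector("list", n_traits)
    for (t in seq_len(n_traits)) {
      E_i <- sqrt(sE2) * mvn_draw(rt_He)
      g_j <- sqrt(sg2) * mvn_draw(rt_Kg)
      gE <- sqrt(sgE2) * mvn_draw(rt_gec)
      eps <- stats::rnorm(n, 0, sqrt(s2))
      y <- mu + E_i[ei] + g_j[gi] + gE + Xb_env[ei] + eps
      obs_list[[t]] <- data.frame(env_id = grid$env_id,
                                  genotype_id = grid$genotype_id,
                                  trait_id = sprintf("T%d", t),
                                  value = y, stringsAsFactors = FALSE)
    }
    trial <- trial_data(do.call(rbind, obs_list), markers, Xe_raw)
    truth <- structure(
      list(informative_covariates = informative, beta_true = beta_true,
           var_components_true = c(env = sE2, g = sg2, ge = sgE2, resid = s2),
           mu = mu, seed = seed),
      class = "synthetic_truth")
    list(trial = trial, truth = truth)
  })
}

# eigen factorisation of a PSD matrix for repeated N(0, K) draws
mvn_factor <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  list(L = e$vectors %*% diag(sqrt(d), length(d)), n = nrow(K))
}

mvn_draw <- function(fac) as.numeric(fac$L %*% stats::rnorm(fac$n))

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d informative covariate(s) [%s]\n",
              length(x$informative_covariates),
              paste(x$informative_covariates, collapse = ", ")))
  cat("  variance components:",
      paste(sprintf("%s=%.3g", names(x$var_components_true),
                    x$var_components_true), collapse = ", "), "\n")
  invisible(x)
}
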