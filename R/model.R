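# Gibbs sampler for the Gaussian kernel mixed model
#
#   y = mu + sum_t u_t + X beta + e,   u_t ~ N(0, sigma_t^2 K_t),
#   e_i ~ N(0, sigma^2) on training rows.
#
# Each kernel effect is re-parameterised in the kernel's eigenbasis:
# K = V D V'  =>  u = B gamma with B = V D^{1/2} and gamma ~ N(0, sigma_t^2 I).
# Eigenvalues below a relative tolerance are truncated. Because the gamma
# prior is isotropic, the sampler works in a second rotation Q that
# diagonalises W'W (W = training rows of B), making every full-conditional
# update elementwise: the whole gamma block is drawn jointly per iteration.
# Held-out rows receive predictions through B's test rows, i.e. through the
# kernel's cross-covariance between training and held-out observations.
#
# Variance components carry scaled-inverse-chi-square priors; the regression
# block keeps a fixed, weakly informative Gaussian prior so it behaves like a
# fixed effect while remaining proper for rank-deficient covariate blocks
# (environment-level covariates expanded to observations have rank <= I).

#' MCMC configuration
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded iterations (< `n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param prior_df scaled-inverse-chi-square degrees of freedom shared by all
#'   variance components.
#' @param prior_variance_split optional named fractions of the training
#'   phenotypic variance allotted to each random term for prior-scale
#'   elicitation; defaults to an equal split of one half across kernel terms,
#'   the other half to the residual.
#' @param beta_prior_mult the regression prior variance is
#'   `beta_prior_mult * var(y_train)` per coefficient (large = near-fixed).
#' @param fixed_variances optional named numeric vector pinning selected
#'   variance components (names = kernel-term names or `"residual"`);
#'   pinned components are not updated.
#' @param seed integer seed for the chain.
#' @param keep_draws retain thinned draws of predictions/variances/beta.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000L, burn_in = 2000L, thin = 5L,
                        prior_df = 5, prior_variance_split = NULL,
                        beta_prior_mult = 25, fixed_variances = NULL,
                        seed = NULL, keep_draws = FALSE) {
  if (!is_count(n_iter, 10) || !is_count(burn_in, 0) || burn_in >= n_iter) {
    stop_gs("need burn_in < n_iter", "enviroGS_argument_error")
  }
  if (!is_count(thin, 1)) stop_gs("thin must be >= 1", "enviroGS_argument_error")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), prior_df = prior_df,
                 prior_variance_split = prior_variance_split,
                 beta_prior_mult = beta_prior_mult,
                 fixed_variances = fixed_variances, seed = seed,
                 keep_draws = keep_draws),
            class = "mcmc_config")
}

#' Pre-factorize a kernel for a given training mask
#'
#' Exposed so callers running many models on the same cross-validation fold
#' can share the eigen work. `fit_predict` accepts these objects in place of
#' raw kernel matrices.
#'
#' @param K n x n symmetric PSD kernel.
#' @param train logical length-n training mask.
#' @param tol relative eigenvalue truncation threshold.
#' @return object of class `prepared_kernel_term`.
#' @export
prepare_kernel_term <- function(K, train, tol = 1e-10) {
  K <- ensure_psd(as.matrix(K), label = "kernel term")
  e <- eigen(K, symmetric = TRUE)
  keep <- which(e$values > tol * max(e$values, 0))
  if (length(keep) == 0) {
    stop_gs("kernel term has no positive eigenvalue", "enviroGS_kernel_error")
  }
  B <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  W <- B[train, , drop = FALSE]
  ew <- eigen(crossprod(W), symmetric = TRUE)
  structure(list(BQ = B %*% ew$vectors, WQ = W %*% ew$vectors,
                 lam = pmax(ew$values, 0), m = length(keep),
                 n = nrow(K), train = train),
            class = "prepared_kernel_term")
}

# a covariate block re-expressed in the same rotated machinery;
# its prior variance is fixed, not sampled
prepare_beta_block <- function(X, train) {
  X <- as.matrix(X)
  W <- X[train, , drop = FALSE]
  ew <- eigen(crossprod(W), symmetric = TRUE)
  list(BQ = X %*% ew$vectors, WQ = W %*% ew$vectors,
       Q = ew$vectors, lam = pmax(ew$values, 0), q = ncol(X))
}

#' Fit the kernel mixed model and predict held-out observations
#'
#' @param y numeric length-n response with `NA` marking held-out
#'   observations (their values are never read).
#' @param kernel_terms named list of n x n PSD kernels (or
#'   [prepare_kernel_term] objects) — one per random term.
#' @param covariates optional n x q numeric matrix (rows aligned with `y`)
#'   entering the fixed-regression block.
#' @param config an [mcmc_config].
#' @return object of class `gs_fit` with posterior-mean `predictions` for all
#'   n observations, `pred_se` (batch-means Monte Carlo standard errors),
#'   `post_mu`, `post_beta` (mean and posterior sd per coefficient),
#'   `post_var` (posterior-mean variance components incl. `residual`),
#'   `n_kept`, and optionally retained draws.
#' @export
fit_predict <- function(y, kernel_terms = list(), covariates = NULL,
                        config = mcmc_config()) {
  y <- as.numeric(y)
  n <- length(y)
  train <- !is.na(y)
  ntr <- sum(train)
  if (ntr == 0) stop_gs("all observations are masked", "enviroGS_argument_error")
  if (ntr < 2) stop_gs("need at least 2 training observations",
                       "enviroGS_argument_error")
  if (!is.list(kernel_terms)) kernel_terms <- list(kernel_terms)
  nt <- length(kernel_terms)
  if (nt > 0 && is.null(names(kernel_terms))) {
    names(kernel_terms) <- sprintf("K%d", seq_len(nt))
  }
  terms <- lapply(kernel_terms, function(K) {
    if (inherits(K, "prepared_kernel_term")) {
      if (K$n != n || !identical(K$train, train)) {
        stop_gs("prepared kernel term does not match y / training mask",
                "enviroGS_argument_error")
      }
      K
    } else {
      if (!is.matrix(K) || nrow(K) != n || ncol(K) != n) {
        stop_gs("kernel terms must be n x n matrices", "enviroGS_argument_error")
      }
      prepare_kernel_term(K, train)
    }
  })
  has_beta <- !is.null(covariates) && NCOL(covariates) > 0
  if (has_beta) {
    X <- as.matrix(covariates)
    if (nrow(X) != n) stop_gs("covariates not row-aligned with y",
                              "enviroGS_argument_error")
    bb <- prepare_beta_block(X, train)
  }

  y_tr <- y[train]
  var_y <- stats::var(y_tr)
  if (!is.finite(var_y)) stop_gs("non-finite training responses",
                                 "enviroGS_argument_error")
  var_y <- max(var_y, 1e-12)
  df0 <- config$prior_df
  split <- config$prior_variance_split
  if (is.null(split)) {
    split <- if (nt > 0) stats::setNames(rep(0.5 / nt, nt), names(terms))
             else numeric(0)
    split <- c(split, residual = 0.5)
  }
  if (sum(split) > 1 + 1e-8) {
    stop_gs("prior_variance_split fractions must sum to <= 1",
            "enviroGS_argument_error")
  }
  frac <- function(nm, fallback) if (nm %in% names(split)) split[[nm]] else fallback
  S0 <- vapply(names(terms), function(nm)
    var_y * frac(nm, 0.5 / max(nt, 1)) * (df0 + 2) / df0, numeric(1))
  S0e <- var_y * frac("residual", 0.5) * (df0 + 2) / df0
  vbeta <- config$beta_prior_mult * var_y

  fixed <- config$fixed_variances
  is_fixed <- function(nm) !is.null(fixed) && nm %in% names(fixed)

  with_seed(config$seed, {
    # state
    mu <- mean(y_tr)
    s2 <- if (is_fixed("residual")) fixed[["residual"]] else var_y / 2
    st2 <- vapply(names(terms), function(nm)
      if (is_fixed(nm)) fixed[[nm]] else var_y / (2 * max(nt, 1)), numeric(1))
    gam <- lapply(terms, function(tm) numeric(tm$m))
    gb <- if (has_beta) numeric(bb$q) else NULL
    e_tr <- y_tr - mu

    kept_iters <- seq.int(config$burn_in + config$thin, config$n_iter,
                          by = config$thin)
    nkept <- length(kept_iters)
    P <- matrix(0, n, nkept)
    VDraws <- matrix(0, nt + 1L, nkept,
                     dimnames = list(c(names(terms), "residual"), NULL))
    BDraws <- if (has_beta) matrix(0, bb$q, nkept) else NULL
    MuDraws <- numeric(nkept)
    k <- 0L

    for (iter in seq_len(config$n_iter)) {
      # grand mean (flat prior)
      r_mu <- e_tr + mu
      mu <- stats::rnorm(1, mean(r_mu), sqrt(s2 / ntr))
      e_tr <- r_mu - mu

      # kernel-effect blocks, jointly per term in the rotated eigenbasis
      for (t in seq_len(nt)) {
        tm <- terms[[t]]
        e_tr <- e_tr + as.numeric(tm$WQ %*% gam[[t]])
        rhs <- crossprod(tm$WQ, e_tr) / s2
        prec <- tm$lam / s2 + 1 / st2[t]
        g_new <- as.numeric(rhs / prec) +
          stats::rnorm(tm$m) / sqrt(prec)
        gam[[t]] <- g_new
        e_tr <- e_tr - as.numeric(tm$WQ %*% g_new)
        if (!is_fixed(names(terms)[t])) {
          st2[t] <- (sum(g_new^2) + df0 * S0[t]) /
            stats::rchisq(1, df0 + tm$m)
        }
      }

      # regression block (fixed Gaussian prior variance)
      if (has_beta) {
        e_tr <- e_tr + as.numeric(bb$WQ %*% gb)
        rhs <- crossprod(bb$WQ, e_tr) / s2
        prec <- bb$lam / s2 + 1 / vbeta
        gb <- as.numeric(rhs / prec) + stats::rnorm(bb$q) / sqrt(prec)
        e_tr <- e_tr - as.numeric(bb$WQ %*% gb)
      }

      # residual variance
      if (!is_fixed("residual")) {
        s2 <- (sum(e_tr^2) + df0 * S0e) / stats::rchisq(1, df0 + ntr)
      }

      if (iter > config$burn_in &&
          (iter - config$burn_in) %% config$thin == 0L) {
        k <- k + 1L
        pred <- rep(mu, n)
        for (t in seq_len(nt)) pred <- pred + as.numeric(terms[[t]]$BQ %*% gam[[t]])
        if (has_beta) pred <- pred + as.numeric(bb$BQ %*% gb)
        P[, k] <- pred
        VDraws[, k] <- c(st2, s2)
        if (has_beta) BDraws[, k] <- as.numeric(bb$Q %*% gb)
        MuDraws[k] <- mu
      }
    }

    predictions <- rowMeans(P)
    # batch-means MC standard error (robust to autocorrelation)
    nb <- max(2L, min(20L, nkept %/% 5L))
    bsize <- nkept %/% nb
    bm <- vapply(seq_len(nb), function(b)
      rowMeans(P[, ((b - 1) * bsize + 1):(b * bsize), drop = FALSE]),
      numeric(n))
    pred_se <- apply(bm, 1, stats::sd) / sqrt(nb)

    post_beta <- NULL
    if (has_beta) {
      post_beta <- data.frame(coef = seq_len(bb$q),
                              mean = rowMeans(BDraws),
                              sd = apply(BDraws, 1, stats::sd))
      if (!is.null(colnames(covariates))) post_beta$name <- colnames(covariates)
    }
    out <- list(predictions = predictions,
                pred_se = pred_se,
                post_mu = mean(MuDraws),
                post_beta = post_beta,
                post_var = rowMeans(VDraws),
                n_kept = nkept,
                train = train,
                seed = config$seed)
    if (config$keep_draws) {
      out$draws <- list(predictions = P, variances = VDraws,
                        beta = BDraws, mu = MuDraws)
    }
    structure(out, class = "gs_fit")
  })
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit: %d observations (%d training, %d held out), %d kept draws\n",
              length(x$predictions), sum(x$train), sum(!x$train), x$n_kept))
  cat("  posterior-mean variance components:\n")
  print(round(x$post_var, 4))
  invisible(x)
}
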