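# Predictor registry (M0-M14), leave-one-environment-out evaluation and the
# reported statistics: NRMSE, Pearson correlation, calibration intercept and
# slope deviation, relative efficiencies vs the covariate-free baseline, and
# pairwise win counts.

#' Normalized root mean squared prediction error
#'
#' RMSE divided by the absolute mean of the observed values (the default), or
#' by their standard deviation (`normalization = "sd"`). Mean normalization
#' is the package's declared convention; whole-environment extrapolation can
#' legitimately push values above 1.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param normalization `"mean"` or `"sd"`.
#' @return non-negative scalar.
#' @export
nrmse <- function(observed, predicted, normalization = c("mean", "sd")) {
  normalization <- match.arg(normalization)
  if (length(observed) != length(predicted) || length(observed) < 1) {
    stop_gs("observed and predicted must be equal-length, non-empty",
            "enviroGS_argument_error")
  }
  rmse <- sqrt(mean((observed - predicted)^2))
  denom <- if (normalization == "mean") abs(mean(observed))
           else stats::sd(observed)
  if (!is.finite(denom) || denom == 0) {
    stop_gs(sprintf(
      "NRMSE undefined: %s of observed values is zero (normalization = '%s')",
      if (normalization == "mean") "mean" else "sd", normalization),
      "enviroGS_degenerate_error")
  }
  rmse / denom
}

#' Correlation and observed-on-predicted calibration regression
#'
#' Ordinary least squares of observed on predicted yields intercept `a` and
#' slope `s`; the reported calibration statistics are `b0 = |a|` and
#' `b = |1 - s|` (both zero for perfect calibration).
#'
#' @param observed,predicted equal-length numeric vectors (length >= 3).
#' @return list with `cor`, `b0`, `b` (all `NA` when `predicted` is constant).
#' @export
cor_and_regression <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop_gs("need >= 3 aligned observed/predicted pairs",
            "enviroGS_argument_error")
  }
  if (stats::sd(predicted) == 0) {
    return(list(cor = NA_real_, b0 = NA_real_, b = NA_real_))
  }
  co <- stats::cor(observed, predicted)
  fit <- stats::lm.fit(cbind(1, predicted), observed)
  list(cor = co, b0 = abs(fit$coefficients[[1]]),
       b = abs(1 - fit$coefficients[[2]]))
}

#' Relative efficiency versus the covariate-free baseline (percent)
#'
#' For error-like metrics (NRMSE, b0, b — smaller is better):
#' `(baseline / model - 1) * 100`. For correlation-like metrics (larger is
#' better): `(model / baseline - 1) * 100`. Positive = the model improves on
#' the baseline.
#'
#' @param metric_baseline baseline (M0) metric value.
#' @param metric_model the compared model's metric value.
#' @param kind `"nrmse_like"` or `"cor_like"`.
#' @return percent relative efficiency.
#' @export
relative_efficiency <- function(metric_baseline, metric_model,
                                kind = c("nrmse_like", "cor_like")) {
  kind <- match.arg(kind)
  denom <- if (kind == "nrmse_like") metric_model else metric_baseline
  if (!is.finite(denom) || denom == 0) {
    stop_gs("relative efficiency undefined: zero denominator",
            "enviroGS_degenerate_error")
  }
  if (kind == "nrmse_like") (metric_baseline / metric_model - 1) * 100
  else (metric_model / metric_baseline - 1) * 100
}

#' The fifteen predictor configurations
#'
#' One row per model M0-M14: which observation-level kernels enter the fit
#' (identity-based K.e/K.ge or covariate-based K.ec/K.gec), which engineered
#' covariate block is added (none, Xe, Xe2, Xe.avg, or the joint
#' marker+covariate block X.g.ec), which selector supplies the covariates,
#' whether Boruta's Tentative features count as selected, and whether markers
#' are themselves Boruta-selected before building K.g.
#'
#' @return data.frame registry.
#' @export
model_registry <- function() {
  reg <- data.frame(
    model_id = paste0("M", 0:14),
    env_kernel = c("K.e", "K.e", "K.ec", "K.e", "K.ec", "K.e", "K.e",
                   "K.ec", "K.ec", "K.e", "K.e", "K.ec", "K.ec", "K.ec",
                   "K.ec"),
    genotype_term = c(rep(TRUE, 9), FALSE, rep(TRUE, 5))[c(1:9, 10, 11:15)],
    interaction = c("K.ge", "K.ge", "K.gec", "K.ge", "K.gec", "K.ge",
                    "K.ge", "K.gec", "K.gec", "K.ge", "K.ge", "K.gec",
                    "K.ge", "K.gec", "K.gec"),
    covariate_block = c("none", "Xe", "none", "Xe", "Xe", "Xe2", "Xe_avg",
                        "Xe_avg", "Xe_avg", "X_g_ec", "Xe", "Xe_avg",
                        "Xe_avg", "Xe_avg", "Xe_avg"),
    selection = c("none", "none", "correlation", "correlation",
                  "correlation", "correlation", "correlation",
                  "correlation", "corr_and_boruta", "boruta_joint",
                  "boruta", "boruta", "boruta", "boruta", "boruta"),
    include_tentative = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                          FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                          FALSE),
    marker_selection = c(rep(FALSE, 10), FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  reg$genotype_term <- reg$model_id != "M9"
  reg$marker_selection <- reg$model_id == "M10"
  reg
}

#' Benchmark configuration
#'
#' @param mcmc an [mcmc_config] used for every fit.
#' @param ladder threshold-correlation ladder for the Pearson selector.
#' @param boruta list of Boruta settings: `alpha`, `max_runs`, `rf_params`.
#' @param nrmse_normalization passed to [nrmse].
#' @param seed master seed; per-fold and per-model streams are derived from
#'   it, so adding a model does not perturb the others.
#' @return list of class `bench_config`.
#' @export
bench_config <- function(mcmc = mcmc_config(), ladder = c(0.7, 0.6, 0.5, 0.4, 0.3),
                         boruta = list(alpha = 0.01, max_runs = 100L,
                                       rf_params = list(num.trees = 500)),
                         nrmse_normalization = "mean", seed = NULL) {
  structure(list(mcmc = mcmc, ladder = ladder, boruta = boruta,
                 nrmse_normalization = nrmse_normalization, seed = seed),
            class = "bench_config")
}

# Per-(trial, trait) precomputations shared across folds and models.
make_trait_context <- function(trial, trait) {
  design <- build_design_matrices(trial, trait)
  Me <- standardize_columns(trial$markers)
  Xe_std <- standardize_columns(trial$env_covariates)
  K_g <- genomic_kernel(trial$markers)
  list(trial = trial, trait = trait, design = design,
       y = design$obs$value, Me = Me, Xe_std = Xe_std,
       X_obs = expand_to_observations(Xe_std, design),
       K_g = K_g,
       K_e = observation_env_kernel(design),
       Kg_obs = genotype_obs_kernel(K_g, design))
}

# Run (or fetch) the selector a model needs, training rows only.
fold_selection <- function(method, ctx, train, cfg, seed, cache) {
  key <- method
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  y_tr <- ctx$y[train]
  out <- switch(
    method,
    correlation = correlation_ladder_select(
      ctx$X_obs[train, , drop = FALSE], y_tr, cfg$ladder),
    boruta = boruta_select(
      ctx$X_obs[train, , drop = FALSE], y_tr, alpha = cfg$boruta$alpha,
      max_runs = cfg$boruta$max_runs, rf_params = cfg$boruta$rf_params,
      seed = derive_seed(seed, "boruta")),
    boruta_joint = {
      Mg_obs <- ctx$design$Zg %*% ctx$Me
      joint <- cbind(Mg_obs, ctx$X_obs)
      colnames(joint) <- c(colnames(ctx$Me), colnames(ctx$Xe_std))
      boruta_select(joint[train, , drop = FALSE], y_tr,
                    alpha = cfg$boruta$alpha, max_runs = cfg$boruta$max_runs,
                    rf_params = cfg$boruta$rf_params,
                    seed = derive_seed(seed, "boruta_joint"),
                    joint_space = TRUE)
    },
    boruta_markers = {
      Mg_obs <- ctx$design$Zg %*% ctx$Me
      boruta_select(Mg_obs[train, , drop = FALSE], y_tr,
                    alpha = cfg$boruta$alpha, max_runs = cfg$boruta$max_runs,
                    rf_params = cfg$boruta$rf_params,
                    seed = derive_seed(seed, "boruta_markers"))
    },
    stop_gs(sprintf("unknown selector '%s'", method), "enviroGS_argument_error"))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

boruta_selected <- function(outcome, include_tentative) {
  st <- outcome$per_feature$status
  which(st == "Confirmed" | (include_tentative & st == "Tentative"))
}

#' Assemble the inputs of one predictor for one cross-validation fold
#'
#' Runs the model's covariate selector on training rows only, builds the
#' kernels and engineered covariate block the registry prescribes, and
#' returns everything [fit_predict] needs. When a model requires
#' covariate-based kernels but the selection comes back empty, the
#' identity-based kernels are used instead and the result is flagged
#' (`fallback = TRUE`).
#'
#' @param model_id one of `"M0"`..`"M14"`.
#' @param trial a [trial_data].
#' @param trait trait id.
#' @param train_mask logical over the trait's observations; `FALSE` marks
#'   the held-out environment.
#' @param seed integer seed for the stochastic selector.
#' @param config a [bench_config].
#' @param context internal precomputation (made if missing).
#' @param selection_cache optional environment for sharing selector runs
#'   across models within a fold.
#' @return list with `kernels` (named list), `covariates`, `selection`,
#'   `fallback`, `model_id`.
#' @export
build_predictor <- function(model_id, trial, trait, train_mask, seed = NULL,
                            config = bench_config(), context = NULL,
                            selection_cache = NULL) {
  reg <- model_registry()
  if (!model_id %in% reg$model_id) {
    stop_gs(sprintf("unknown model_id '%s'", model_id),
            "enviroGS_argument_error")
  }
  spec <- reg[reg$model_id == model_id, ]
  ctx <- if (is.null(context)) make_trait_context(trial, trait) else context
  if (length(train_mask) != length(ctx$y)) {
    stop_gs("train_mask must align with the trait's observations",
            "enviroGS_argument_error")
  }
  design <- ctx$design
  y_tr <- ctx$y[train_mask]

  selection <- NULL
  sel_std_idx <- integer(0)     # indices into standardized covariate columns
  if (spec$selection == "correlation") {
    selection <- fold_selection("correlation", ctx, train_mask, config, seed,
                                selection_cache)
    sel_std_idx <- selection$selected
  } else if (spec$selection == "boruta") {
    selection <- fold_selection("boruta", ctx, train_mask, config, seed,
                                selection_cache)
    sel_std_idx <- boruta_selected(selection, spec$include_tentative)
  } else if (spec$selection == "corr_and_boruta") {
    sc <- fold_selection("correlation", ctx, train_mask, config, seed,
                         selection_cache)
    sb <- fold_selection("boruta", ctx, train_mask, config, seed,
                         selection_cache)
    sel_std_idx <- intersect(sc$selected,
                             boruta_selected(sb, spec$include_tentative))
    selection <- list(correlation = sc, boruta = sb)
  } else if (spec$selection == "boruta_joint") {
    selection <- fold_selection("boruta_joint", ctx, train_mask, config, seed,
                                selection_cache)
  } else if (spec$model_id == "M1") {
    sel_std_idx <- seq_len(ncol(ctx$Xe_std))   # all covariates, no selection
  }

  # genomic kernel, optionally from Boruta-selected markers (M10)
  K_g <- ctx$K_g; Kg_obs <- ctx$Kg_obs
  marker_sel <- NULL
  if (spec$marker_selection) {
    marker_sel <- fold_selection("boruta_markers", ctx, train_mask, config,
                                 seed, selection_cache)
    midx <- boruta_selected(marker_sel, spec$include_tentative)
    if (length(midx) > 0) {
      src <- attr(ctx$Me, "kept")[midx]
      K_g <- genomic_kernel(ctx$trial$markers[, src, drop = FALSE])
      Kg_obs <- genotype_obs_kernel(K_g, design)
    }
  }

  # environment and interaction kernels
  fallback <- FALSE
  needs_cov_kernel <- spec$env_kernel == "K.ec" || spec$interaction == "K.gec"
  kernels <- list()
  kernel_sel_key <- ""
  if (needs_cov_kernel && length(sel_std_idx) == 0) {
    fallback <- TRUE
  }
  use_cov_kernel <- needs_cov_kernel && !fallback
  if (use_cov_kernel) {
    src <- attr(ctx$Xe_std, "kept")[sel_std_idx]
    H_e <- env_covariate_kernel(ctx$trial$env_covariates[, src, drop = FALSE])
    K_ec <- observation_env_kernel(design, H_e)
    kernel_sel_key <- paste(sort(sel_std_idx), collapse = ",")
  }

  marker_key <- if (spec$marker_selection && !is.null(marker_sel)) {
    paste0("|markers:", paste(boruta_selected(marker_sel,
                                              spec$include_tentative),
                              collapse = ","))
  } else ""
  if (spec$env_kernel == "K.ec" && use_cov_kernel) {
    env_name <- "K.ec"
    env_K <- structure(K_ec, cache_key = paste0("K.ec|", kernel_sel_key))
  } else {
    env_name <- "K.e"
    env_K <- structure(ctx$K_e, cache_key = "K.e")
  }
  if (spec$interaction == "K.gec" && use_cov_kernel) {
    int_name <- "K.gec"
    int_K <- structure(interaction_kernel(K_ec, K_g, design),
                       cache_key = paste0("K.gec|", kernel_sel_key, marker_key))
  } else {
    int_name <- "K.ge"
    int_K <- structure(interaction_kernel(ctx$K_e, K_g, design),
                       cache_key = paste0("K.ge", marker_key))
  }
  kernels[[env_name]] <- env_K
  if (spec$genotype_term) {
    kernels[["K.g"]] <- structure(Kg_obs,
                                  cache_key = paste0("K.g", marker_key))
  }
  kernels[[int_name]] <- int_K

  # engineered covariate block
  covariates <- NULL
  if (spec$covariate_block == "Xe" && length(sel_std_idx) > 0) {
    covariates <- ctx$X_obs[, sel_std_idx, drop = FALSE]
  } else if (spec$covariate_block == "Xe2" && length(sel_std_idx) > 0) {
    src <- attr(ctx$Xe_std, "kept")[sel_std_idx]
    Xe2 <- suppressWarnings(
      quadratic_augment(ctx$trial$env_covariates[, src, drop = FALSE]))
    covariates <- expand_to_observations(Xe2, design)
  } else if (spec$covariate_block == "Xe_avg" && length(sel_std_idx) > 0) {
    design_train <- list(Ze = design$Ze[train_mask, , drop = FALSE])
    avg <- signed_average(ctx$Xe_std[, sel_std_idx, drop = FALSE], y_tr,
                          design_train)
    covariates <- expand_to_observations(matrix(avg$xe_avg, ncol = 1), design)
    colnames(covariates) <- "Xe.avg"
    attr(covariates, "sign_flips") <- avg$sign_flips
  } else if (spec$covariate_block == "X_g_ec") {
    jidx <- boruta_selected(selection, spec$include_tentative)
    if (length(jidx) > 0) {
      Mg_obs <- ctx$design$Zg %*% ctx$Me
      joint <- cbind(Mg_obs, ctx$X_obs)
      covariates <- joint[, jidx, drop = FALSE]
    }
  }

  list(model_id = model_id, kernels = kernels, covariates = covariates,
       selection = selection, marker_selection = marker_sel,
       fallback = fallback)
}

#' Leave-one-environment-out evaluation
#'
#' For every environment of every requested trait: mask that environment's
#' responses, run each model's selector on the remaining (training) rows
#' only, fit the kernel mixed model, and score the held-out environment.
#' Kernel eigen-factorizations are shared across models within a fold.
#'
#' @param trial a [trial_data].
#' @param traits trait ids (default: all).
#' @param models model ids (default M0-M14).
#' @param config a [bench_config].
#' @param verbose print fold progress.
#' @return data.frame of metric cells (`trait`, `env`, `model_id`, `n_test`,
#'   `nrmse`, `cor`, `b0`, `b`, `threshold_used`, `n_selected`, `fallback`),
#'   with the per-fold selection outcomes attached as attribute
#'   `"selections"`.
#' @export
loeo_run <- function(trial, traits = NULL, models = paste0("M", 0:14),
                     config = bench_config(), verbose = FALSE) {
  if (is.null(traits)) traits <- trial_traits(trial)
  reg <- model_registry()
  bad <- setdiff(models, reg$model_id)
  if (length(bad) > 0) {
    stop_gs(paste("unknown models:", paste(bad, collapse = ", ")),
            "enviroGS_argument_error")
  }
  rows <- list()
  sel_log <- list()
  for (trait in traits) {
    ctx <- make_trait_context(trial, trait)
    envs <- unique(ctx$design$obs$env_id)
    if (length(envs) < 2) {
      stop_gs(sprintf("trait '%s' needs >= 2 environments for LOEO", trait),
              "enviroGS_argument_error")
    }
    for (env in envs) {
      train <- ctx$design$obs$env_id != env
      fold_seed <- derive_seed(config$seed, trait, env)
      sel_cache <- new.env(parent = emptyenv())
      prep_cache <- new.env(parent = emptyenv())
      y_masked <- ctx$y
      y_masked[!train] <- NA_real_
      for (m in models) {
        if (verbose) message(sprintf("[loeo] %s | %s | %s", trait, env, m))
        bp <- build_predictor(m, trial, trait, train, seed = fold_seed,
                              config = config, context = ctx,
                              selection_cache = sel_cache)
        kt <- lapply(bp$kernels, function(K) {
          key <- attr(K, "cache_key")
          if (!is.null(key) && !is.null(prep_cache[[key]])) return(prep_cache[[key]])
          pt <- prepare_kernel_term(K, train)
          if (!is.null(key)) prep_cache[[key]] <- pt
          pt
        })
        mc <- config$mcmc
        mc$seed <- derive_seed(fold_seed, m, "fit")
        fit <- fit_predict(y_masked, kt, bp$covariates, mc)
        obs_t <- ctx$y[!train]
        pred_t <- fit$predictions[!train]
        cell_nrmse <- nrmse(obs_t, pred_t, config$nrmse_normalization)
        cr <- if (length(obs_t) >= 3) cor_and_regression(obs_t, pred_t)
              else list(cor = NA_real_, b0 = NA_real_, b = NA_real_)
        thr <- if (!is.null(bp$selection) &&
                   inherits(bp$selection, "selection_outcome"))
          bp$selection$threshold_used else NA_real_
        nsel <- if (!is.null(bp$covariates)) ncol(bp$covariates) else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, env = env, model_id = m, n_test = length(obs_t),
          nrmse = cell_nrmse, cor = cr$cor, b0 = cr$b0, b = cr$b,
          threshold_used = thr, n_selected = nsel, fallback = bp$fallback,
          stringsAsFactors = FALSE)
        sel_log[[paste(trait, env, m, sep = "|")]] <-
          list(selection = bp$selection, fallback = bp$fallback)
      }
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  attr(cells, "selections") <- sel_log
  cells
}

#' Pairwise win counts from LOEO metric cells
#'
#' Environment-level counts: within each (trait, environment) cell a model
#' scores a win over another when its NRMSE is strictly lower (ties score
#' for neither). Trait-level counts compare per-trait mean NRMSE. Totals are
#' opponents x cells from the supplied grid.
#'
#' @param cells the data.frame produced by [loeo_run] (must cover every
#'   model on an identical trait x environment grid).
#' @return list with `env_level` and `trait_level` data.frames
#'   (`model_id`, `won`, `total`, `pct`).
#' @export
win_table <- function(cells) {
  models <- unique(cells$model_id)
  grid <- unique(cells[, c("trait", "env")])
  counts <- table(cells$model_id, paste(cells$trait, cells$env))
  if (any(counts != 1)) {
    gaps <- which(counts != 1, arr.ind = TRUE)
    stop_gs(paste("incomplete metric grid, e.g.:",
                  paste(rownames(counts)[gaps[, 1]][1], "x",
                        colnames(counts)[gaps[, 2]][1])),
            "enviroGS_argument_error")
  }
  M <- length(models)
  won_env <- stats::setNames(numeric(M), models)
  for (i in seq_len(nrow(grid))) {
    sub <- cells[cells$trait == grid$trait[i] & cells$env == grid$env[i], ]
    x <- stats::setNames(sub$nrmse, sub$model_id)[models]
    for (m in models) won_env[m] <- won_env[m] + sum(x[m] < x[names(x) != m])
  }
  tot_env <- (M - 1) * nrow(grid)
  agg <- stats::aggregate(nrmse ~ model_id + trait, data = cells, FUN = mean)
  traits <- unique(agg$trait)
  won_tr <- stats::setNames(numeric(M), models)
  for (tr in traits) {
    sub <- agg[agg$trait == tr, ]
    x <- stats::setNames(sub$nrmse, sub$model_id)[models]
    for (m in models) won_tr[m] <- won_tr[m] + sum(x[m] < x[names(x) != m])
  }
  tot_tr <- (M - 1) * length(traits)
  list(
    env_level = data.frame(model_id = models, won = as.numeric(won_env),
                           total = tot_env,
                           pct = as.numeric(won_env) / tot_env * 100,
                           stringsAsFactors = FALSE),
    trait_level = data.frame(model_id = models, won = as.numeric(won_tr),
                             total = tot_tr,
                             pct = as.numeric(won_tr) / tot_tr * 100,
                             stringsAsFactors = FALSE))
}

#' Dataset-level summary with relative efficiencies
#'
#' Aggregates metric cells to one row per model (unweighted mean over
#' trait x environment cells) and appends relative-efficiency columns versus
#' the baseline model: error-like RE for NRMSE, b0 and b, correlation-like
#' RE for Cor.
#'
#' @param cells [loeo_run] output.
#' @param baseline baseline model id (default `"M0"`).
#' @return list of class `comparison_report` with `summary`, `win_env`,
#'   `win_trait`.
#' @export
comparison_report <- function(cells, baseline = "M0") {
  if (!baseline %in% cells$model_id) {
    stop_gs(sprintf("baseline '%s' absent from cells", baseline),
            "enviroGS_argument_error")
  }
  models <- unique(cells$model_id)
  agg <- do.call(rbind, lapply(models, function(m) {
    sub <- cells[cells$model_id == m, ]
    data.frame(model_id = m,
               nrmse = mean(sub$nrmse),
               cor = mean(sub$cor, na.rm = TRUE),
               b0 = mean(sub$b0, na.rm = TRUE),
               b = mean(sub$b, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  base <- agg[agg$model_id == baseline, ]
  agg$re_nrmse <- vapply(seq_len(nrow(agg)), function(i)
    relative_efficiency(base$nrmse, agg$nrmse[i], "nrmse_like"), numeric(1))
  agg$re_cor <- vapply(seq_len(nrow(agg)), function(i)
    relative_efficiency(base$cor, agg$cor[i], "cor_like"), numeric(1))
  agg$re_b0 <- vapply(seq_len(nrow(agg)), function(i)
    relative_efficiency(base$b0, agg$b0[i], "nrmse_like"), numeric(1))
  agg$re_b <- vapply(seq_len(nrow(agg)), function(i)
    relative_efficiency(base$b, agg$b[i], "nrmse_like"), numeric(1))
  wt <- win_table(cells)
  structure(list(summary = agg, win_env = wt$env_level,
                 win_trait = wt$trait_level, baseline = baseline),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report (baseline %s)\n", x$baseline))
  print(cbind(x$summary[, c("model_id", "nrmse", "cor")],
              re_nrmse = round(x$summary$re_nrmse, 2),
              win_pct_env = round(x$win_env$pct[match(x$summary$model_id,
                                                      x$win_env$model_id)], 2)),
        row.names = FALSE)
  invisible(x)
}
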