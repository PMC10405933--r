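# Leakage-safe covariate selection: a descending Pearson threshold-correlation
# ladder and a Boruta-style shadow-feature random forest selector. Both
# consume training-fold responses only; the calling code never hands them
# test-fold values.

new_selection_outcome <- function(method, selected, per_feature,
                                  threshold_used = NA_real_,
                                  joint_space = FALSE) {
  structure(list(method = method, selected = selected,
                 per_feature = per_feature, threshold_used = threshold_used,
                 joint_space = joint_space),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("selection_outcome [%s]: %d of %d feature(s) selected",
              x$method, length(x$selected), nrow(x$per_feature)))
  if (!is.na(x$threshold_used)) cat(sprintf(" (TC = %.1f)", x$threshold_used))
  cat("\n")
  invisible(x)
}

#' Threshold-correlation ladder selection
#'
#' Computes the Pearson correlation of every feature column with the training
#' response, then walks a descending ladder of threshold correlations (TC):
#' the first TC met by at least one |correlation| defines the selected set.
#' If no feature reaches the lowest rung, the selection is empty and
#' downstream models run without environmental covariates.
#'
#' @param features numeric matrix, training observations x features.
#' @param y_train training responses, row-aligned with `features`.
#' @param ladder descending TC values (default 0.7, 0.6, 0.5, 0.4, 0.3).
#' @return a `selection_outcome` with `method = "correlation"`,
#'   `threshold_used` (NA when nothing was selected) and per-feature
#'   correlations.
#' @export
correlation_ladder_select <- function(features, y_train,
                                      ladder = c(0.7, 0.6, 0.5, 0.4, 0.3)) {
  features <- as.matrix(features)
  if (nrow(features) != length(y_train)) {
    stop_gs("features and y_train are not row-aligned", "enviroGS_argument_error")
  }
  if (stats::sd(y_train) == 0 || !is.finite(stats::sd(y_train))) {
    stop_gs("y_train has zero variance; correlations undefined",
            "enviroGS_degenerate_error")
  }
  if (is.unsorted(rev(ladder))) ladder <- sort(ladder, decreasing = TRUE)
  sds <- apply(features, 2, stats::sd)
  cors <- rep(0, ncol(features))
  ok <- which(sds > 0)
  if (length(ok) > 0) {
    cors[ok] <- as.numeric(stats::cor(features[, ok, drop = FALSE], y_train))
  }
  per_feature <- data.frame(feature = seq_len(ncol(features)),
                            correlation = cors)
  if (!is.null(colnames(features))) per_feature$name <- colnames(features)
  for (tc in ladder) {
    hit <- which(abs(cors) >= tc)
    if (length(hit) > 0) {
      return(new_selection_outcome("correlation", hit, per_feature,
                                   threshold_used = tc))
    }
  }
  new_selection_outcome("correlation", integer(0), per_feature)
}

#' Boruta binomial decision for one feature
#'
#' Given the number of runs in which a feature's importance exceeded the
#' maximum shadow importance (`hits`), classifies the feature by the exact
#' binomial test against chance p = 1/2: `Confirmed` when the upper tail
#' P(X >= hits) falls below `alpha`, `Rejected` when the lower tail
#' P(X <= hits) does, `Tentative` otherwise.
#'
#' @param hits number of importance wins over the shadow maximum.
#' @param runs number of completed Boruta runs (>= 1).
#' @param alpha significance level in (0, 1).
#' @return one of `"Confirmed"`, `"Tentative"`, `"Rejected"`.
#' @export
boruta_hit_test <- function(hits, runs, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_gs("alpha must lie in (0, 1)", "enviroGS_argument_error")
  }
  if (!is_count(runs, 1) || !is_count(hits, 0) || hits > runs) {
    stop_gs("need 0 <= hits <= runs with runs >= 1", "enviroGS_argument_error")
  }
  upper <- stats::pbinom(hits - 1, runs, 0.5, lower.tail = FALSE)
  lower <- stats::pbinom(hits, runs, 0.5)
  if (upper < alpha) "Confirmed" else if (lower < alpha) "Rejected" else "Tentative"
}

#' Boruta-style all-relevant feature selection
#'
#' Iteratively contrasts every still-undecided feature with permuted "shadow"
#' copies: per run a random forest is fitted on the real plus shadow columns,
#' a feature scores a hit when its permutation importance strictly exceeds
#' the maximum shadow importance, and after every run the exact binomial test
#' ([boruta_hit_test]) promotes features to `Confirmed` or `Rejected`.
#' Features still undecided after `max_runs` remain `Tentative`.
#'
#' @param features numeric matrix, training observations x features.
#' @param y_train training responses, row-aligned with `features`.
#' @param alpha binomial-test significance level.
#' @param max_runs maximum shadow-contrast runs (>= 10).
#' @param include_tentative if `TRUE`, Tentative features are selected along
#'   with Confirmed ones.
#' @param rf_params list of [ranger::ranger] arguments (e.g. `num.trees`).
#' @param seed integer seed for permutation and forest randomness.
#' @param joint_space flag recorded on the outcome when the feature space
#'   mixes markers and covariates.
#' @return a `selection_outcome` with `method = "boruta"` and per-feature
#'   status, hit counts and run counts.
#' @export
boruta_select <- function(features, y_train, alpha = 0.01, max_runs = 100L,
                          include_tentative = FALSE,
                          rf_params = list(num.trees = 500), seed = NULL,
                          joint_space = FALSE) {
  features <- as.matrix(features)
  q <- ncol(features)
  if (nrow(features) != length(y_train)) {
    stop_gs("features and y_train are not row-aligned", "enviroGS_argument_error")
  }
  if (nrow(features) < 10) {
    stop_gs("fewer than 10 training rows; the forest is unreliable",
            "enviroGS_argument_error")
  }
  if (stats::sd(y_train) == 0 || !is.finite(stats::sd(y_train))) {
    stop_gs("y_train has zero variance", "enviroGS_degenerate_error")
  }
  if (!is_count(max_runs, 10)) {
    stop_gs("max_runs must be >= 10", "enviroGS_argument_error")
  }
  with_seed(seed, {
    status <- rep("Undecided", q)
    hits <- integer(q)
    runs <- integer(q)
    colnames(features) <- sprintf("f%d", seq_len(q))
    run <- 0L
    while (any(status == "Undecided") && run < max_runs) {
      run <- run + 1L
      active <- which(status == "Undecided")
      real <- features[, active, drop = FALSE]
      shadow <- apply(real, 2, sample)
      colnames(shadow) <- sprintf("shadow%d", seq_along(active))
      dat <- cbind(real, shadow)
      args <- c(list(x = dat, y = y_train, importance = "permutation",
                     num.threads = 1,
                     seed = sample.int(.Machine$integer.max, 1)),
                rf_params)
      fit <- do.call(ranger::ranger, args)
      imp <- fit$variable.importance
      shadow_max <- max(imp[colnames(shadow)])
      win <- imp[colnames(real)] > shadow_max
      hits[active] <- hits[active] + as.integer(win)
      runs[active] <- runs[active] + 1L
      for (j in active) {
        verdict <- boruta_hit_test(hits[j], runs[j], alpha)
        if (verdict != "Tentative") status[j] <- verdict
      }
    }
    status[status == "Undecided"] <- "Tentative"
    selected <- which(status == "Confirmed" |
                        (include_tentative & status == "Tentative"))
    per_feature <- data.frame(feature = seq_len(q), status = status,
                              hits = hits, runs = runs)
    new_selection_outcome("boruta", selected, per_feature,
                          joint_space = joint_space)
  })
}
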