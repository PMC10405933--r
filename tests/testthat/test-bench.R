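test_that("NRMSE follows its definition and scale invariance", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3) / 2, tolerance = 1e-12)
  o <- rnorm(30, mean = 4); p <- o + rnorm(30)
  expect_equal(nrmse(o, p), nrmse(7 * o, 7 * p), tolerance = 1e-12)
  expect_equal(nrmse(o, p, "sd"), sqrt(mean((o - p)^2)) / sd(o),
               tolerance = 1e-12)
  expect_error(nrmse(c(-1, 1), c(0, 0)), class = "enviroGS_degenerate_error")
  expect_error(nrmse(1:3, 1:2), class = "enviroGS_argument_error")
})

test_that("calibration regression returns correlation, |intercept| and |1 - slope|", {
  r <- cor_and_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(r), c(cor = 1, b0 = 0, b = 0), tolerance = 1e-12)
  r2 <- cor_and_regression(c(2, 3, 4), c(1, 2, 3))       # obs = pred + 1
  expect_equal(unlist(r2), c(cor = 1, b0 = 1, b = 0), tolerance = 1e-12)
  r3 <- cor_and_regression(c(1, 2, 3), c(0.5, 1.0, 1.5)) # slope 2
  expect_equal(unlist(r3), c(cor = 1, b0 = 0, b = 1), tolerance = 1e-12)
  rc <- cor_and_regression(c(1, 2, 3), c(2, 2, 2))
  expect_true(all(is.na(unlist(rc))))
  expect_error(cor_and_regression(1:2, 1:2), class = "enviroGS_argument_error")
})

test_that("relative efficiency implements both metric directions", {
  expect_equal(relative_efficiency(1.0, 0.8, "nrmse_like"), 25)
  expect_equal(relative_efficiency(0.4, 0.5, "cor_like"), 25)
  expect_equal(relative_efficiency(1.37, 1.37, "nrmse_like"), 0)
  expect_equal(relative_efficiency(0.52, 0.52, "cor_like"), 0)
  # antitone in the model's error
  res <- vapply(seq(0.5, 2, by = 0.25),
                function(m) relative_efficiency(1, m, "nrmse_like"), 1)
  expect_true(all(diff(res) < 0))
  expect_error(relative_efficiency(1, 0, "nrmse_like"),
               class = "enviroGS_degenerate_error")
})

test_that("the predictor registry encodes the fifteen configurations", {
  reg <- model_registry()
  expect_equal(nrow(reg), 15)
  m0 <- reg[reg$model_id == "M0", ]
  expect_equal(m0$covariate_block, "none")
  expect_equal(m0$selection, "none")
  expect_equal(m0$env_kernel, "K.e")
  expect_false(any(reg$marker_selection[reg$model_id != "M10"]))
  expect_false(reg$genotype_term[reg$model_id == "M9"])
  expect_equal(reg$covariate_block[reg$model_id == "M9"], "X_g_ec")
  expect_equal(reg$covariate_block[reg$model_id == "M5"], "Xe2")
  expect_equal(reg$selection[reg$model_id == "M8"], "corr_and_boruta")
  expect_true(all(reg$include_tentative[reg$model_id %in% c("M10", "M12", "M13")]))
  expect_false(any(reg$include_tentative[reg$model_id %in% c("M11", "M14")]))
  # every Xe.avg model carries exactly one engineered covariate
  expect_true(all(reg$covariate_block[reg$model_id %in%
    c("M6", "M7", "M8", "M11", "M12", "M13", "M14")] == "Xe_avg"))
})

test_that("build_predictor assembles kernels and covariates per the registry", {
  sim <- make_toy_trial(J = 15, I = 4, p = 30, r = 6, n_informative = 2,
                        seed = 55, beta_scale = 3)
  tr <- build_design_matrices(sim$trial, "T1")$obs$env_id != "Env1"
  cfg <- quick_bench(seed = 2)
  b0 <- build_predictor("M0", sim$trial, "T1", tr, seed = 1, config = cfg)
  expect_setequal(names(b0$kernels), c("K.e", "K.g", "K.ge"))
  expect_null(b0$covariates)
  expect_null(b0$selection)

  b3 <- build_predictor("M3", sim$trial, "T1", tr, seed = 1, config = cfg)
  expect_setequal(names(b3$kernels), c("K.e", "K.g", "K.ge"))
  if (length(b3$selection$selected) > 0) {
    expect_equal(ncol(b3$covariates), length(b3$selection$selected))
  } else {
    expect_null(b3$covariates)
  }

  b6 <- build_predictor("M6", sim$trial, "T1", tr, seed = 1, config = cfg)
  if (!is.null(b6$covariates)) expect_equal(ncol(b6$covariates), 1)

  expect_error(build_predictor("M15", sim$trial, "T1", tr),
               class = "enviroGS_argument_error")
})

test_that("empty selections trigger the identity-kernel fallback", {
  sim <- make_toy_trial(J = 12, I = 4, p = 20, r = 5, n_informative = 0,
                        seed = 56)
  tr <- build_design_matrices(sim$trial, "T1")$obs$env_id != "Env1"
  # an unreachable ladder forces an empty correlation selection
  cfg <- quick_bench(seed = 3, ladder = c(0.9999))
  b2 <- build_predictor("M2", sim$trial, "T1", tr, seed = 1, config = cfg)
  expect_true(b2$fallback)
  expect_setequal(names(b2$kernels), c("K.e", "K.g", "K.ge"))
  b4 <- build_predictor("M4", sim$trial, "T1", tr, seed = 1, config = cfg)
  expect_true(b4$fallback)
  expect_null(b4$covariates)
})

test_that("LOEO produces one disjoint fold per environment", {
  sim <- simulate_trial(J = 10, I = 2, p = 15, r = 4, n_informative = 1,
                        seed = 57)
  cfg <- bench_config(mcmc = mcmc_config(n_iter = 400, burn_in = 100,
                                         thin = 2),
                      seed = 4)
  cells <- loeo_run(sim$trial, models = c("M0", "M3"), config = cfg)
  expect_equal(nrow(cells), 4)                    # 2 envs x 2 models
  expect_setequal(unique(cells$env), c("Env1", "Env2"))
  expect_true(all(cells$n_test == 10))
  expect_true(all(cells$nrmse >= 0))
  expect_true(all(is.finite(cells$nrmse)))
})

test_that("win tables match exhaustive pairwise enumeration and conserve counts", {
  # hand-built NRMSE grid: 3 models x 2 envs x 1 trait
  cells <- expand.grid(trait = "t", env = c("e1", "e2"),
                       model_id = c("A", "B", "C"), stringsAsFactors = FALSE)
  cells$nrmse <- c(1.0, 2.0,   # A in e1, e2
                   1.5, 1.5,   # B
                   2.0, 1.0)   # C
  wt <- win_table(cells)
  # enumeration: e1: A<B<C (A 2 wins, B 1, C 0); e2: C<B<A
  won <- setNames(wt$env_level$won, wt$env_level$model_id)
  expect_equal(won, c(A = 2, B = 2, C = 2))
  expect_true(all(wt$env_level$total == 2 * 2))
  expect_equal(wt$env_level$pct, rep(50, 3))
  # trait level: all means equal 1.5 -> all ties, no wins
  expect_true(all(wt$trait_level$won == 0))

  # conservation: wins(m over m') + wins(m' over m) + ties = cells per pair
  set.seed(58)
  cells2 <- expand.grid(trait = c("t1", "t2"), env = c("e1", "e2", "e3"),
                        model_id = c("A", "B", "C", "D"),
                        stringsAsFactors = FALSE)
  cells2$nrmse <- sample(rep(seq(0.5, 2, length.out = 8), 3))
  models <- unique(cells2$model_id)
  grid <- unique(cells2[, c("trait", "env")])
  for (i in seq_along(models)) for (j in seq_along(models)) {
    if (i >= j) next
    mi <- models[i]; mj <- models[j]
    wins_ij <- wins_ji <- ties <- 0
    for (g in seq_len(nrow(grid))) {
      sub <- cells2[cells2$trait == grid$trait[g] & cells2$env == grid$env[g], ]
      xi <- sub$nrmse[sub$model_id == mi]; xj <- sub$nrmse[sub$model_id == mj]
      wins_ij <- wins_ij + (xi < xj); wins_ji <- wins_ji + (xj < xi)
      ties <- ties + (xi == xj)
    }
    expect_equal(wins_ij + wins_ji + ties, nrow(grid))
  }
  # a strictly dominated model never wins
  cells3 <- cells
  cells3$nrmse[cells3$model_id == "C"] <- 99
  wt3 <- win_table(cells3)
  expect_equal(wt3$env_level$won[wt3$env_level$model_id == "C"], 0)

  expect_error(win_table(cells[-1, ]), class = "enviroGS_argument_error")
})

test_that("comparison reports aggregate cells and baseline RE is zero", {
  cells <- expand.grid(trait = "t", env = c("e1", "e2"),
                       model_id = c("M0", "M3"), stringsAsFactors = FALSE)
  cells$nrmse <- c(1.2, 1.4, 1.0, 1.1)
  cells$cor <- c(0.5, 0.4, 0.6, 0.5)
  cells$b0 <- c(1, 1, 0.5, 0.5)
  cells$b <- c(0.2, 0.2, 0.1, 0.1)
  rep_ <- comparison_report(cells)
  s <- rep_$summary
  expect_equal(s$re_nrmse[s$model_id == "M0"], 0)
  expect_equal(s$re_cor[s$model_id == "M0"], 0)
  expect_equal(s$re_nrmse[s$model_id == "M3"],
               (1.3 / 1.05 - 1) * 100, tolerance = 1e-12)
  expect_equal(s$re_cor[s$model_id == "M3"],
               (0.55 / 0.45 - 1) * 100, tolerance = 1e-12)
  expect_error(comparison_report(cells, baseline = "M9"),
               class = "enviroGS_argument_error")
})
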