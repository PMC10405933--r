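test_that("column standardization centres, scales, drops constants and is idempotent", {
  z <- standardize_columns(matrix(c(0, 2), ncol = 1))
  expect_equal(as.numeric(z), c(-1 / sqrt(2), 1 / sqrt(2)))

  M <- matrix(rnorm(40), 10, 4)
  S <- standardize_columns(M)
  expect_equal(colMeans(S), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(S, 2, sd), rep(1, 4), tolerance = 1e-12)
  S2 <- standardize_columns(S)
  expect_equal(unname(S2[, ]), unname(S[, ]), tolerance = 1e-12)

  Mc <- cbind(a = rep(5, 6), b = rnorm(6))
  expect_warning(Sc <- standardize_columns(Mc), "zero-variance")
  expect_equal(ncol(Sc), 1)
  expect_equal(attr(Sc, "kept"), 2L)

  expect_error(standardize_columns(matrix(1, 5, 2)),
               class = "enviroGS_degenerate_error")
  expect_error(standardize_columns(matrix(1, 1, 2)),
               class = "enviroGS_argument_error")
})

test_that("design matrices are one-hot incidence matrices in observation order", {
  sim <- make_toy_trial(seed = 8)
  d <- build_design_matrices(sim$trial, "T1")
  expect_true(all(rowSums(d$Ze) == 1))
  expect_true(all(rowSums(d$Zg) == 1))
  expect_equal(colSums(d$Ze),
               table(factor(d$obs$env_id, d$env_levels)) |> as.numeric() |>
                 setNames(d$env_levels))
  # two observations in two distinct environments -> Ze is the identity
  toy <- trial_data(
    data.frame(env_id = c("E1", "E2"), genotype_id = c("g1", "g1"),
               trait_id = "t", value = c(1, 2)),
    matrix(c(0, 1, 2, 1), 1, 4, dimnames = list("g1", NULL)),
    matrix(rnorm(4), 2, 2, dimnames = list(c("E1", "E2"), NULL)))
  d2 <- build_design_matrices(toy, "t")
  expect_equal(unname(d2$Ze), diag(2))
  expect_error(build_design_matrices(sim$trial, "nope"),
               class = "enviroGS_argument_error")
})

test_that("genomic and environmental kernels match hand and brute-force oracles", {
  expect_equal(genomic_kernel(matrix(c(0L, 2L), 2, 1,
                                     dimnames = list(c("a", "b"), NULL))),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))

  set.seed(14)
  M <- matrix(sample(0:2, 15, replace = TRUE), 5, 3,
              dimnames = list(paste0("g", 1:5), NULL))
  K <- genomic_kernel(M)
  expect_equal(unname(K), brute_force_kernel(standardize_columns(M)),
               tolerance = 1e-12)

  X1 <- matrix(c(3, 7), 2, 1, dimnames = list(c("E1", "E2"), NULL))
  expect_equal(unname(env_covariate_kernel(X1)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12)

  set.seed(15)
  Xe <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("E", 1:4), NULL))
  He <- env_covariate_kernel(Xe)
  expect_equal(unname(He), brute_force_kernel(standardize_columns(Xe)),
               tolerance = 1e-12)

  # orthonormalised standardized columns with r = I - 1 give the centring projector
  Xh <- standardize_columns(contr.helmert(4))
  rownames(Xh) <- paste0("E", 1:4)
  expect_equal(unname(env_covariate_kernel(Xh)), diag(4) - 1 / 4,
               tolerance = 1e-10)

  expect_error(genomic_kernel(matrix(1L, 3, 2)),
               class = "enviroGS_degenerate_error")
  expect_error(env_covariate_kernel(matrix(0, 3, 0)),
               class = "enviroGS_degenerate_error")
})

test_that("observation-level environment kernels follow their definitions", {
  toy <- trial_data(
    data.frame(env_id = c("E1", "E2"), genotype_id = c("g1", "g2"),
               trait_id = "t", value = c(1, 2)),
    matrix(c(0L, 2L, 1L, 1L), 2, 2, dimnames = list(c("g1", "g2"), NULL)),
    matrix(c(1, 4), 2, 1, dimnames = list(c("E1", "E2"), NULL)))
  d <- build_design_matrices(toy, "t")
  expect_equal(unname(observation_env_kernel(d)), diag(2) / 2)
  expect_equal(unname(observation_env_kernel(d, diag(2))), diag(2))
  # rows of K.ec are shared within an environment
  sim <- make_toy_trial(seed = 20)
  ds <- build_design_matrices(sim$trial, "T1")
  He <- env_covariate_kernel(sim$trial$env_covariates)
  Kec <- observation_env_kernel(ds, He)
  same_env <- which(ds$obs$env_id == ds$obs$env_id[1])
  expect_equal(Kec[same_env[1], ], Kec[same_env[2], ], tolerance = 1e-12)
  expect_error(observation_env_kernel(d, diag(3)),
               class = "enviroGS_argument_error")
})

test_that("the Hadamard interaction kernel matches elementwise multiplication", {
  toy <- trial_data(
    data.frame(env_id = c("E1", "E1", "E2"), genotype_id = c("g1", "g2", "g1"),
               trait_id = "t", value = 1:3),
    matrix(c(0L, 2L, 1L, 0L, 2L, 0L), 2, 3, dimnames = list(c("g1", "g2"), NULL)),
    matrix(c(1, 4), 2, 1, dimnames = list(c("E1", "E2"), NULL)))
  d <- build_design_matrices(toy, "t")
  Kg <- genomic_kernel(toy$markers)
  Ke <- observation_env_kernel(d)
  Kge <- interaction_kernel(Ke, Kg, d)
  ZKZ <- d$Zg %*% Kg %*% t(d$Zg)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(Kge[i, j], Ke[i, j] * ZKZ[i, j], tolerance = 1e-12)
  }
  # all-ones environment factor is the Hadamard identity
  ones <- matrix(1, 3, 3)
  expect_equal(unname(interaction_kernel(ones, Kg, d)), unname(ZKZ),
               tolerance = 1e-12)
  expect_error(interaction_kernel(Ke, diag(3), d),
               class = "enviroGS_argument_error")
})

test_that("K.gec built from an identity H.e collapses to K.ge", {
  sim <- make_toy_trial(seed = 21)
  d <- build_design_matrices(sim$trial, "T1")
  Kg <- genomic_kernel(sim$trial$markers)
  I_env <- ncol(d$Ze)
  Kge <- interaction_kernel(observation_env_kernel(d), Kg, d)
  Kgec_id <- interaction_kernel(observation_env_kernel(d, diag(I_env) / I_env),
                                Kg, d)
  expect_equal(Kge, Kgec_id, tolerance = 1e-12)
})

test_that("all kernels are symmetric and PSD on random trials", {
  for (s in 1:3) {
    sim <- make_toy_trial(J = 12, I = 3, p = 25, r = 5, seed = 300 + s,
                          balance = if (s == 3) 0.8 else 1)
    d <- build_design_matrices(sim$trial, "T1")
    Kg <- genomic_kernel(sim$trial$markers)
    He <- env_covariate_kernel(sim$trial$env_covariates)
    Ke <- observation_env_kernel(d)
    Kec <- observation_env_kernel(d, He)
    for (K in list(Kg, He, Ke, Kec,
                   interaction_kernel(Ke, Kg, d),
                   interaction_kernel(Kec, Kg, d))) {
      expect_lt(max(abs(K - t(K))), 1e-10 * max(abs(K)))
      expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                -1e-8 * max(abs(K)))
    }
  }
})
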