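# Shared fixtures: everything is generated in code at test time.

# a small fully in-memory trial with a hand-set structure
make_toy_trial <- function(J = 20, I = 4, p = 40, r = 8, n_informative = 2,
                           seed = 42, ...) {
  simulate_trial(J = J, I = I, p = p, r = r, n_informative = n_informative,
                 seed = seed, ...)
}

# short chains for unit tests; enough draws for posterior means of tiny fits
quick_mcmc <- function(seed = 1, ...) {
  mcmc_config(n_iter = 1200, burn_in = 300, thin = 2, seed = seed, ...)
}

quick_bench <- function(seed = 1, ...) {
  bench_config(mcmc = quick_mcmc(seed),
               boruta = list(alpha = 0.01, max_runs = 15L,
                             rf_params = list(num.trees = 120)),
               seed = seed, ...)
}

# brute-force O(n^2 p) cross-product kernel: independent of the implementation
brute_force_kernel <- function(M_std) {
  n <- nrow(M_std); p <- ncol(M_std)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(p)) acc <- acc + M_std[i, k] * M_std[j, k]
    K[i, j] <- acc / p
  }
  K
}

# exact binomial tail by coefficient summation (oracle for boruta_hit_test)
binom_upper_tail <- function(h, n) sum(choose(n, h:n)) / 2^n
binom_lower_tail <- function(h, n) sum(choose(n, 0:h)) / 2^n
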