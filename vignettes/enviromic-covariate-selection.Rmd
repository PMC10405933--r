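---
title: "Kernel methods and covariate selection for multi-environment genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel methods and covariate selection for multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enviroGS)
```

## The problem

Genomic selection trains a statistical model on phenotyped, genotyped lines
and predicts the merit of lines (or line-by-environment combinations) that
have not been phenotyped. In multi-environment trials (METs) a large share of
phenotypic variation sits at the environment level, and quantitative
descriptors of each environment — temperature, radiation, humidity and the
like, often called *enviromic* covariates — can in principle predict it. In
practice, naively adding every measured covariate can just as easily inject
noise. `enviroGS` implements a kernel-based Bayesian MET prediction model
together with two leakage-safe covariate-selection procedures and a
benchmarking harness that quantifies, under leave-one-environment-out (LOEO)
cross-validation, whether selected covariates help.

## The model

For genotype $j$ in environment $i$,

$$
y_{ij} = \mu + E_i + g_j + gE_{ij} + \sum_{k=1}^{r_s} X_{ik}\beta_k +
\varepsilon_{ij},
$$

with $E \sim N(0, \sigma_E^2\, H_e)$, $g \sim N(0, \sigma_g^2\, K_g)$,
$gE \sim N(0, \sigma_{gE}^2\, K_{gec})$ and
$\varepsilon_{ij} \sim N(0, \sigma^2)$ i.i.d. The relationship matrices are
linear kernels on standardized inputs:

* $K_g = M_e M_e^\top / p$, where $M_e$ is the column-standardized
  $J \times p$ matrix of 0/1/2 marker dosages (`genomic_kernel()`).
* $H_e = X_e X_e^\top / r$, the same construction over the $I \times r$
  standardized environmental covariates (`env_covariate_kernel()`).
* At observation level, the environment kernel is either identity-based,
  $K_e = Z_e Z_e^\top / I$, or covariate-based, $K_{ec} = Z_e H_e Z_e^\top$,
  where $Z_e$ is the environment incidence matrix
  (`observation_env_kernel()`). The printed source formula for $K_e$ is
  typographically ambiguous; it is read as division by the number of
  environments $I$.
* Interactions are Hadamard products,
  $K_{ge} = K_e \odot Z_g K_g Z_g^\top$ and
  $K_{gec} = K_{ec} \odot Z_g K_g Z_g^\top$ (`interaction_kernel()`).

Standardization uses the sample ($n-1$) standard deviation; the sources say
only "centered and scaled", and the $n-1$ convention matches common genomic
selection practice. Zero-variance columns (monomorphic markers, constant
covariates) are dropped with a warning, never imputed; the divisor is the
count of retained columns. Markers are standardized over **all** lines and
covariates over **all** environments, including the held-out one: genotypes
and covariate measurements are legitimately available at prediction time.
Only *responses* are held out, and covariate **selection** sees training
responses only.

## Posterior computation

`fit_predict()` draws from the posterior by Gibbs sampling. Each kernel
effect is re-parameterised in the kernel's eigenbasis,
$u_t = B_t\gamma_t$ with $B_t = V_t D_t^{1/2}$ and
$\gamma_t \sim N(0, \sigma_t^2 I)$; eigenvalues below $10^{-10}$ of the
largest are truncated. Because the prior on $\gamma_t$ is isotropic, a second
(fixed) rotation diagonalising $W_t^\top W_t$ — $W_t$ being the training rows
of $B_t$ — makes the full conditional of the whole block elementwise, so each
term is updated *jointly* per iteration at $O(nm)$ cost. Held-out rows
receive predictions through the test rows of $B_t$, i.e. through the kernel's
training–test cross-covariance; held-out responses are never read.

Priors and defaults (all tunable through `mcmc_config()`):

* Variance components: scaled-inverse-$\chi^2$ with `prior_df = 5`; scales
  elicited by splitting half the training phenotypic variance equally among
  the kernel terms and half to the residual (mode matching).
* Regression coefficients: Gaussian with fixed variance
  `beta_prior_mult = 25` times the training phenotypic variance — weakly
  informative, near-fixed-effect behaviour, but proper. This matters because
  environment-level covariates expanded to observations have rank at most
  $I$, so the coefficient vector is never fully identified; the proper prior
  keeps the sampler stable and the posterior SD honest about the
  unidentified directions.
* Chain: 10,000 iterations, 2,000 burn-in, thinning 5 by default. The test
  suite and benchmark runs use shorter chains (typically 800–8,000 iterations
  depending on the check) because posterior *means* of this conjugate
  Gaussian model mix quickly; Monte Carlo standard errors are estimated by
  batch means and reported per prediction.
* `fixed_variances` pins selected components, which is how the test suite
  compares the sampler against the closed-form mixed-model (GBLUP) solution.

## Covariate selection

Both selectors receive training-fold rows only — by interface, they can never
see a held-out response. Correlations are computed at observation level
(covariates expanded by $Z_e$) per trait; the sources do not state whether
environment-mean or observation-level responses are used, and the
observation-level choice keeps selection consistent with the sign-alignment
step below.

**Threshold-correlation (TC) ladder** (`correlation_ladder_select()`): the
absolute Pearson correlation of each covariate with the training response is
compared against the descending ladder 0.7, 0.6, 0.5, 0.4, 0.3. The first
rung met by at least one covariate defines the selected set; if none reaches
0.3 the selection is empty and the model trains without covariates.
Selection is sign-agnostic (|r|), consistent with the later sign-flipping of
negatively correlated covariates.

**Boruta** (`boruta_select()`): per run, every still-undecided covariate is
cloned into a randomly permuted "shadow"; a random forest
(`ranger`, permutation importance, 500 trees by default) is fitted on real
plus shadow columns; a covariate scores a *hit* when its importance strictly
exceeds the maximum shadow importance; after every run the exact binomial
test against $p = 1/2$ (`boruta_hit_test()`, `alpha = 0.01`) promotes
covariates to Confirmed or Rejected; whatever is undecided after `max_runs`
(default 100) stays Tentative. The sources name neither alpha, run count,
forest size nor importance type; these defaults are declared choices
following the original Boruta description. No multiple-testing correction is
applied across covariates (the test is per-feature), and the optional
"rough fix" for tentative features is out of scope.

## Engineered covariate blocks

* `expand_to_observations()` replicates environment rows to observations
  ($Z_e X_e$) — covariates are constant within an environment.
* `signed_average()` builds the single covariate $X_{e.avg}$: training
  correlations fix each selected covariate's direction, negatively
  correlated columns are multiplied by $-1$, and the per-environment row
  mean over all environments is returned. Flips are functions of training
  rows only and are recomputed per trait per LOEO fold. A zero training
  correlation leaves the sign unchanged.
* `quadratic_augment()` implements the quadratic block $X_{e2}$ as the
  **concatenation** $[X_e \mid X_e \circ X_e]$ — the source formula
  "$X_e + X_e * X_e$" is read as extra columns, since the accompanying prose
  says the squares "also were used ... as covariates". Squares are taken on
  standardized columns and re-standardized; squares that come out constant
  are dropped with a warning.

## The fifteen predictors and LOEO evaluation

`model_registry()` encodes M0–M14: M0 is the covariate-free baseline
($K_e + K_g + K_{ge}$); M1 adds all covariates unselected; M2–M8 use the
correlation ladder in kernels ($K_{ec}/K_{gec}$) and/or regression blocks
($X_e$, $X_{e2}$, $X_{e.avg}$), with M8 intersecting ladder and Boruta
selections; M9–M14 use Boruta, including the joint marker-plus-covariate
space ($X_{g.ec}$, M9 — whose kernel set deliberately has no standalone
genotype term), Boruta-selected markers feeding $K_g$ (M10), and
tentative-in/tentative-out variants (M11–M14). M12 is implemented literally
from its tabulated definition ($K_{ec} + K_g + K_{ge} + X_{e.avg}$) even
though the neighbouring prose hints it lacked covariate kernels; the
contradiction is resolved in favour of the table. When a model requires
covariate-based kernels but the fold's selection is empty, it falls back to
the identity-based kernels, flagged in the output.

`loeo_run()` holds out each environment in turn, reruns selection on the
remaining rows, fits, and scores the held-out environment with:
NRMSE, Pearson correlation, and the calibration statistics $b_0 = |a|$ and
$b = |1 - s|$ from regressing observed on predicted. NRMSE is RMSE divided
by the **absolute mean** of the observed test values — the sources never
define the normalization, and mean-normalization is consistent with
published values above 1 under whole-environment extrapolation
(`normalization = "sd"` is available). Dataset-level summaries are
unweighted means over trait-by-environment cells. Relative efficiency versus
M0 is $(\mathrm{NRMSE}_{M0}/\mathrm{NRMSE}_{Mk} - 1)\times 100$ for
error-like metrics (also applied to $b_0$ and $b$) and
$(\mathrm{Cor}_{Mk}/\mathrm{Cor}_{M0} - 1)\times 100$ for correlation.
Win tables count, per trait-by-environment cell, every ordered model pair
whose NRMSE is strictly lower (ties score for neither); totals are
opponents × cells of our own grid, since the published totals do not factor
consistently. Kernel eigen-factorizations are cached per fold and shared
across the models that use them.

## The synthetic generator

`simulate_trial()` draws data from exactly the generative structure the
model assumes, with known truth: which covariates are informative, their
coefficients, and the variance components. Design choices:

* Covariates are i.i.d. standard normal across environments. The analysis
  needs only their correlation structure with the response, and desk-scale
  testability beats meteorological realism. Real covariates are smooth,
  cross-correlated and shared across years — none of which the generator
  emulates, so passing tests certify the *machinery*, not field performance.
* Informative covariates act twice, as in the model's own dual use of
  $X_e$: through the fixed regression $\sum_k X_{ik}\beta_k$ and through
  $H_e$ (built from all covariates).
* Defaults: variance components
  $(\sigma_E^2, \sigma_g^2, \sigma_{gE}^2, \sigma^2) =
  (0.25, 0.75, 0.25, 0.75)$ and `beta_scale = 2` with signs drawn at
  random. This emulates the regime where measured covariates explain most
  environment-level variance ($\sigma_E^2$ is the *unexplained* remainder)
  — the setting in which covariate selection has something to find. With
  four independent informative covariates the per-covariate observation-level
  correlation has a hard ceiling near $0.5$ (four covariates at $r = 0.6$
  each would need $R^2 = 1.44$), and these defaults sit close to that
  ceiling (population $r \approx 0.47$ per informative covariate).
* Unbalance is uniform random deletion of genotype-by-environment cells
  (the mechanism is unstated in the sources); every environment keeps at
  least two cells. $\mu$ defaults to 0 and traits are independent.
* Marker allele frequencies are uniform on `maf_range`; monomorphic markers
  are redrawn a bounded number of times, then dropped with a warning. No
  linkage disequilibrium is simulated.

## Known limitations, and what the tests show

* **Selection at few environments is intrinsically unreliable.** An
  environment-level covariate carries $I$ effective data points regardless
  of how many observations expand it. At $I = 6$, null sample correlations
  have a standard deviation near $0.45$, so among 16 noise covariates
  several typically exceed the attainable correlation of a true covariate;
  and for a random forest *any* environment-level covariate indexes
  environments, so observation-level shadow permutation makes Boruta
  confirm liberally. The recovery experiments in the acceptance suite and
  `scripts/acceptance.R` quantify this: selector precision/recall at
  $I = 6$ falls far short of what the same selectors achieve on
  observation-level features (where the unit tests show clean separation of
  planted signals). Benchmarks on real METs with few environments should be
  read with the same caution.
* The benchmark directionally reproduces both published regimes on
  synthetic data: with informative covariates, the sign-aligned average
  model (M6) and the selected-covariate model (M3) achieve lower mean LOEO
  NRMSE than the all-covariates model (M1), whose unshrunk regression block
  extrapolates wildly; with no informative covariates, no covariate model
  beats the covariate-free baseline M0 beyond Monte Carlo noise.
* Numerical conventions: kernels are symmetrized and receive at most
  $10^{-8}$ relative diagonal jitter (round-off-scale negatives are left
  untouched); matrices indefinite beyond that raise structured errors.
  NRMSE errors out when the observed test mean is zero, naming the
  normalization decision. Ties in win counts score for neither model.
* Problem sizes: the heavy acceptance checks run at $J = 100$ lines,
  $I = 6$ environments, $p = 500$ markers, $r = 20$ covariates, with
  reduced chains (800–2,000 iterations) and seed counts of 5–20 depending
  on the check; these are the package's documented experiment sizes.
* Out of scope: BLUE computation from plot data, the full prior menu of
  general-purpose Bayesian regression software (BayesA/B/C, Bayesian
  LASSO), REML, multi-trait models, pedigree or nonlinear kernels, other
  cross-validation schemes, and real weather-data ingestion.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_trial(J = 40, I = 5, p = 150, r = 10, n_informative = 3,
                      seed = 11)
cfg <- bench_config(mcmc = mcmc_config(n_iter = 1500, burn_in = 500,
                                       thin = 2),
                    seed = 1)
cells <- loeo_run(sim$trial, models = c("M0", "M1", "M3", "M6"),
                  config = cfg)
comparison_report(cells)
```
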