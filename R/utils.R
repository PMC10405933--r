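# Internal helpers: structured errors, seed scoping, matrix hygiene.

#' @keywords internal
stop_gs <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "enviroGS_error"), call = call))
}

#' Evaluate an expression under a fixed RNG seed, restoring the caller's stream
#'
#' All stochastic operations in the package funnel through this helper so that
#' a fixed seed yields bit-reproducible output without perturbing the global
#' random number stream of the session.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_gs("`seed` must be a single integer", "enviroGS_argument_error")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream-specific child seed from a master seed
#'
#' Hashes the master seed together with any number of string or numeric
#' labels into a new seed below 2^31. Every stochastic stage of the pipeline
#' draws its seed this way, so runs are reproducible and adding one stream
#' (a model, a fold) does not perturb the others.
#'
#' @param seed master seed (or `NULL`, passed through).
#' @param ... labels (strings or numbers) identifying the stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  x <- as.numeric(seed)
  for (p in parts) x <- (x * 7919 + p * 104729 + 1299709) %% 2147483629
  as.integer(x)
}

# Symmetrize and (if needed) jitter a kernel so it is numerically PSD.
# Jitter is bounded; a matrix that is indefinite beyond the bound errors out.
ensure_psd <- function(K, max_jitter = 1e-8, label = "kernel") {
  K <- (K + t(K)) / 2
  d <- mean(diag(K))
  scale <- max(abs(K), 1e-300)
  lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min < -max_jitter * scale) {
    stop_gs(sprintf("%s is not positive semi-definite (min eigenvalue %.3e)",
                    label, lam_min), "enviroGS_kernel_error")
  }
  # only jitter when the deficit exceeds plain round-off; tiny negative
  # eigenvalues (|.| <= 1e-12 * scale) are left untouched so exact-arithmetic
  # identities survive
  if (lam_min < -1e-12 * scale) {
    diag(K) <- diag(K) + (-lam_min + 1e-12 * scale)
  }
  K
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
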