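#' Derive a reproducible child seed from a master seed
#'
#' Fans a single master seed out to per-subject / per-condition / per-stage
#' streams via a fixed counter scheme, keeping results inside the 32-bit
#' integer range R's RNG seeding accepts.
#'
#' @param master integer master seed.
#' @param ... integer counters (e.g. subject index, condition index, stage).
#' @return a single integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, ...) {
  counters <- c(...)
  x <- as.double(master) %% 2147483647
  for (k in counters) {
    # LCG-style mixing; constants are primes below 2^31
    x <- (x * 48271 + as.double(k) * 16807 + 11) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators that draw random
#' numbers internally do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Symmetric positive-semidefinite matrix square root
#'
#' @param M symmetric PSD matrix; eigenvalues slightly below zero (round-off)
#'   are clipped at zero, genuinely negative ones are an error.
#' @return matrix A with A %*% t(A) = M.
#' @keywords internal
sqrtm_psd <- function(M, tol = 1e-10) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol * max(abs(lam), 1))) {
    stop("matrix is not positive semidefinite (eigenvalue ", min(lam), ")")
  }
  lam[lam < 0] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Invert a symmetric matrix with an eigenvalue floor
#'
#' Guards the noise-free limit where the inferred noise matrix collapses to
#' numerical zero.
#' @keywords internal
solve_psd <- function(M, floor = 1e-14) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, floor * max(abs(e$values), floor))
  e$vectors %*% ((1 / lam) * t(e$vectors))
}

#' Unwrap a wrapped phase sequence
#'
#' @param p phase values in radians (wrapped or partially wrapped).
#' @return unwrapped phase with jumps larger than pi removed.
#' @keywords internal
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
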