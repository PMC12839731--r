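#' Fourier basis for the coupled phase model
#'
#' Builds the truncated Fourier basis in which each oscillator's phase
#' velocity is expanded: per oscillator one constant term (whose coefficient
#' is the natural frequency omega_i) plus sin and cos of every integer
#' combination k*phi1 + s*phi2 with |k|, |s| <= K, (k, s) != (0, 0),
#' deduplicated under sign symmetry (sin(-theta) = -sin(theta)). The
#' canonical representative has k > 0, or k = 0 and s > 0.
#'
#' With K = 1 each oscillator has 1 + 2*4 = 9 terms; with K = 2 (the working
#' truncation here) 1 + 2*12 = 25 terms.
#'
#' @param K truncation order (>= 1).
#' @return a \code{fourier_basis}: list with \code{K}, \code{terms} (data
#'   frame: \code{osc}, \code{k}, \code{s}, \code{kind}, \code{name}) and
#'   \code{M} (total number of terms over both oscillators).
#' @export
build_basis <- function(K = 2) {
  if (!is.numeric(K) || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  pairs <- expand.grid(k = 0:K, s = -K:K)
  pairs <- pairs[pairs$k > 0 | (pairs$k == 0 & pairs$s > 0), ]
  pairs <- pairs[order(pairs$k, pairs$s), ]
  terms <- do.call(rbind, lapply(1:2, function(osc) {
    tt <- rbind(
      data.frame(osc = osc, k = 0L, s = 0L, kind = "const"),
      do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        data.frame(osc = osc, k = pairs$k[i], s = pairs$s[i],
                   kind = c("sin", "cos"))
      }))
    )
    tt
  }))
  terms$name <- ifelse(terms$kind == "const",
                       paste0("c", terms$osc, "_const"),
                       paste0("c", terms$osc, "_", terms$kind, "_",
                              terms$k, "_", terms$s))
  rownames(terms) <- NULL
  structure(list(K = K, terms = terms, M = nrow(terms)),
            class = "fourier_basis")
}

#' @export
print.fourier_basis <- function(x, ...) {
  cat("Fourier basis: K =", x$K, ",", x$M, "terms (",
      x$M / 2, "per oscillator )\n")
  invisible(x)
}

# Evaluate the basis functions of one oscillator at given phases.
# Returns an L x M_osc matrix (columns follow the basis term order).
eval_basis <- function(basis, osc, phi1, phi2) {
  tt <- basis$terms[basis$terms$osc == osc, , drop = FALSE]
  out <- matrix(0, length(phi1), nrow(tt))
  for (j in seq_len(nrow(tt))) {
    out[, j] <- if (tt$kind[j] == "const") 1 else {
      th <- tt$k[j] * phi1 + tt$s[j] * phi2
      if (tt$kind[j] == "sin") sin(th) else cos(th)
    }
  }
  colnames(out) <- tt$name
  out
}

# Derivative of each basis function with respect to the oscillator's own
# phase (phi1 for osc 1, phi2 for osc 2) — the Jacobian term of the
# likelihood.
eval_basis_deriv <- function(basis, osc, phi1, phi2) {
  tt <- basis$terms[basis$terms$osc == osc, , drop = FALSE]
  out <- matrix(0, length(phi1), nrow(tt))
  for (j in seq_len(nrow(tt))) {
    if (tt$kind[j] == "const") next
    m <- if (osc == 1) tt$k[j] else tt$s[j]
    if (m == 0) next
    th <- tt$k[j] * phi1 + tt$s[j] * phi2
    out[, j] <- if (tt$kind[j] == "sin") m * cos(th) else -m * sin(th)
  }
  colnames(out) <- tt$name
  out
}
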