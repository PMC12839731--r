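#' Logarithmic CWT frequency grid
#'
#' @param fmin,fmax band limits in Hz (defaults cover the respiration and
#'   cardiac bands, 0.05-2 Hz).
#' @param voices grid points per octave (default 24).
#' @export
cwt_freq_grid <- function(fmin = 0.05, fmax = 2, voices = 24) {
  stopifnot(fmin > 0, fmax > fmin, voices >= 1)
  2^seq(log2(fmin), log2(fmax), by = 1 / voices)
}

#' Continuous Morlet wavelet transform
#'
#' Time-frequency decomposition with the complex Morlet wavelet of central
#' frequency f0 = 1,
#' \deqn{\psi(u) = \frac{1}{\sqrt{2\pi}}\left(e^{i 2\pi f_0 u} -
#'   e^{-(2\pi f_0)^2/2}\right) e^{-u^2/2},}
#' including the (numerically tiny) zero-mean admissibility correction term.
#' For each analysis frequency f the signal is correlated with the rescaled
#' wavelet \eqn{\sqrt{f}\,\psi(f(u-t))}; the computation runs in the Fourier
#' domain using the wavelet's closed-form spectrum.
#'
#' @param x real signal, finite everywhere.
#' @param fs_hz sampling rate; must exceed twice the highest analysis
#'   frequency.
#' @param freqs_hz strictly increasing positive analysis frequencies.
#' @return a \code{tf_map}: list with \code{time_s}, \code{freqs_hz},
#'   \code{coeffs} (complex matrix, frequency x time), \code{coi_s}
#'   (per-frequency cone-of-influence half-width: coefficients closer than
#'   this to either edge are edge-affected) and \code{fs_hz}.
#' @export
morlet_cwt <- function(x, fs_hz, freqs_hz = cwt_freq_grid()) {
  if (anyNA(x) || any(!is.finite(x))) stop("signal contains NaN or non-finite values")
  stopifnot(fs_hz > 0, all(freqs_hz > 0), !is.unsorted(freqs_hz, strictly = TRUE))
  if (fs_hz <= 2 * max(freqs_hz)) {
    stop("frequency grid reaches ", max(freqs_hz),
         " Hz, at or beyond Nyquist for fs = ", fs_hz, " Hz")
  }
  n <- length(x)
  np <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, np - n)))
  nu <- c(0:(np / 2), -(np / 2 - 1):-1) * fs_hz / np # FFT bin frequencies
  f0 <- 1
  W <- matrix(0 + 0i, length(freqs_hz), n)
  corr <- exp(-(2 * pi * f0)^2 / 2)
  for (j in seq_along(freqs_hz)) {
    f <- freqs_hz[j]
    # closed-form Morlet spectrum evaluated at nu/f (unit-scale wavelet)
    psi_hat <- exp(-(2 * pi * (nu / f - f0))^2 / 2) -
      corr * exp(-(2 * pi * nu / f)^2 / 2)
    row <- stats::fft(X * psi_hat, inverse = TRUE) / np
    W[j, ] <- row[seq_len(n)] / sqrt(f) / fs_hz
  }
  structure(list(time_s = (seq_len(n) - 1) / fs_hz, freqs_hz = freqs_hz,
                 coeffs = W, coi_s = sqrt(2) / freqs_hz, fs_hz = fs_hz),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat("Morlet CWT:", length(x$freqs_hz), "frequencies x",
      length(x$time_s), "time points, band [",
      signif(min(x$freqs_hz), 3), ",", signif(max(x$freqs_hz), 3), "] Hz\n")
  invisible(x)
}

#' Extract the wavelet ridge (instantaneous frequency curve)
#'
#' Finds the frequency path maximizing the integrated log-modulus of the
#' transform subject to a per-step quadratic frequency-jump penalty, by
#' dynamic programming over the (band-restricted) frequency grid. The path
#' score uses the frequency-normalized modulus \eqn{\sqrt{f}\,|W(f,t)|}
#' (amplitude scalogram), which removes the systematic low-frequency tilt of
#' the raw modulus under the \eqn{\sqrt{\omega}} transform normalization.
#'
#' @param tf a \code{tf_map} from [morlet_cwt()].
#' @param freq_band length-2 numeric band (Hz) inside the map's grid.
#' @param smoothness_penalty weight of the squared per-step jump (in grid
#'   bins); larger values give smoother ridges.
#' @return a \code{frequency_trace} on the map's time grid with attribute
#'   \code{interior} (logical: outside the cone of influence at the ridge
#'   frequency).
#' @export
extract_ridge <- function(tf, freq_band = range(tf$freqs_hz),
                          smoothness_penalty = 0.2) {
  stopifnot(inherits(tf, "tf_map"), length(freq_band) == 2)
  keep <- which(tf$freqs_hz >= freq_band[1] & tf$freqs_hz <= freq_band[2])
  if (length(keep) == 0) stop("empty frequency band [", freq_band[1], ", ",
                              freq_band[2], "] Hz")
  f <- tf$freqs_hz[keep]
  A <- log(abs(tf$coeffs[keep, , drop = FALSE]) + 1e-300) + 0.5 * log(f)
  nf <- length(f); nt <- ncol(A)
  jump <- smoothness_penalty * outer(seq_len(nf), seq_len(nf), function(i, j) (i - j)^2)
  score <- A[, 1]
  back <- matrix(0L, nf, nt)
  for (t in 2:nt) {
    cand <- score - jump             # nf x nf: previous bin x current bin
    best <- max.col(t(cand), ties.method = "first")
    score <- cand[cbind(best, seq_len(nf))] + A[, t]
    back[, t] <- best
  }
  path <- integer(nt)
  path[nt] <- which.max(score)
  for (t in nt:2) path[t - 1] <- back[path[t], t]
  ridge_f <- f[path]
  out <- new_frequency_trace(tf$time_s, ridge_f)
  coi <- sqrt(2) / ridge_f
  attr(out, "interior") <- tf$time_s >= coi & tf$time_s <= max(tf$time_s) - coi
  attr(out, "bin_index") <- path
  out
}
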