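#' Instantaneous phase via the analytic signal
#'
#' Zero-phase band-pass (4th-order Butterworth, forward-backward), mean
#' removal, analytic-signal angle and unwrapping. Used for the respiration
#' channel; the protophase is used directly without a protophase-to-phase
#' transformation.
#'
#' @param x real waveform.
#' @param fs_hz sampling rate.
#' @param band length-2 pass band in Hz, inside (0, fs/2).
#' @return data frame \code{time_s}, \code{phi} (unwrapped, radians).
#' @export
hilbert_phase <- function(x, fs_hz, band) {
  stopifnot(length(band) == 2)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs_hz / 2) {
    stop("band must satisfy 0 < low < high < fs/2")
  }
  if (stats::sd(x) < 1e-12 * (abs(mean(x)) + 1)) {
    stop("signal has no oscillation (constant input)")
  }
  fc <- mean(band)
  if (length(x) < 10 * fs_hz / fc) {
    stop("signal shorter than 10 cycles of the band centre frequency")
  }
  bf <- signal::butter(4, band / (fs_hz / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  xf <- xf - mean(xf)
  # analytic signal: zero the negative-frequency half of the spectrum
  n <- length(xf)
  H <- numeric(n)
  if (n %% 2 == 0) {
    H[c(1, n / 2 + 1)] <- 1
    H[2:(n / 2)] <- 2
  } else {
    H[1] <- 1
    H[2:((n + 1) / 2)] <- 2
  }
  xa <- stats::fft(stats::fft(xf) * H, inverse = TRUE) / n
  phi <- unwrap_phase(Arg(xa))
  data.frame(time_s = (seq_len(n) - 1) / fs_hz, phi = phi)
}

#' Instantaneous phase from marked events
#'
#' Assigns phase 2*pi*(i-1) to the i-th event (e.g. R-peak) and interpolates
#' linearly onto the output grid; the phase advances by exactly 2*pi between
#' consecutive events. Samples before the first or after the last event are
#' returned as NA (invalid).
#'
#' @param event_times_s strictly increasing event times (>= 3 events).
#' @param out_grid output time grid in seconds.
#' @return data frame \code{time_s}, \code{phi} (NA outside the event span).
#' @export
event_phase <- function(event_times_s, out_grid) {
  if (length(event_times_s) < 3) stop("need at least 3 events")
  if (is.unsorted(event_times_s, strictly = TRUE)) {
    stop("event times must be strictly increasing")
  }
  phi_ev <- 2 * pi * (seq_along(event_times_s) - 1)
  phi <- stats::approx(event_times_s, phi_ev, xout = out_grid,
                       rule = 1)$y # NA outside
  data.frame(time_s = out_grid, phi = phi)
}

#' Detect events in an impulse-train surrogate channel
#'
#' Simple threshold detector for the rendered cardiac impulse train (not a
#' clinical QRS detector).
#' @param x impulse-train waveform.
#' @param fs_hz sampling rate.
#' @param threshold detection level.
#' @return event times in seconds.
#' @export
detect_impulses <- function(x, fs_hz, threshold = 0.5) {
  (which(x >= threshold) - 1) / fs_hz
}

#' Align two phase series onto a common uniform grid
#'
#' Linearly resamples both unwrapped phases onto a uniform grid with step
#' \code{target_h_s} over the intersection of their valid (non-NA) ranges.
#'
#' @param phi1_series,phi2_series data frames \code{time_s}, \code{phi}
#'   (respiration and cardiac phase).
#' @param target_h_s output step (s); default 0.05 s gives >= 10 samples per
#'   cardiac cycle near 1 Hz.
#' @param subject_id,condition labels carried into the output.
#' @return a \code{phase_series}.
#' @export
align_phases <- function(phi1_series, phi2_series, target_h_s = 0.05,
                         subject_id = NA_character_,
                         condition = NA_character_) {
  v1 <- !is.na(phi1_series$phi); v2 <- !is.na(phi2_series$phi)
  if (!any(v1) || !any(v2)) stop("no valid samples in one of the phase series")
  r1 <- range(phi1_series$time_s[v1]); r2 <- range(phi2_series$time_s[v2])
  t0 <- max(r1[1], r2[1]); t1 <- min(r1[2], r2[2])
  if (t1 - t0 <= target_h_s) stop("phase series have no overlapping valid range")
  grid <- seq(t0, t1, by = target_h_s)
  p1 <- stats::approx(phi1_series$time_s[v1], phi1_series$phi[v1], xout = grid)$y
  p2 <- stats::approx(phi2_series$time_s[v2], phi2_series$phi[v2], xout = grid)$y
  new_phase_series(target_h_s, p1, p2, subject_id, condition, t0 = t0)
}

#' Estimate a phase series from rendered signals
#'
#' Convenience composition of [hilbert_phase()] (respiration), [event_phase()]
#' (cardiac, from the surrogate R-peaks) and [align_phases()].
#'
#' @param rec a \code{signal_record}.
#' @param resp_band respiration pass band (Hz).
#' @param target_h_s output sampling step (s).
#' @export
estimate_phases <- function(rec, resp_band = c(0.04, 0.6), target_h_s = 0.05) {
  stopifnot(inherits(rec, "signal_record"))
  p1 <- hilbert_phase(rec$resp, rec$fs_hz, resp_band)
  grid <- seq(0, max(rec$time_s), by = target_h_s)
  p2 <- event_phase(rec$rpeaks_s, grid)
  align_phases(p1, p2, target_h_s, rec$subject_id, rec$condition)
}
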