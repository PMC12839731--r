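#' Ground-truth stochastic phase model
#'
#' Specifies the generating model for a pair of weakly coupled phase
#' oscillators (oscillator 1 = respiration, oscillator 2 = cardiac):
#' \deqn{\dot\varphi_i = \omega_i + q_{i,j}(\varphi_i, \varphi_j) + \xi_i,}
#' with white Gaussian dynamic noise of intensity matrix
#' \eqn{\langle \xi_i(t)\xi_j(\tau)\rangle = \delta(t-\tau) E_{ij}}.
#' The respiration frequency \eqn{\omega_1(t)} is supplied at simulation time
#' by a protocol reference curve; \code{omega2_hz} is the cardiac base
#' frequency.
#'
#' @param omega2_hz cardiac base frequency in Hz (default 1.1).
#' @param coupling data frame with columns \code{osc} (1 or 2: which phase
#'   velocity the term enters), \code{k}, \code{s} (integer multipliers of
#'   phi1 and phi2), \code{kind} ("sin" or "cos") and \code{amp} (rad/s).
#'   Default: respiration modulates the cardiac phase via
#'   0.3 sin(phi1 - phi2), with a weak 0.05 sin(phi2 - phi1) back-coupling.
#' @param E_true symmetric positive-semidefinite 2x2 noise-intensity matrix
#'   (rad^2/s); default diag(0.05, 0.02).
#' @return object of class \code{ground_truth_model}.
#' @export
ground_truth_model <- function(omega2_hz = 1.1,
                               coupling = default_coupling(),
                               E_true = diag(c(0.05, 0.02))) {
  E_true <- (E_true + t(E_true)) / 2
  ev <- eigen(E_true, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("E_true must be positive semidefinite")
  stopifnot(omega2_hz > 0)
  if (nrow(coupling) > 0) {
    stopifnot(all(coupling$osc %in% c(1L, 2L)),
              all(coupling$kind %in% c("sin", "cos")))
  }
  structure(list(omega2_hz = omega2_hz, coupling = coupling, E_true = E_true),
            class = "ground_truth_model")
}

#' Default coupling ground truth
#'
#' Respiration-to-cardiac coupling 0.3 sin(phi1 - phi2) (the dominant,
#' RSA-like direction) and a weak cardiac-to-respiration term
#' 0.05 sin(phi2 - phi1).
#' @param amp21 amplitude (rad/s) of the respiration-to-cardiac term.
#' @param amp12 amplitude (rad/s) of the cardiac-to-respiration term.
#' @export
default_coupling <- function(amp21 = 0.3, amp12 = 0.05) {
  data.frame(osc = c(2L, 1L), k = c(1L, 1L), s = c(-1L, -1L),
             kind = c("sin", "sin"), amp = c(amp21, -amp12))
}

new_phase_series <- function(h_s, phi1, phi2, subject_id = NA_character_,
                             condition = NA_character_, t0 = 0) {
  stopifnot(h_s > 0, length(phi1) == length(phi2))
  structure(list(h_s = h_s, t0 = t0, phi1 = phi1, phi2 = phi2,
                 subject_id = subject_id, condition = condition),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat("Phase series:", length(x$phi1), "samples at h =", x$h_s, "s (",
      round(length(x$phi1) * x$h_s, 1), "s )\n")
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id,
                                " condition:", x$condition, "\n")
  invisible(x)
}

#' Time axis of a phase series
#' @param phases a \code{phase_series}.
#' @export
phase_times <- function(phases) {
  phases$t0 + (seq_along(phases$phi1) - 1) * phases$h_s
}

#' Simulate coupled stochastic phase dynamics (Euler-Maruyama)
#'
#' Integrates the two-oscillator stochastic phase model with the
#' Euler-Maruyama scheme: per step of length h the noise increment is jointly
#' Gaussian with covariance \code{E_true * h} (matrix square root of E_true
#' applied to independent standard normals). The respiration frequency
#' follows \code{2*pi} times the protocol reference curve.
#'
#' @param truth a [ground_truth_model()].
#' @param protocol a \code{frequency_trace} giving the respiration frequency.
#' @param duration_s simulated duration; defaults to the protocol's span.
#' @param h_s integration step (s); \code{h_s * f_max} must be < 0.1.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param phi0 initial phases (rad).
#' @param subject_id,condition labels carried into the output.
#' @return a \code{phase_series} with unwrapped phases phi1 (respiration) and
#'   phi2 (cardiac).
#' @export
simulate_coupled_phases <- function(truth, protocol, duration_s = NULL,
                                    h_s = 0.01, seed = 1, phi0 = c(0, 0),
                                    subject_id = NA_character_,
                                    condition = NA_character_) {
  stopifnot(inherits(truth, "ground_truth_model"),
            inherits(protocol, "frequency_trace"))
  duration_s <- duration_s %||% max(protocol$time_s)
  if (max(protocol$time_s) < duration_s - 1e-9) {
    stop("protocol (", max(protocol$time_s), " s) is shorter than duration_s (",
         duration_s, " s)")
  }
  f_max <- max(max(protocol$freq_hz), truth$omega2_hz)
  if (h_s * f_max >= 0.1) {
    stop("h_s too large: h_s * f_max = ", signif(h_s * f_max, 3), " >= 0.1")
  }
  n_steps <- floor(duration_s / h_s + 1e-9)
  t_steps <- (0:(n_steps - 1)) * h_s
  omega1 <- 2 * pi * stats::approx(protocol$time_s, protocol$freq_hz,
                                   xout = t_steps, rule = 2)$y
  omega2 <- 2 * pi * truth$omega2_hz
  A <- sqrtm_psd(truth$E_true)
  dW <- with_seed(seed, matrix(stats::rnorm(2 * n_steps), n_steps, 2)) %*%
    t(A) * sqrt(h_s)
  phi1 <- numeric(n_steps + 1); phi2 <- numeric(n_steps + 1)
  phi1[1] <- phi0[1]; phi2[1] <- phi0[2]
  # unpack coupling terms once; the integration loop stays scalar
  cpl <- truth$coupling
  c1 <- cpl[cpl$osc == 1L, , drop = FALSE]
  c2 <- cpl[cpl$osc == 2L, , drop = FALSE]
  k1 <- c1$k; s1 <- c1$s; a1 <- c1$amp; sin1 <- c1$kind == "sin"
  k2 <- c2$k; s2 <- c2$s; a2 <- c2$amp; sin2 <- c2$kind == "sin"
  for (n in seq_len(n_steps)) {
    p1 <- phi1[n]; p2 <- phi2[n]
    th1 <- k1 * p1 + s1 * p2
    th2 <- k2 * p1 + s2 * p2
    q1 <- sum(a1 * ifelse(sin1, sin(th1), cos(th1)))
    q2 <- sum(a2 * ifelse(sin2, sin(th2), cos(th2)))
    phi1[n + 1] <- p1 + (omega1[n] + q1) * h_s + dW[n, 1]
    phi2[n + 1] <- p2 + (omega2 + q2) * h_s + dW[n, 2]
  }
  new_phase_series(h_s, phi1, phi2, subject_id, condition)
}

#' Render surrogate respiration and cardiac-event signals from phases
#'
#' Respiration waveform is cos(phi1); the cardiac channel is emitted both as
#' an impulse-train waveform and as the list of times where phi2 crosses
#' multiples of 2*pi (surrogate R-peaks). These take the place of measured
#' chest-circumference and ECG recordings.
#'
#' @param phases a \code{phase_series}.
#' @param fs_hz output waveform sampling rate; must be at least twice the
#'   maximum instantaneous cardiac frequency.
#' @param am_depth optional slow amplitude modulation depth of the
#'   respiration waveform (0 = pure cosine).
#' @return a \code{signal_record}: list with fields \code{fs_hz},
#'   \code{time_s}, \code{resp}, \code{ecg} (impulse train),
#'   \code{rpeaks_s}, \code{subject_id}, \code{condition}.
#' @export
render_signals <- function(phases, fs_hz = 10, am_depth = 0) {
  stopifnot(inherits(phases, "phase_series"))
  n <- length(phases$phi1)
  if (n < 2) stop("phases must contain at least two samples")
  t_in <- phase_times(phases)
  f2_max <- max(diff(phases$phi2)) / phases$h_s / (2 * pi)
  if (fs_hz < 2 * f2_max) {
    stop("fs_hz = ", fs_hz, " below twice the maximum cardiac frequency (",
         signif(f2_max, 3), " Hz)")
  }
  t_out <- seq(0, t_in[n], by = 1 / fs_hz)
  phi1_o <- stats::approx(t_in, phases$phi1, xout = t_out)$y
  resp <- cos(phi1_o)
  if (am_depth > 0) resp <- resp * (1 + am_depth * cos(2 * pi * 0.01 * t_out))
  # surrogate R-peaks: upward crossings of phi2 through multiples of 2*pi
  phi2_m <- cummax(phases$phi2) # monotone envelope for crossing inversion
  lev <- seq(2 * pi * ceiling(phi2_m[1] / (2 * pi) + 1e-12),
             phi2_m[n], by = 2 * pi)
  rpeaks <- if (length(lev)) stats::approx(phi2_m, t_in, xout = lev,
                                           ties = "ordered")$y else numeric(0)
  ecg <- numeric(length(t_out))
  if (length(rpeaks)) {
    idx <- pmin(pmax(round(rpeaks * fs_hz) + 1, 1), length(t_out))
    ecg[idx] <- 1
  }
  structure(list(fs_hz = fs_hz, time_s = t_out, resp = resp, ecg = ecg,
                 rpeaks_s = rpeaks, subject_id = phases$subject_id,
                 condition = phases$condition),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat("Signal record:", length(x$resp), "samples at", x$fs_hz, "Hz,",
      length(x$rpeaks_s), "surrogate R-peaks\n")
  invisible(x)
}

jitter_truth <- function(template, jitter, seed) {
  with_seed(seed, {
    omega2 <- template$omega2_hz * exp((jitter$omega2 %||% 0) * stats::rnorm(1))
    cpl <- template$coupling
    if (nrow(cpl) > 0) {
      cpl$amp <- cpl$amp * exp((jitter$coupling %||% 0) * stats::rnorm(nrow(cpl)))
    }
    E <- template$E_true
    g <- exp((jitter$E %||% 0) * stats::rnorm(2))
    D <- diag(sqrt(g))
    E <- D %*% E %*% D # keeps PSD, scales diagonals by g, E12 by sqrt(g1 g2)
    ground_truth_model(omega2_hz = omega2, coupling = cpl, E_true = E)
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' Emulates the study design: \code{n_subjects} subjects, each recorded under
#' each breathing condition (free 30 min, others 20 min, scalable by a single
#' duration factor). Subject-level physiology (cardiac frequency, coupling
#' amplitudes, noise intensities) is jittered log-normally around the
#' template; controlled-protocol reference curves are shared across subjects
#' while free breathing is drawn per subject. The full ground truth is stored
#' beside each record.
#'
#' @param n_subjects number of subjects (default 20, the study size).
#' @param conditions character vector of protocol kinds.
#' @param truth_template a [ground_truth_model()] around which subjects vary.
#' @param between_subject_jitter list of log-normal jitter scales:
#'   \code{omega2}, \code{coupling}, \code{E} (defaults 0.05, 0.1, 0.1).
#' @param seed master seed; the whole cohort is deterministic given it.
#' @param duration_scale single factor scaling all record durations.
#' @param h_s integration step (s).
#' @param condition_E11 optional named numeric: condition-specific respiration
#'   noise intensity E11 (rad^2/s) overriding the template, for experiments
#'   with condition-dependent dynamic noise.
#' @return a \code{phase_cohort}: list with \code{records} (each holding
#'   \code{phases}, \code{truth}, \code{protocol}), the call parameters and
#'   the master seed.
#' @export
make_cohort <- function(n_subjects = 20,
                        conditions = c("free", "ramp", "sine", "aperiodic"),
                        truth_template = ground_truth_model(),
                        between_subject_jitter = list(omega2 = 0.05,
                                                      coupling = 0.1, E = 0.1),
                        seed = 1, duration_scale = 1, h_s = 0.01,
                        condition_E11 = NULL) {
  stopifnot(n_subjects >= 1, length(conditions) >= 1)
  shared_protocols <- list()
  for (cond in setdiff(conditions, "free")) {
    dur <- 1200 * duration_scale
    prm <- if (cond == "ramp" && duration_scale < 1) {
      list(baseline_s = 60 * duration_scale, ramp_s = 510 * duration_scale,
           seed = derive_seed(seed, 7, match(cond, conditions)))
    } else if (cond == "ramp") {
      list(seed = derive_seed(seed, 7, match(cond, conditions)))
    } else if (cond == "aperiodic" && duration_scale < 1) {
      # keep the pace of the chaotic modulation, not its span
      list()
    } else list()
    shared_protocols[[cond]] <- make_protocol(
      protocol_spec(cond, duration_s = dur, params = prm))
  }
  records <- list()
  for (s in seq_len(n_subjects)) {
    truth_s <- jitter_truth(truth_template, between_subject_jitter,
                            derive_seed(seed, s, 0))
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      truth_sc <- truth_s
      if (!is.null(condition_E11) && cond %in% names(condition_E11)) {
        E <- truth_sc$E_true
        scale11 <- condition_E11[[cond]] / truth_template$E_true[1, 1]
        E[1, 1] <- E[1, 1] * scale11
        E[1, 2] <- E[2, 1] <- E[1, 2] * sqrt(scale11)
        truth_sc <- ground_truth_model(truth_sc$omega2_hz, truth_sc$coupling, E)
      }
      protocol <- if (cond == "free") {
        make_protocol(protocol_spec("free", duration_s = 1800 * duration_scale,
                                    params = list(seed = derive_seed(seed, s, ci, 1))))
      } else shared_protocols[[cond]]
      phases <- simulate_coupled_phases(
        truth_sc, protocol, h_s = h_s,
        seed = derive_seed(seed, s, ci, 2),
        subject_id = sprintf("S%02d", s), condition = cond)
      records[[length(records) + 1]] <- list(
        subject_id = sprintf("S%02d", s), condition = cond,
        phases = phases, truth = truth_sc, protocol = protocol)
    }
  }
  structure(list(records = records, seed = seed, n_subjects = n_subjects,
                 conditions = conditions, duration_scale = duration_scale,
                 h_s = h_s, jitter = between_subject_jitter),
            class = "phase_cohort")
}

#' @export
print.phase_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$n_subjects, "subjects x",
      length(x$conditions), "conditions =", length(x$records), "records",
      "(duration scale", x$duration_scale, ")\n")
  invisible(x)
}
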