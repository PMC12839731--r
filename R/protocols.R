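#' Breathing-protocol specification
#'
#' Describes one of the four paced-breathing conditions of the study design:
#' \describe{
#'   \item{free}{spontaneous breathing; a slowly drifting bounded random
#'     frequency around a configurable mean (default 0.25 Hz, 30 min).}
#'   \item{ramp}{1 min free baseline, 8.5 min linear increase from
#'     \code{f_min} = 0.08 Hz to \code{f_max} = 0.4 Hz, 1 min free baseline,
#'     8.5 min linear decrease back to 0.08 Hz (20 min nominal).}
#'   \item{sine}{frequency follows \code{f_base + f_amp * sin(2*pi*t/period_s)},
#'     defaults 0.3 + 0.2 sin(2 pi t / 400) Hz.}
#'   \item{aperiodic}{frequency follows the z-component of a chaotic Lorenz
#'     trajectory mapped affinely into a frequency band (default
#'     \[0.08, 0.4\] Hz).}
#' }
#'
#' @param kind one of "free", "ramp", "sine", "aperiodic".
#' @param duration_s total duration in seconds; defaults to the study design
#'   (1800 s free, 1200 s otherwise).
#' @param dt_s sampling step of the reference curve in seconds.
#' @param params named list overriding kind-specific defaults (see Details).
#'
#' @details Kind-specific parameters and defaults:
#' free: \code{mean_hz} 0.25, \code{sd_hz} 0.03, \code{tau_s} 60 (drift time
#' constant), \code{min_hz} 0.1, \code{max_hz} 0.4, \code{seed} 1.
#' ramp: \code{f_min} 0.08, \code{f_max} 0.4, \code{baseline_s} 60,
#' \code{ramp_s} 510, \code{sd_hz} 0.015, \code{tau_s} 30, \code{seed} 1
#' (free-baseline filler; pinned to the adjoining ramp endpoints so the curve
#' has no jumps).
#' sine: \code{f_base} 0.3, \code{f_amp} 0.2, \code{period_s} 400.
#' aperiodic: \code{sigma} 10, \code{rho} 28, \code{beta} 8/3 (classic chaotic
#' Lorenz set), \code{band_hz} c(0.08, 0.4), \code{time_scale_s} 60 (seconds of
#' real time per Lorenz time unit), \code{lorenz_dt} 0.005,
#' \code{transient} 10, \code{init} c(1, 1, 20).
#'
#' @return an object of class \code{protocol_spec}.
#' @export
protocol_spec <- function(kind = c("free", "ramp", "sine", "aperiodic"),
                          duration_s = NULL, dt_s = 0.1, params = list()) {
  kind <- match.arg(kind)
  duration_s <- duration_s %||% if (kind == "free") 1800 else 1200
  stopifnot(duration_s > 0, dt_s > 0)
  defaults <- switch(kind,
    free = list(mean_hz = 0.25, sd_hz = 0.03, tau_s = 60,
                min_hz = 0.1, max_hz = 0.4, seed = 1L),
    ramp = list(f_min = 0.08, f_max = 0.4, baseline_s = 60, ramp_s = 510,
                sd_hz = 0.015, tau_s = 30, seed = 1L),
    sine = list(f_base = 0.3, f_amp = 0.2, period_s = 400),
    aperiodic = list(sigma = 10, rho = 28, beta = 8 / 3,
                     band_hz = c(0.08, 0.4), time_scale_s = 60,
                     lorenz_dt = 0.005, transient = 10, init = c(1, 1, 20))
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown ", kind, " parameters: ",
                            paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  if (kind == "ramp") {
    if (p$f_min >= p$f_max) stop("ramp requires f_min < f_max")
    if (2 * p$baseline_s + 2 * p$ramp_s > duration_s + 1e-9) {
      stop("ramp segments (", 2 * p$baseline_s + 2 * p$ramp_s,
           " s) exceed duration_s (", duration_s, " s)")
    }
    stopifnot(p$f_min > 0)
  }
  if (kind == "sine") {
    stopifnot(p$f_base > 0, p$f_amp >= 0, p$period_s > 0)
    if (p$f_amp >= p$f_base) stop("sine f_amp must be < f_base (frequencies must stay positive)")
  }
  if (kind == "free") stopifnot(p$mean_hz > 0, p$min_hz > 0, p$max_hz > p$min_hz)
  if (kind == "aperiodic") stopifnot(all(p$band_hz > 0), p$band_hz[1] < p$band_hz[2])
  structure(list(kind = kind, duration_s = duration_s, dt_s = dt_s, params = p),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Breathing protocol:", x$kind, "-", x$duration_s, "s at dt =", x$dt_s, "s\n")
  invisible(x)
}

new_frequency_trace <- function(time_s, freq_hz) {
  stopifnot(length(time_s) == length(freq_hz), all(diff(time_s) > 0),
            all(freq_hz > 0))
  structure(data.frame(time_s = time_s, freq_hz = freq_hz),
            class = c("frequency_trace", "data.frame"))
}

# Ornstein-Uhlenbeck frequency drift, optionally pinned to start/end values
# via a linear bridge so segment boundaries are continuous.
ou_freq <- function(times, mean_hz, sd_hz, tau_s, seed,
                    pin_start = NULL, pin_end = NULL,
                    min_hz = 0.02, max_hz = Inf) {
  n <- length(times)
  if (n == 0) return(numeric(0))
  dt <- if (n > 1) diff(times)[1] else 0
  f <- numeric(n)
  with_seed(seed, {
    x <- 0 # deviation from the mean path
    for (i in seq_len(n)) {
      f[i] <- x
      if (i < n) x <- x - x * dt / tau_s + sd_hz * sqrt(2 * dt / tau_s) * stats::rnorm(1)
    }
  })
  base <- rep(mean_hz, n)
  if (!is.null(pin_start) || !is.null(pin_end)) {
    a <- pin_start %||% mean_hz
    b <- pin_end %||% mean_hz
    base <- a + (b - a) * (times - times[1]) / max(times[n] - times[1], 1e-12)
    # taper the random deviation to zero at pinned endpoints
    w <- rep(1, n)
    if (!is.null(pin_start)) w <- w * pmin(1, (times - times[1]) / max(tau_s, dt))
    if (!is.null(pin_end)) w <- w * pmin(1, (times[n] - times) / max(tau_s, dt))
    f <- f * w
  }
  pmin(pmax(base + f, min_hz), max_hz)
}

#' Generate a breathing-protocol reference frequency curve
#'
#' Evaluates the instantaneous-frequency law of the given protocol on its
#' sampling grid: the sine law \code{f_base + f_amp*sin(2*pi*t/period)}, the
#' piecewise-linear ramp between 0.08 and 0.4 Hz with free-baseline filler
#' minutes, an affinely band-mapped Lorenz z-trajectory, or a bounded
#' random drift for free breathing.
#'
#' @param spec a [protocol_spec()].
#' @return a \code{frequency_trace}: data frame with columns \code{time_s}
#'   and \code{freq_hz}. For ramp, the attribute \code{segments} marks the
#'   controlled (linear) portions.
#' @export
make_protocol <- function(spec) {
  if (!inherits(spec, "protocol_spec")) stop("spec must be a protocol_spec")
  t <- seq(0, spec$duration_s, by = spec$dt_s)
  p <- spec$params
  f <- switch(spec$kind,
    sine = p$f_base + p$f_amp * sin(2 * pi * t / p$period_s),
    free = ou_freq(t, p$mean_hz, p$sd_hz, p$tau_s, p$seed,
                   min_hz = p$min_hz, max_hz = p$max_hz),
    ramp = {
      b <- p$baseline_s; r <- p$ramp_s
      edges <- c(0, b, b + r, 2 * b + r, 2 * b + 2 * r)
      f <- numeric(length(t))
      seg <- findInterval(t, edges, rightmost.closed = FALSE)
      seg[t >= edges[5]] <- 5L
      in1 <- seg == 1; in2 <- seg == 2; in3 <- seg == 3; in4 <- seg == 4; in5 <- seg == 5
      f[in2] <- p$f_min + (p$f_max - p$f_min) * (t[in2] - edges[2]) / r
      f[in4] <- p$f_max - (p$f_max - p$f_min) * (t[in4] - edges[4]) / r
      f[in1] <- ou_freq(t[in1], p$f_min + 0.04, p$sd_hz, p$tau_s,
                        derive_seed(p$seed, 101), pin_end = p$f_min)
      f[in3] <- ou_freq(t[in3], p$f_max, p$sd_hz, p$tau_s,
                        derive_seed(p$seed, 102),
                        pin_start = p$f_max, pin_end = p$f_max)
      if (any(in5)) {
        f[in5] <- ou_freq(t[in5], p$f_min, p$sd_hz, p$tau_s,
                          derive_seed(p$seed, 103), pin_start = p$f_min)
      }
      attr(f, "segments") <- data.frame(
        segment = c("baseline1", "up", "baseline2", "down", "tail"),
        start_s = edges, end_s = c(edges[-1], spec$duration_s),
        controlled = c(FALSE, TRUE, FALSE, TRUE, FALSE)
      )
      f
    },
    aperiodic = {
      z <- lorenz_z(spec$duration_s, spec$dt_s,
                    params = c(sigma = p$sigma, rho = p$rho, beta = p$beta),
                    initial_state = p$init, time_scale = p$time_scale_s,
                    dt_lorenz = p$lorenz_dt, transient = p$transient)
      zr <- range(z)
      p$band_hz[1] + (z - zr[1]) / (zr[2] - zr[1]) * diff(p$band_hz)
    }
  )
  segments <- attr(f, "segments")
  out <- new_frequency_trace(t, as.numeric(f))
  if (!is.null(segments)) attr(out, "segments") <- segments
  out
}

#' Lorenz z-component trajectory
#'
#' Integrates the Lorenz system with a fixed-step RK4 scheme, discards an
#' initial transient, and returns the z-component resampled onto a real-time
#' grid after rescaling model time by \code{time_scale} (seconds of real time
#' per Lorenz time unit), so the chaotic modulation unfolds over tens of
#' seconds.
#'
#' @param duration_s real-time duration in seconds (0 gives an empty trajectory).
#' @param dt_s real-time output step in seconds.
#' @param params named vector with positive \code{sigma}, \code{rho}, \code{beta}.
#' @param initial_state numeric length-3 state (x, y, z).
#' @param time_scale seconds of real time per Lorenz model-time unit.
#' @param dt_lorenz fixed integration step in model-time units.
#' @param transient model-time units discarded before the output window.
#' @return numeric vector of z values at \code{seq(0, duration_s, dt_s)}.
#' @export
lorenz_z <- function(duration_s, dt_s, params = c(sigma = 10, rho = 28, beta = 8 / 3),
                     initial_state = c(1, 1, 20), time_scale = 60,
                     dt_lorenz = 0.005, transient = 10) {
  stopifnot(all(params > 0), dt_s > 0, time_scale > 0, dt_lorenz > 0)
  if (duration_s <= 0) return(numeric(0))
  t_out <- seq(0, duration_s, by = dt_s)
  t_model_end <- transient + duration_s / time_scale
  deriv <- function(t, y, p) {
    list(c(p["sigma"] * (y[2] - y[1]),
           y[1] * (p["rho"] - y[3]) - y[2],
           y[1] * y[2] - p["beta"] * y[3]))
  }
  grid <- seq(0, t_model_end + dt_lorenz, by = dt_lorenz)
  sol <- deSolve::ode(y = initial_state, times = grid, func = deriv,
                      parms = params, method = "rk4")
  z <- sol[, 4]
  if (any(!is.finite(z))) {
    stop("Lorenz integration blew up at step dt_lorenz = ", dt_lorenz,
         "; reduce the step size")
  }
  stats::approx(x = (grid - transient) * time_scale, y = z, xout = t_out)$y
}
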