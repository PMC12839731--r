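# Shared fixtures: small deterministic simulations used across test files.

# constant-frequency reference trace
const_trace <- function(f_hz, duration_s) {
  phasenoise:::new_frequency_trace(c(0, duration_s), rep(f_hz, 2))
}

# stationary two-oscillator simulation subsampled to the inference step
sim_stationary <- function(seed, duration_s = 300, f1 = 0.25, omega2_hz = 1.1,
                           amp21 = 0.3, E = diag(c(0.05, 0.02)),
                           h_sim = 0.01, h_inf = 0.05) {
  tru <- ground_truth_model(
    omega2_hz = omega2_hz,
    coupling = data.frame(osc = 2L, k = 1L, s = -1L, kind = "sin", amp = amp21),
    E_true = E)
  sim <- simulate_coupled_phases(tru, const_trace(f1, duration_s),
                                 duration_s = duration_s, h_s = h_sim,
                                 seed = seed)
  idx <- seq(1, length(sim$phi1), by = round(h_inf / h_sim))
  phasenoise:::new_phase_series(h_inf, sim$phi1[idx], sim$phi2[idx])
}

# nearest grid index of a frequency on a log grid
nearest_bin <- function(grid, f) {
  vapply(f, function(ff) which.min(abs(log(grid) - log(ff))), integer(1))
}

wrap_pi <- function(d) atan2(sin(d), cos(d))
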