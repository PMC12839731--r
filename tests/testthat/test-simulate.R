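test_that("noise-free uncoupled phases grow exactly linearly", {
  tru <- ground_truth_model(omega2_hz = 1.1,
                            coupling = default_coupling(0, 0),
                            E_true = matrix(0, 2, 2))
  ph <- simulate_coupled_phases(tru, const_trace(0.3, 100),
                                duration_s = 100, h_s = 0.01, seed = 1)
  t <- phase_times(ph)
  expect_equal(ph$phi1, 2 * pi * 0.3 * t, tolerance = 1e-10)
  expect_equal(ph$phi2, 2 * pi * 1.1 * t, tolerance = 1e-10)
})

test_that("Euler-Maruyama increment variance matches E_true * h", {
  h <- 0.01
  tru <- ground_truth_model(coupling = default_coupling(0, 0),
                            E_true = diag(c(0.04, 0.01)))
  ph <- simulate_coupled_phases(tru, const_trace(0.3, 1000),
                                duration_s = 1000, h_s = h, seed = 3)
  v1 <- stats::var(diff(ph$phi1) - 2 * pi * 0.3 * h) / h
  v2 <- stats::var(diff(ph$phi2) - 2 * pi * 1.1 * h) / h
  expect_lt(abs(v1 / 0.04 - 1), 0.05) # 1e5 steps, < 5% relative
  expect_lt(abs(v2 / 0.01 - 1), 0.05)
})

test_that("deterministic sin coupling with small detuning locks the phases", {
  tru <- ground_truth_model(
    omega2_hz = 1.03,
    coupling = data.frame(osc = 1L, k = 1L, s = -1L, kind = "sin", amp = -0.5),
    E_true = matrix(0, 2, 2)) # dphi1 gets 0.5*sin(phi2 - phi1)
  ph <- simulate_coupled_phases(tru, const_trace(1.0, 200),
                                duration_s = 200, h_s = 0.005, seed = 1)
  d <- ph$phi2 - ph$phi1
  tail_d <- d[seq(round(length(d) / 2), length(d))]
  expect_lt(diff(range(tail_d)), 0.5) # bounded phase difference
})

test_that("simulation rejects invalid inputs and is seed-reproducible", {
  tru <- ground_truth_model()
  expect_error(simulate_coupled_phases(tru, const_trace(0.3, 50),
                                       duration_s = 100), "shorter")
  badE <- matrix(c(1, 2, 2, 1), 2, 2) # eigenvalues 3, -1
  expect_error(ground_truth_model(E_true = badE), "semidefinite")
  expect_error(simulate_coupled_phases(tru, const_trace(0.3, 100),
                                       duration_s = 100, h_s = 0.2), "h_s")
  a <- simulate_coupled_phases(tru, const_trace(0.3, 60), h_s = 0.01, seed = 9)
  b <- simulate_coupled_phases(tru, const_trace(0.3, 60), h_s = 0.01, seed = 9)
  expect_identical(a$phi1, b$phi1)
})

test_that("surrogate R-peaks of a 1 Hz cardiac phase are spaced 1.0 s", {
  tru <- ground_truth_model(omega2_hz = 1.0, coupling = default_coupling(0, 0),
                            E_true = matrix(0, 2, 2))
  ph <- simulate_coupled_phases(tru, const_trace(0.3, 10.0001),
                                duration_s = 10.0001, h_s = 0.001, seed = 1)
  sig <- render_signals(ph, fs_hz = 20)
  expect_length(sig$rpeaks_s, 10)
  expect_equal(diff(sig$rpeaks_s), rep(1, 9), tolerance = 1e-6)
  expect_error(render_signals(phasenoise:::new_phase_series(0.01, 1, 1)),
               "two samples")
})

test_that("hilbert phase round-trips through the rendered respiration waveform", {
  tru <- ground_truth_model(coupling = default_coupling(0, 0),
                            E_true = matrix(0, 2, 2))
  prot <- make_protocol(protocol_spec("sine", duration_s = 400))
  ph <- simulate_coupled_phases(tru, prot, h_s = 0.01, seed = 5)
  sig <- render_signals(ph, fs_hz = 10)
  est <- hilbert_phase(sig$resp, sig$fs_hz, c(0.04, 0.6))
  truth <- stats::approx(phase_times(ph), ph$phi1, xout = est$time_s)$y
  n <- length(truth)
  core <- seq(round(0.1 * n), round(0.9 * n))
  expect_lt(max(abs(wrap_pi(est$phi - truth))[core]), 0.1)
})

test_that("cohorts honour the study layout and the master seed", {
  tmpl <- ground_truth_model()
  one <- make_cohort(1, "sine", tmpl,
                     between_subject_jitter = list(omega2 = 0, coupling = 0, E = 0),
                     seed = 2, duration_scale = 0.05)
  expect_equal(one$records[[1]]$truth$omega2_hz, tmpl$omega2_hz)
  expect_equal(one$records[[1]]$truth$E_true, tmpl$E_true)

  co <- make_cohort(20, c("free", "ramp", "sine", "aperiodic"), tmpl,
                    seed = 3, duration_scale = 0.02)
  expect_length(co$records, 80)
  ids <- sapply(co$records, function(r) paste(r$subject_id, r$condition))
  expect_equal(anyDuplicated(ids), 0L)
  # records genuinely differ across subjects
  p1 <- co$records[[1]]$phases$phi1
  p2 <- co$records[[5]]$phases$phi1
  expect_false(identical(p1, p2))

  co2 <- make_cohort(20, c("free", "ramp", "sine", "aperiodic"), tmpl,
                     seed = 3, duration_scale = 0.02)
  expect_identical(co$records[[17]]$phases, co2$records[[17]]$phases)
})

test_that("condition-specific E11 overrides rescale only the respiration noise", {
  tmpl <- ground_truth_model(E_true = diag(c(0.05, 0.02)))
  co <- make_cohort(1, c("ramp", "sine"), tmpl,
                    between_subject_jitter = list(omega2 = 0, coupling = 0, E = 0),
                    seed = 1, duration_scale = 0.02,
                    condition_E11 = c(sine = 0.01))
  Es <- lapply(co$records, function(r) r$truth$E_true)
  names(Es) <- sapply(co$records, `[[`, "condition")
  expect_equal(Es$ramp[1, 1], 0.05)
  expect_equal(Es$sine[1, 1], 0.01)
  expect_equal(Es$ramp[2, 2], Es$sine[2, 2])
})
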