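# phasenoise

Inference of **dynamic physiological noise** in weakly coupled biological
oscillators with time-varying deterministic dynamics, applied to the
cardio-respiratory system under paced breathing.

Dynamic noise acts *inside* the equations of motion — as opposed to
measurement noise added to the recorded signal — and shapes how an
oscillator responds to perturbation. This package asks, on synthetic
cohorts with known ground truth: when a subject's breathing frequency is
driven along a prescribed time-varying profile (free, linear ramp, sine,
or chaotic aperiodic pacing), how much stochastic forcing remains in the
respiratory and cardiac phase dynamics once the deterministic
time-variability is tracked, and does it differ between pacing patterns?

## Model

Each oscillator is phase-reduced,

```
dφ_i/dt = ω_i + q_{i,j}(φ_i, φ_j) + ξ_i(t),      i ∈ {1 = respiration, 2 = cardiac},
⟨ξ_i(t) ξ_j(τ)⟩ = δ(t−τ) E_ij,
```

with the coupling functions `q` expanded in a sin/cos Fourier basis on the
torus truncated at order K = 2 and the symmetric 2×2 matrix `E` carrying
the noise intensities (E11 respiration, E22 cardiac, E12 = E21 their
correlation). The model is inferred window-by-window by dynamical Bayesian
inference: within each window the Gaussian posterior over the coefficient
vector and the stationary noise matrix is found by closed-form recursive
updates of the minus log-likelihood

```
S = (L/2) ln|E| + (h/2) Σ_l [ c_k ∂Φ_k/∂φ + (φ̇_l − cΦ(φ*_l))ᵀ E⁻¹ (φ̇_l − cΦ(φ*_l)) ],
```

and between windows the posterior is propagated into the next prior with a
diffusion covariance `diag((p_w c_i)²)`, so the deterministic part may
drift. The window length `t_w` and propagation fraction `p_w` are selected
by prequential (one-step-ahead, pre-update) prediction error.

Around this core the package provides the complete study pipeline:
breathing-protocol reference curves (including `f = 0.3 + 0.2 sin(2πt/400)`
Hz sine pacing, the 0.08–0.4 Hz ramp, and Lorenz-driven aperiodic pacing),
an Euler–Maruyama simulator for cohorts with known truth, Morlet wavelet
transform and penalized ridge extraction for protocol verification,
analytic-signal and R-peak phase estimation, and Holm–Bonferroni-corrected
paired group comparisons of the noise statistics.

## Worked example

Simulate one subject paced by the sine protocol, infer the windowed model,
and summarise the noise trajectories:

```r
library(phasenoise)

prot  <- make_protocol(protocol_spec("sine", duration_s = 800))
truth <- ground_truth_model()          # ω2 = 1.1 Hz, E = diag(0.05, 0.02)
sim   <- simulate_coupled_phases(truth, prot, h_s = 0.01, seed = 11)

idx <- seq(1, length(sim$phi1), by = 5)        # inference step h = 0.05 s
ph  <- phasenoise:::new_phase_series(0.05, sim$phi1[idx], sim$phi2[idx])
run <- run_inference(ph, t_w_s = 30, propagation_spec(0.2), build_basis(2))
run
#> Inference run: 26 windows of 30 s, p_w = 0.2 , K = 2
#>   prequential MSE: 0.7834

head(run$table[, c("window_index", "omega1_rad_s", "omega2_rad_s", "E11", "E12", "E22")], 4)
#>   window_index omega1_rad_s omega2_rad_s        E11           E12        E22
#> 1            1     2.204897     6.908095 0.04825223 -0.0008503659 0.01787992
#> 2            2     2.720356     6.943098 0.04679093 -0.0017333467 0.02005760
#> 3            3     3.044961     6.939596 0.05135161 -0.0009166144 0.01960192
#> 4            4     3.104767     6.951994 0.04687664 -0.0001989213 0.01961754

summarize_subject(noise_trajectories(run, "S01", "sine"))
#>   subject_id condition     std_E11     std_E12     std_E22 corr_E11_omega1
#> 1        S01      sine 0.003012276 0.001492143 0.001168435       0.3449573
#>   corr_E12_omega1 corr_E22_omega1 n_windows
#> 1       -0.314188      -0.4140171        26
```

Reading the output: `omega1_rad_s` tracks the imposed sine modulation
(window 1 centre: 2.20 rad/s ≈ 0.35 Hz, rising toward the 0.5 Hz crest);
`omega2_rad_s` stays near 2π·1.1 = 6.91 rad/s; the inferred noise
intensities hover around their true values 0.05, 0, 0.02 rad²/s. The
per-subject summary (std over windows of each component, and its Spearman
correlation with the inferred breathing frequency) is the unit of the
group statistics.

The cohort-level analysis — 20 subjects × 4 conditions, protocol-following
verification by wavelet ridge, inference on estimated phases, and
Holm-corrected pairwise condition contrasts — lives in the numbered
scripts under `analysis/` (run them in order; outputs land in
`results/analysis/`).

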