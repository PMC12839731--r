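test_that("basis enumeration matches the truncated Fourier grid", {
  b1 <- build_basis(1)
  expect_equal(b1$M, 18) # 9 per oscillator: const + sin/cos over 4 pairs
  b2 <- build_basis(2)
  expect_equal(b2$M, 50) # 25 per oscillator: const + sin/cos over 12 pairs
  expect_error(build_basis(0), "K")
  # no duplicate (osc, k, s, kind) entries
  key <- with(b2$terms, paste(osc, k, s, kind))
  expect_equal(anyDuplicated(key), 0L)
  # the constant term evaluates to 1 at any phases
  P <- phasenoise:::eval_basis(b1, 1L, c(0.3, 5), c(1, 2))
  expect_equal(unname(P[, 1]), c(1, 1))
})

test_that("minus log-likelihood has its closed form and truth-favouring shape", {
  b1 <- build_basis(1)
  # c = 0, constant phases: residuals and Jacobian identically zero, E = I
  win0 <- list(phi1 = rep(1, 51), phi2 = rep(2, 51), h_s = 0.05)
  expect_equal(neg_log_likelihood(numeric(b1$M), diag(2), win0, b1), 0)

  tru <- ground_truth_model(
    coupling = data.frame(osc = 2L, k = 1L, s = -1L, kind = "sin", amp = 0.3),
    E_true = diag(c(0.05, 0.02)))
  sim <- simulate_coupled_phases(tru, const_trace(0.25, 120),
                                 duration_s = 120, h_s = 0.05, seed = 21)
  win <- list(phi1 = sim$phi1, phi2 = sim$phi2, h_s = 0.05)
  c_true <- numeric(b1$M)
  names(c_true) <- b1$terms$name
  c_true["c1_const"] <- 2 * pi * 0.25
  c_true["c2_const"] <- 2 * pi * 1.1
  c_true["c2_sin_1_-1"] <- 0.3
  S_true <- neg_log_likelihood(c_true, tru$E_true, win, b1)
  S_pert <- neg_log_likelihood(1.5 * c_true, tru$E_true, win, b1)
  expect_lt(S_true, S_pert)
  expect_error(neg_log_likelihood(c_true, matrix(0, 2, 2), win, b1),
               "positive definite")
})

test_that("the recursive fixed point is a stationary point of S", {
  b1 <- build_basis(1)
  ph <- sim_stationary(31, duration_s = 60, h_sim = 0.01, h_inf = 0.05)
  win <- list(phi1 = ph$phi1, phi2 = ph$phi2, h_s = 0.05)
  post <- infer_window(win, basis = b1, tol = 1e-12, max_iter = 500)
  # numeric gradient of S w.r.t. c at the converged coefficients, holding E
  # at its stationary value, must vanish
  g <- vapply(seq_len(b1$M), function(j) {
    e <- numeric(b1$M); e[j] <- 1e-6
    (neg_log_likelihood(post$c_mean + e, post$E, win, b1) -
       neg_log_likelihood(post$c_mean - e, post$E, win, b1)) / 2e-6
  }, numeric(1))
  S0 <- abs(neg_log_likelihood(post$c_mean, post$E, win, b1))
  expect_lt(max(abs(g)), 1e-4 * max(S0, 1))
})

test_that("noise-free uncoupled phases are recovered exactly in the basis", {
  b2 <- build_basis(2)
  h <- 0.05; t <- seq(0, 60, by = h)
  post <- infer_window(list(phi1 = 2 * pi * 0.3 * t, phi2 = 2 * pi * 1.1 * t,
                            h_s = h), basis = b2)
  expect_lt(abs(post$c_mean[["c1_const"]] / (2 * pi * 0.3) - 1), 1e-3)
  expect_lt(abs(post$c_mean[["c2_const"]] / (2 * pi * 1.1) - 1), 1e-3)
  cpl <- post$c_mean[!grepl("const", names(post$c_mean))]
  expect_lt(max(abs(cpl)), 0.05)
  expect_lt(max(abs(post$E)), 1e-4)
})

test_that("an infinitely concentrated zero prior reduces E to the increment form", {
  b1 <- build_basis(1)
  set.seed(41)
  h <- 0.05; L <- 1500
  phi1 <- c(0, cumsum(stats::rnorm(L, 0, sqrt(0.04 * h))))
  phi2 <- c(0, cumsum(stats::rnorm(L, 0, sqrt(0.02 * h))))
  post <- infer_window(list(phi1 = phi1, phi2 = phi2, h_s = h),
                       prior_mean = numeric(b1$M),
                       prior_Xi = diag(1e14, b1$M), basis = b1)
  expect_equal(post$E[1, 1], (h / L) * sum((diff(phi1) / h)^2),
               tolerance = 1e-6)
  expect_equal(post$E[2, 2], (h / L) * sum((diff(phi2) / h)^2),
               tolerance = 1e-6)
})

test_that("inferred E is symmetric PSD across random noisy windows", {
  b1 <- build_basis(1)
  for (i in 1:5) {
    ph <- sim_stationary(50 + i, duration_s = 40,
                         E = matrix(c(0.05, 0.01, 0.01, 0.02), 2, 2))
    post <- infer_window(list(phi1 = ph$phi1, phi2 = ph$phi2, h_s = ph$h_s),
                         basis = b1)
    expect_identical(post$E, t(post$E))
    expect_gte(min(eigen(post$E, symmetric = TRUE)$values), 0)
  }
})

test_that("prior propagation adds exactly the diffusion diagonal", {
  ph <- sim_stationary(61, duration_s = 60)
  post <- infer_window(list(phi1 = ph$phi1, phi2 = ph$phi2, h_s = ph$h_s),
                       basis = build_basis(1))
  pr0 <- propagate_prior(post, propagation_spec(0))
  Sig_post <- unname(solve(post$Xi))
  expect_equal(unname(solve(pr0$Xi)), Sig_post, tolerance = 1e-8)
  expect_equal(pr0$mean, post$c_mean)

  # p_w = 0.2 with unit coefficients: prior covariance = posterior + 0.04 I
  post1 <- post
  post1$c_mean <- rep(1, length(post$c_mean))
  pr <- propagate_prior(post1, propagation_spec(0.2))
  expect_equal(unname(solve(pr$Xi)), Sig_post + diag(0.04, nrow(Sig_post)),
               tolerance = 1e-8)
  # added diffusion is PSD for any p_w >= 0
  dS <- unname(solve(pr$Xi)) - Sig_post
  expect_gte(min(eigen((dS + t(dS)) / 2, symmetric = TRUE)$values), -1e-10)
})

test_that("sequential inference is stable and deterministic on stationary data", {
  b2 <- build_basis(2)
  ph <- sim_stationary(71, duration_s = 300)
  run <- run_inference(ph, 30, propagation_spec(0.1), b2)
  expect_equal(nrow(run$table), 10)
  w1 <- run$table$omega1_rad_s
  expect_lt(stats::sd(w1) / mean(w1), 0.03)
  run2 <- run_inference(ph, 30, propagation_spec(0.1), b2)
  expect_identical(run$table, run2$table)
  expect_error(run_inference(ph, 200), "fewer than 2 windows")
})

test_that("hyperparameter selection returns single-point grids and finite scores", {
  ph <- sim_stationary(81, duration_s = 150)
  opt <- optimize_hyperparams(ph, t_w_grid = 30, p_w_grid = 0.1,
                              basis = build_basis(1))
  expect_equal(opt$t_w_s, 30)
  expect_equal(opt$prop$p_w, 0.1)
  expect_true(all(is.finite(opt$diagnostics$criterion)))
})

test_that("coupling surfaces evaluate the non-constant terms on the torus", {
  b1 <- build_basis(1)
  post <- list(c_mean = stats::setNames(numeric(b1$M), b1$terms$name))
  zero <- coupling_surface(post, b1, 16)
  expect_equal(zero$q1, matrix(0, 16, 16))
  # single term c * sin(phi2 - phi1) on oscillator 1: in canonical form the
  # basis holds sin(phi1 - phi2), so its coefficient is -c
  post$c_mean[["c1_sin_1_-1"]] <- -0.4
  sf <- coupling_surface(post, b1, 32)
  expected <- outer(sf$phi, sf$phi, function(a, b) 0.4 * sin(b - a))
  expect_equal(sf$q1, expected, tolerance = 1e-12)
  expect_lt(abs(mean(sf$q1)), 1e-12) # zero grid mean, constant excluded
  expect_error(coupling_surface(post, b1, 4), "grid_n")
})
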