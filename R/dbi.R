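#' Prior-propagation specification for time-varying inference
#'
#' Between consecutive windows the parameter distribution is widened by a
#' diffusion covariance: the next prior covariance is the posterior
#' covariance plus \code{Sigma_diff}, with
#' \code{(Sigma_diff)_ii = (p_w * c_i)^2} and zero off-diagonal (each
#' parameter's diffusion standard deviation is a known fraction p_w of the
#' parameter itself, and changes are uncorrelated across parameters).
#'
#' @param p_w dimensionless propagation fraction (>= 0; 0 freezes the model
#'   into a static fit).
#' @param rho correlation convention for the diffusion matrix; only
#'   "identity" (uncorrelated changes) is implemented.
#' @export
propagation_spec <- function(p_w = 0.2, rho = "identity") {
  stopifnot(p_w >= 0, identical(rho, "identity"))
  structure(list(p_w = p_w, rho = rho), class = "propagation_spec")
}

# Shared per-window precomputation: forward-difference phase velocities,
# midpoint-evaluated basis matrices and the summed own-phase derivative.
window_design <- function(phi1, phi2, h_s, basis) {
  L <- length(phi1) - 1
  if (L < 1) stop("window too short")
  mid1 <- (phi1[-1] + phi1[-(L + 1)]) / 2
  mid2 <- (phi2[-1] + phi2[-(L + 1)]) / 2
  dphi <- cbind(diff(phi1), diff(phi2)) / h_s
  P1 <- eval_basis(basis, 1L, mid1, mid2)
  P2 <- eval_basis(basis, 2L, mid1, mid2)
  D1 <- eval_basis_deriv(basis, 1L, phi1[-(L + 1)], phi2[-(L + 1)])
  D2 <- eval_basis_deriv(basis, 2L, phi1[-(L + 1)], phi2[-(L + 1)])
  list(L = L, dphi = dphi, P1 = P1, P2 = P2,
       dsum = c(colSums(D1), colSums(D2)),
       m1 = ncol(P1), m2 = ncol(P2))
}

split_coef <- function(cvec, d) list(c1 = cvec[seq_len(d$m1)],
                                     c2 = cvec[d$m1 + seq_len(d$m2)])

residuals_dw <- function(cvec, d) {
  cc <- split_coef(cvec, d)
  d$dphi - cbind(d$P1 %*% cc$c1, d$P2 %*% cc$c2)
}

#' Minus log-likelihood of the stochastic phase model
#'
#' Evaluates
#' \deqn{S = \frac{L}{2}\ln|E| + \frac{h}{2}\sum_l \Big[ c_k
#'   \frac{\partial \Phi_k}{\partial \varphi}(\varphi_l) +
#'   (\dot\varphi_l - c\Phi(\varphi^*_l))^\top E^{-1}
#'   (\dot\varphi_l - c\Phi(\varphi^*_l)) \Big],}
#' with forward-difference phase velocities
#' \eqn{\dot\varphi_l = (\varphi_{l+1}-\varphi_l)/h} and the basis evaluated
#' at the midpoint \eqn{\varphi^*_l = (\varphi_l + \varphi_{l+1})/2}; the
#' Jacobian (own-phase derivative) term is evaluated at the left sample.
#'
#' @param c_vec stacked coefficient vector (oscillator 1 terms then
#'   oscillator 2 terms, basis order).
#' @param E symmetric positive-definite 2x2 noise matrix (rad^2/s).
#' @param phases a \code{phase_series}, or a list with \code{phi1},
#'   \code{phi2}, \code{h_s}.
#' @param basis a [build_basis()] object.
#' @return scalar S.
#' @export
neg_log_likelihood <- function(c_vec, E, phases, basis) {
  h <- phases$h_s
  d <- window_design(phases$phi1, phases$phi2, h, basis)
  if (length(c_vec) != d$m1 + d$m2) stop("coefficient vector has wrong length")
  detE <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  if (!is.finite(detE) || detE <= 0) stop("E must be positive definite")
  Einv <- solve(E)
  R <- residuals_dw(c_vec, d)
  quad <- sum((R %*% Einv) * R)
  jac <- sum(d$dsum * c_vec)
  d$L / 2 * log(detE) + h / 2 * (jac + quad)
}

#' Infer the phase model on one window (recursive Bayesian update)
#'
#' Alternates the stationary-point updates of the quadratic posterior until
#' convergence: the noise matrix from the weighted residual outer products,
#' the coefficient vector from the prior-plus-data linear system (including
#' the -(h/2) * dPhi/dphi Jacobian term), and the concentration matrix from
#' prior plus data concentration:
#' \deqn{E = \frac{h}{L}\sum_l r_l r_l^\top, \quad
#'   \Xi = \Xi_{prior} + h\sum_l \Phi_l^\top E^{-1} \Phi_l, \quad
#'   c = \Xi^{-1}\Big(\Xi_{prior} c_{prior} + h\sum_l \Phi_l^\top E^{-1}
#'   \dot\varphi_l - \frac{h}{2}\sum_l \frac{\partial\Phi_l}{\partial\varphi}\Big).}
#'
#' @param phases window of phases (\code{phase_series} or list with
#'   \code{phi1}, \code{phi2}, \code{h_s}).
#' @param prior_mean,prior_Xi prior mean vector and concentration
#'   (inverse-covariance) matrix; default is an effectively flat prior (zero
#'   mean, 1e-6 * I).
#' @param basis a [build_basis()] object.
#' @param max_iter,tol iteration cap and relative-change convergence
#'   tolerance. Non-convergence is flagged in the result, never silent.
#' @return a \code{model_posterior}: list with \code{c_mean}, \code{Xi},
#'   \code{E} (symmetrized; negative eigenvalues clipped at 0 with a
#'   warning), \code{converged}, \code{n_iter}, \code{L}.
#' @export
infer_window <- function(phases, prior_mean = NULL, prior_Xi = NULL,
                         basis = build_basis(2), max_iter = 100, tol = 1e-6) {
  h <- phases$h_s
  d <- window_design(phases$phi1, phases$phi2, h, basis)
  M <- d$m1 + d$m2
  if (d$L < M) stop("window length L = ", d$L, " below basis size ", M)
  prior_mean <- prior_mean %||% numeric(M)
  prior_Xi <- prior_Xi %||% diag(1e-6, M)
  if (length(prior_mean) != M || any(dim(prior_Xi) != M)) {
    stop("prior dimensions do not match basis size ", M)
  }
  cvec <- prior_mean
  E <- diag(1e-2, 2)
  Xi <- prior_Xi
  prior_term <- prior_Xi %*% prior_mean
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    R <- residuals_dw(cvec, d)
    E_new <- (h / d$L) * crossprod(R)
    E_new <- (E_new + t(E_new)) / 2
    ev <- eigen(E_new, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < 0)) {
      if (any(ev < -1e-10 * max(abs(ev), 1e-300))) {
        warning("noise matrix eigenvalue clipped at 0")
      }
      es <- eigen(E_new, symmetric = TRUE)
      E_new <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
    }
    Einv <- solve_psd(E_new)
    # data concentration, exploiting the block structure of the design
    X11 <- crossprod(d$P1); X22 <- crossprod(d$P2); X12 <- crossprod(d$P1, d$P2)
    Xi_data <- rbind(cbind(Einv[1, 1] * X11, Einv[1, 2] * X12),
                     cbind(Einv[2, 1] * t(X12), Einv[2, 2] * X22))
    Xi <- prior_Xi + h * Xi_data
    G <- d$dphi %*% Einv # L x 2
    r <- as.numeric(prior_term) +
      h * c(crossprod(d$P1, G[, 1]), crossprod(d$P2, G[, 2])) -
      (h / 2) * d$dsum
    c_new <- tryCatch(solve(Xi, r), error = function(e) {
      stop("singular coefficient system (condition: ",
           signif(kappa(Xi), 3), "): ", conditionMessage(e))
    })
    # relative change, with an absolute floor so the noise-free limit
    # (E collapsing to numerical zero) still registers as converged
    dc <- max(abs(c_new - cvec)) / max(max(abs(cvec)), 1e-9)
    dE <- max(abs(E_new - E)) / max(max(abs(E)), 1e-9)
    cvec <- as.numeric(c_new); E <- E_new
    if (dc < tol && dE < tol) { converged <- TRUE; break }
  }
  names(cvec) <- basis$terms$name
  structure(list(c_mean = cvec, Xi = Xi, E = E, converged = converged,
                 n_iter = it, L = d$L, basis_K = basis$K),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("Model posterior:", length(x$c_mean), "coefficients, L =", x$L,
      if (x$converged) "(converged" else "(NOT converged", "in", x$n_iter,
      "iterations)\n")
  cat("  omega1 =", signif(x$c_mean[1], 4), "rad/s, omega2 =",
      signif(x$c_mean[length(x$c_mean) / 2 + 1], 4), "rad/s\n")
  cat("  E11 =", signif(x$E[1, 1], 3), " E12 =", signif(x$E[1, 2], 3),
      " E22 =", signif(x$E[2, 2], 3), "\n")
  invisible(x)
}

#' Propagate a window posterior into the next window's prior
#'
#' The next prior mean is the posterior mean; the next prior covariance is
#' the posterior covariance plus the diffusion matrix
#' \code{diag((p_w * c_i)^2)} (see [propagation_spec()]); returned as a
#' concentration matrix.
#'
#' @param posterior a \code{model_posterior}.
#' @param prop a [propagation_spec()].
#' @return list with \code{mean} and \code{Xi} for the next window.
#' @export
propagate_prior <- function(posterior, prop) {
  stopifnot(inherits(posterior, "model_posterior"),
            inherits(prop, "propagation_spec"))
  Sigma_post <- solve_psd(posterior$Xi)
  Sigma_diff <- diag((prop$p_w * posterior$c_mean)^2,
                     length(posterior$c_mean))
  list(mean = posterior$c_mean, Xi = solve_psd(Sigma_post + Sigma_diff))
}

#' Sequential windowed inference over a recording
#'
#' Splits the recording into contiguous non-overlapping windows of length
#' \code{t_w_s}; the first window uses an effectively flat prior, each later
#' window's prior is the propagated posterior of the previous one. The
#' prequential (one-step-ahead, pre-update) prediction error of each window
#' under its prior mean is recorded for hyperparameter selection.
#'
#' @param phases a \code{phase_series} covering at least two windows.
#' @param t_w_s window length in seconds.
#' @param prop a [propagation_spec()].
#' @param basis a [build_basis()] object.
#' @param max_iter,tol passed to [infer_window()].
#' @return an \code{inference_run}: list with \code{windows} (posteriors),
#'   \code{table} (per-window data frame: window_index, t_start_s, t_end_s,
#'   omega1_rad_s, omega2_rad_s, E11, E12, E22, all coefficients,
#'   converged), \code{preq_mse}, and the run settings.
#' @export
run_inference <- function(phases, t_w_s = 30, prop = propagation_spec(0.2),
                          basis = build_basis(2), max_iter = 100, tol = 1e-6) {
  h <- phases$h_s
  Lw <- round(t_w_s / h)
  n <- length(phases$phi1)
  n_win <- floor((n - 1) / Lw)
  if (n_win < 2) stop("recording holds fewer than 2 windows of ", t_w_s, " s")
  prior <- list(mean = NULL, Xi = NULL)
  windows <- vector("list", n_win)
  preq <- rep(NA_real_, n_win)
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * Lw + 1):(w * Lw + 1)
    win <- list(phi1 = phases$phi1[idx], phi2 = phases$phi2[idx], h_s = h)
    if (w > 1) { # prequential score before updating on this window
      dd <- window_design(win$phi1, win$phi2, h, basis)
      preq[w] <- mean(residuals_dw(prior$mean, dd)^2)
    }
    post <- tryCatch(
      infer_window(win, prior$mean, prior$Xi, basis, max_iter, tol),
      error = function(e) e)
    if (inherits(post, "error")) {
      windows[[w]] <- NULL
      rows[[w]] <- NULL
      warning("window ", w, " failed: ", conditionMessage(post))
      next
    }
    windows[[w]] <- post
    cm <- post$c_mean
    m1 <- sum(basis$terms$osc == 1)
    rows[[w]] <- data.frame(
      window_index = w,
      t_start_s = phases$t0 + (w - 1) * Lw * h,
      t_end_s = phases$t0 + w * Lw * h,
      omega1_rad_s = unname(cm[1]), omega2_rad_s = unname(cm[m1 + 1]),
      E11 = post$E[1, 1], E12 = post$E[1, 2], E22 = post$E[2, 2],
      converged = post$converged,
      as.list(stats::setNames(cm, basis$terms$name)),
      check.names = FALSE)
    prior <- propagate_prior(post, prop)
  }
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(windows = windows, table = table, t_w_s = t_w_s,
                 prop = prop, basis = basis, h_s = h,
                 preq_mse = mean(preq, na.rm = TRUE),
                 preq_by_window = preq,
                 subject_id = phases$subject_id %||% NA_character_,
                 condition = phases$condition %||% NA_character_),
            class = "inference_run")
}

#' @export
print.inference_run <- function(x, ...) {
  cat("Inference run:", length(x$windows), "windows of", x$t_w_s,
      "s, p_w =", x$prop$p_w, ", K =", x$basis$K, "\n")
  cat("  prequential MSE:", signif(x$preq_mse, 4), "\n")
  invisible(x)
}

#' Select window length and propagation fraction on a grid
#'
#' Runs the full sequential inference for every (t_w, p_w) pair and returns
#' the pair minimizing the criterion: by default the mean prequential
#' one-step-ahead prediction error of the phase velocities (each window
#' scored under its prior, before the model is updated on it); alternatively
#' the total minus log-likelihood at the window posteriors.
#'
#' @param phases a \code{phase_series}.
#' @param t_w_grid candidate window lengths (s); default c(20, 30, 50, 80).
#' @param p_w_grid candidate propagation fractions; default
#'   c(0, 0.05, 0.1, 0.2, 0.5).
#' @param criterion "prequential" (default) or "nll".
#' @param basis a [build_basis()] object.
#' @return list with \code{t_w_s}, \code{prop} (a [propagation_spec()]),
#'   \code{diagnostics} (full grid table) and \code{best_run}.
#' @export
optimize_hyperparams <- function(phases, t_w_grid = c(20, 30, 50, 80),
                                 p_w_grid = c(0, 0.05, 0.1, 0.2, 0.5),
                                 criterion = c("prequential", "nll"),
                                 basis = build_basis(2)) {
  criterion <- match.arg(criterion)
  stopifnot(length(t_w_grid) >= 1, length(p_w_grid) >= 1)
  grid <- expand.grid(t_w_s = t_w_grid, p_w = p_w_grid)
  score <- rep(NA_real_, nrow(grid))
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    run <- tryCatch(
      run_inference(phases, grid$t_w_s[i], propagation_spec(grid$p_w[i]),
                    basis),
      error = function(e) e)
    if (inherits(run, "error")) next
    runs[[i]] <- run
    score[i] <- if (criterion == "prequential") run$preq_mse else {
      sum(vapply(run$windows, function(p) {
        if (is.null(p)) return(NA_real_)
        # S at the posterior; guard the noise-free limit
        detE <- max(det(p$E), 1e-300)
        p$L / 2 * log(detE)
      }, numeric(1)), na.rm = TRUE)
    }
  }
  if (all(is.na(score))) stop("all hyperparameter grid points failed")
  best <- which.min(score)
  list(t_w_s = grid$t_w_s[best], prop = propagation_spec(grid$p_w[best]),
       diagnostics = cbind(grid, criterion = score),
       best_run = runs[[best]])
}

#' Evaluate the inferred coupling surfaces on a phase grid
#'
#' Sums all non-constant basis terms of each oscillator on a uniform
#' (phi1, phi2) grid over \[0, 2*pi)^2, giving the inferred coupling
#' functions q_1(phi1, phi2) and q_2(phi1, phi2).
#'
#' @param posterior a \code{model_posterior}.
#' @param basis the basis used for inference.
#' @param grid_n grid points per axis (>= 8).
#' @return list with \code{phi} (grid axis), \code{q1}, \code{q2}
#'   (grid_n x grid_n matrices; rows index phi1).
#' @export
coupling_surface <- function(posterior, basis, grid_n = 32) {
  stopifnot(grid_n >= 8)
  phi <- seq(0, 2 * pi, length.out = grid_n + 1)[1:grid_n]
  gg <- expand.grid(phi1 = phi, phi2 = phi)
  out <- lapply(1:2, function(osc) {
    P <- eval_basis(basis, osc, gg$phi1, gg$phi2)
    cc <- posterior$c_mean[basis$terms$osc == osc]
    keep <- basis$terms$kind[basis$terms$osc == osc] != "const"
    matrix(P[, keep, drop = FALSE] %*% cc[keep], grid_n, grid_n)
  })
  list(phi = phi, q1 = out[[1]], q2 = out[[2]])
}
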