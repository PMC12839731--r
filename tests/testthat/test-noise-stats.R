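make_run_table <- function(E11, E12, E22, omega1, conv = TRUE) {
  n <- length(E11)
  structure(list(
    windows = vector("list", n),
    table = data.frame(window_index = seq_len(n),
                       t_start_s = (seq_len(n) - 1) * 30,
                       t_end_s = seq_len(n) * 30,
                       omega1_rad_s = omega1, omega2_rad_s = 2 * pi * 1.1,
                       E11 = E11, E12 = E12, E22 = E22,
                       converged = rep_len(conv, n)),
    subject_id = "S01", condition = "sine"),
    class = "inference_run")
}

test_that("noise trajectories drop non-converged windows and need three usable ones", {
  run <- make_run_table(rep(0.05, 5), rep(0.01, 5), rep(0.02, 5),
                        rep(1.6, 5), conv = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  traj <- noise_trajectories(run)
  expect_equal(nrow(traj), 4)
  expect_equal(attr(traj, "n_excluded"), 1)
  expect_equal(traj$E11, rep(0.05, 4))
  run_bad <- make_run_table(rep(0.05, 4), rep(0.01, 4), rep(0.02, 4),
                            rep(1.6, 4), conv = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(noise_trajectories(run_bad), "usable")
})

test_that("subject summaries match a hand computation on a 5-window example", {
  E11 <- c(0.040, 0.052, 0.047, 0.061, 0.045)
  E12 <- c(0.010, 0.012, 0.009, 0.015, 0.011)
  E22 <- c(0.020, 0.020, 0.020, 0.020, 0.020) # constant on purpose
  om1 <- c(1.50, 1.70, 1.60, 1.90, 1.55)
  traj <- noise_trajectories(make_run_table(E11, E12, E22, om1))
  sm <- summarize_subject(traj, "spearman")
  # independent spreadsheet-style computation
  sd_hand <- function(x) sqrt(sum((x - sum(x) / 5)^2) / 4)
  expect_equal(sm$std_E11, sd_hand(E11))
  expect_equal(sm$std_E12, sd_hand(E12))
  expect_equal(sm$std_E22, 0)
  # ranks of E11: 1,4,3,5,2 ; ranks of om1: 1,4,3,5,2 -> rho = 1
  expect_equal(sm$corr_E11_omega1, 1)
  expect_true(is.na(sm$corr_E22_omega1)) # zero variance: undefined, not 0
  # monotone linear transform gives rho = 1 for both methods
  traj2 <- noise_trajectories(make_run_table(2 * om1 + 1, E12, E11, om1))
  expect_equal(summarize_subject(traj2, "spearman")$corr_E11_omega1, 1)
  expect_equal(summarize_subject(traj2, "pearson")$corr_E11_omega1, 1)
})

test_that("Holm-Bonferroni adjustment matches hand-computed examples", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(c(0.5, 0.9)), c(1.0, 1.0))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
  # order-preservation under permutation of the input
  p <- c(0.02, 0.001, 0.3, 0.04, 0.9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(holm_bonferroni(p[perm]), holm_bonferroni(p)[perm])
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p) && all(adj <= 1))
})

test_that("group comparisons run all pairs, handle ties, and enforce pairing", {
  sm <- simulate_noise_summaries(n_subjects = 12, seed = 5)
  gc <- group_compare(sm, "std", "E11")
  expect_equal(nrow(gc), 6) # 4 conditions -> 6 pairwise contrasts
  expect_true(all(gc$p_adjusted >= gc$p_raw - 1e-12))
  expect_true(all(gc$p_adjusted <= 1))

  # identical groups: all paired differences zero -> p = 1, never significant
  dup <- sm[sm$condition %in% c("free", "ramp"), ]
  dup$std_E11[dup$condition == "ramp"] <-
    dup$std_E11[dup$condition == "free"]
  gdup <- group_compare(dup, "std", "E11")
  expect_equal(gdup$p_raw, 1)
  expect_false(any(gdup$significant))

  broken <- sm[!(sm$subject_id == "S03" & sm$condition == "sine"), ]
  expect_error(group_compare(broken, "std", "E11"), "S03")
})

test_that("undefined correlations are excluded pairwise with a count", {
  sm <- simulate_noise_summaries(n_subjects = 10, seed = 6)
  sm$corr_E22_omega1[sm$subject_id == "S02"] <- NA
  gc <- group_compare(sm, "corr", "E22")
  expect_true(all(gc$n_excluded == 1))
  expect_true(all(gc$n_pairs == 9))
})

test_that("null data keep the family-wise error rate controlled", {
  hits <- vapply(1:100, function(r) {
    sm <- simulate_noise_summaries(n_subjects = 20, seed = 1000 + r)
    any(group_compare(sm, "std", "E11")$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.07)
})

test_that("condition-dependent respiration noise is detected, condition-independent components are not", {
  # sine E11-variability three subject-level SDs below ramp
  e11 <- c(free = 0.02, ramp = 0.03, sine = 0.03 * exp(-3 * 0.3),
           aperiodic = 0.02)
  det <- vapply(1:20, function(r) {
    sm <- simulate_noise_summaries(n_subjects = 20,
                                   std_mean = list(E11 = e11, E12 = 0.01,
                                                   E22 = 0.008),
                                   seed = 2000 + r)
    g11 <- group_compare(sm, "std", "E11")
    rs <- g11$significant[(g11$condition_a == "ramp" & g11$condition_b == "sine") |
                          (g11$condition_a == "sine" & g11$condition_b == "ramp")]
    null_ok <- !any(group_compare(sm, "std", "E22")$significant) &&
      !any(group_compare(sm, "std", "E12")$significant)
    c(rs, null_ok)
  }, logical(2))
  expect_gte(mean(det[1, ]), 0.9) # ramp-vs-sine E11 contrast found
  expect_gte(mean(det[2, ]), 0.8) # cardiac/cross components stay quiet
})
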