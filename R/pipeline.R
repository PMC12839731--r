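#' Pipeline configuration
#'
#' Assembles the resolved configuration for a full analysis run with every
#' default explicit. Any block can be overridden; the resolved configuration
#' is serialized into the output directory of [run_pipeline()].
#'
#' @param n_subjects subjects in the synthetic cohort.
#' @param conditions breathing conditions to simulate.
#' @param duration_scale single factor shrinking all record durations
#'   (protocol shapes are preserved).
#' @param seed master seed; fans out per subject/condition/stage.
#' @param truth list overriding [ground_truth_model()] arguments.
#' @param phase list: \code{method} ("estimated" = Hilbert + R-peak
#'   interpolation on rendered signals, "true" = simulated phases),
#'   \code{h_s}, \code{resp_band}, \code{fs_hz}.
#' @param timefreq list: \code{fmin}, \code{fmax}, \code{voices},
#'   \code{penalty}, \code{ridge_band}.
#' @param dbi list: \code{K}, \code{t_w_s}, \code{p_w}, \code{optimize}
#'   (logical: select t_w/p_w on the first record), \code{t_w_grid},
#'   \code{p_w_grid}, \code{tol}, \code{max_iter}.
#' @param stats list: \code{corr_method}, \code{test}, \code{alpha}.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(n_subjects = 20,
                            conditions = c("free", "ramp", "sine", "aperiodic"),
                            duration_scale = 0.25, seed = 1,
                            truth = list(), phase = list(), timefreq = list(),
                            dbi = list(), stats = list()) {
  cfg <- list(
    n_subjects = n_subjects, conditions = conditions,
    duration_scale = duration_scale, seed = seed,
    truth = utils::modifyList(list(omega2_hz = 1.1, amp21 = 0.3, amp12 = 0.05,
                                   E11 = 0.05, E22 = 0.02, E12 = 0,
                                   jitter = list(omega2 = 0.05, coupling = 0.1,
                                                 E = 0.1)), truth),
    phase = utils::modifyList(list(method = "estimated", h_s = 0.05,
                                   resp_band = c(0.04, 0.6), fs_hz = 10,
                                   sim_h_s = 0.01), phase),
    timefreq = utils::modifyList(list(fmin = 0.05, fmax = 0.7, voices = 24,
                                      penalty = 0.2,
                                      ridge_band = c(0.05, 0.6)), timefreq),
    dbi = utils::modifyList(list(K = 2, t_w_s = 30, p_w = 0.2,
                                 optimize = FALSE,
                                 t_w_grid = c(20, 30, 50, 80),
                                 p_w_grid = c(0, 0.05, 0.1, 0.2, 0.5),
                                 tol = 1e-6, max_iter = 100), dbi),
    stats = utils::modifyList(list(corr_method = "spearman",
                                   test = "wilcoxon", alpha = 0.05), stats)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys mirror the [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_truth <- function(cfg) {
  tr <- cfg$truth
  E <- matrix(c(tr$E11, tr$E12, tr$E12, tr$E22), 2, 2)
  ground_truth_model(omega2_hz = tr$omega2_hz,
                     coupling = default_coupling(tr$amp21, tr$amp12),
                     E_true = E)
}

#' Verify that simulated subjects follow their breathing protocols
#'
#' Ridge-extracts each subject's respiration frequency from the rendered
#' waveform, averages across subjects per time point, and reports the mean
#' absolute deviation from the shared protocol reference for each controlled
#' condition.
#'
#' @param cohort a [make_cohort()] result.
#' @param cfg a [pipeline_config()] (time-frequency block is used).
#' @param conditions conditions to verify (default: all controlled
#'   conditions present in the cohort).
#' @return list per condition: data frame (\code{time_s}, \code{ref_hz},
#'   \code{mean_hz}, per-subject columns) with attributes \code{mad_hz}
#'   (mean absolute deviation of the across-subject mean from the reference,
#'   interior points) and \code{n_failed}.
#' @export
verify_protocol_following <- function(cohort, cfg = pipeline_config(),
                                      conditions = NULL) {
  stopifnot(inherits(cohort, "phase_cohort"))
  if (length(cohort$records) == 0) stop("empty cohort")
  conditions <- conditions %||%
    intersect(c("ramp", "sine", "aperiodic"), cohort$conditions)
  tf_cfg <- cfg$timefreq
  grid <- cwt_freq_grid(tf_cfg$fmin, tf_cfg$fmax, tf_cfg$voices)
  out <- list()
  for (cond in conditions) {
    recs <- Filter(function(r) r$condition == cond, cohort$records)
    if (length(recs) == 0) next
    ref <- recs[[1]]$protocol
    per_subj <- list(); interior_all <- NULL; n_failed <- 0
    for (r in recs) {
      res <- tryCatch({
        sig <- render_signals(r$phases, fs_hz = cfg$phase$fs_hz)
        # decimate: the respiration band needs only a few Hz
        dec <- max(1L, floor(cfg$phase$fs_hz / (4 * tf_cfg$fmax)))
        x <- sig$resp[seq(1, length(sig$resp), by = dec)]
        fs <- cfg$phase$fs_hz / dec
        tf <- morlet_cwt(x, fs, grid)
        ridge <- extract_ridge(tf, tf_cfg$ridge_band, tf_cfg$penalty)
        f <- stats::approx(ridge$time_s, ridge$freq_hz, xout = ref$time_s,
                           rule = 2)$y
        inter <- stats::approx(ridge$time_s,
                               as.numeric(attr(ridge, "interior")),
                               xout = ref$time_s, rule = 2)$y >= 1
        list(f = f, inter = inter)
      }, error = function(e) e)
      if (inherits(res, "error")) { n_failed <- n_failed + 1; next }
      per_subj[[r$subject_id]] <- res$f
      interior_all <- if (is.null(interior_all)) res$inter else
        interior_all & res$inter
    }
    if (length(per_subj) == 0) stop("ridge extraction failed for every subject in ", cond)
    mat <- do.call(cbind, per_subj)
    mean_f <- rowMeans(mat)
    tab <- data.frame(time_s = ref$time_s, ref_hz = ref$freq_hz,
                      mean_hz = mean_f)
    tab <- cbind(tab, mat)
    attr(tab, "mad_hz") <- mean(abs(mean_f - ref$freq_hz)[interior_all])
    attr(tab, "n_failed") <- n_failed
    out[[cond]] <- tab
  }
  out
}

#' Run the full analysis pipeline
#'
#' Cohort generation, protocol-following verification, phase estimation,
#' windowed dynamical Bayesian inference, and group noise statistics, writing
#' every table plus the resolved configuration and a run log into
#' \code{out_dir}. Rerunning with an identical configuration reproduces
#' identical numeric outputs.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML file).
#' @param out_dir writable output directory (created if missing).
#' @return invisibly, a list with \code{summaries}, \code{comparisons},
#'   \code{verification}, \code{runs} and the resolved \code{cfg}.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  cat("", file = log_path)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
  logf("stage: cohort; seed =", cfg$seed)
  cohort <- tryCatch(
    make_cohort(cfg$n_subjects, cfg$conditions, config_truth(cfg),
                cfg$truth$jitter, seed = cfg$seed,
                duration_scale = cfg$duration_scale, h_s = cfg$phase$sim_h_s),
    error = function(e) stop("stage cohort failed: ", conditionMessage(e)))

  logf("stage: verification")
  verification <- tryCatch(
    verify_protocol_following(cohort, cfg),
    error = function(e) stop("stage verification failed: ", conditionMessage(e)))
  for (cond in names(verification)) {
    utils::write.csv(verification[[cond]],
                     file.path(out_dir, paste0("verify_", cond, ".csv")),
                     row.names = FALSE)
    logf("  ", cond, ": mean |mean - ref| =",
         signif(attr(verification[[cond]], "mad_hz"), 4), "Hz")
  }

  basis <- build_basis(cfg$dbi$K)
  t_w <- cfg$dbi$t_w_s; prop <- propagation_spec(cfg$dbi$p_w)
  if (isTRUE(cfg$dbi$optimize)) {
    logf("stage: hyperparameter selection (first record)")
    ph0 <- pipeline_phases(cohort$records[[1]], cfg)
    opt <- optimize_hyperparams(ph0, cfg$dbi$t_w_grid, cfg$dbi$p_w_grid,
                                basis = basis)
    t_w <- opt$t_w_s; prop <- opt$prop
    logf("  selected t_w =", t_w, "s, p_w =", prop$p_w)
  }

  logf("stage: inference; t_w =", t_w, "s, p_w =", prop$p_w, ", K =", cfg$dbi$K)
  runs <- list(); summaries <- list(); win_rows <- list()
  for (r in cohort$records) {
    tag <- paste(r$subject_id, r$condition, sep = "/")
    res <- tryCatch({
      phases <- pipeline_phases(r, cfg)
      run <- run_inference(phases, t_w, prop, basis,
                           cfg$dbi$max_iter, cfg$dbi$tol)
      traj <- noise_trajectories(run, r$subject_id, r$condition)
      list(run = run, traj = traj,
           summary = summarize_subject(traj, cfg$stats$corr_method))
    }, error = function(e) stop("stage inference failed for ", tag, ": ",
                                conditionMessage(e)))
    runs[[tag]] <- res$run
    summaries[[tag]] <- res$summary
    wt <- res$run$table
    wt$subject_id <- r$subject_id; wt$condition <- r$condition
    win_rows[[tag]] <- wt
  }
  windows_tab <- do.call(rbind, win_rows)
  utils::write.csv(windows_tab, file.path(out_dir, "windows.csv"),
                   row.names = FALSE)
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  utils::write.csv(summaries, file.path(out_dir, "noise_summaries.csv"),
                   row.names = FALSE)

  logf("stage: group statistics")
  comparisons <- do.call(rbind, lapply(c("std", "corr"), function(metric) {
    do.call(rbind, lapply(c("E11", "E12", "E22"), function(comp) {
      group_compare(summaries, metric, comp, cfg$stats$test, cfg$stats$alpha)
    }))
  }))
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  report <- list(
    n_subjects = cfg$n_subjects, conditions = cfg$conditions,
    duration_scale = cfg$duration_scale, seed = cfg$seed,
    corr_method = cfg$stats$corr_method, test = cfg$stats$test,
    t_w_s = t_w, p_w = prop$p_w, K = cfg$dbi$K,
    n_significant = sum(comparisons$significant),
    verification_mad_hz = lapply(verification, attr, "mad_hz"))
  jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done:", nrow(comparisons), "contrasts,",
       sum(comparisons$significant), "significant")
  invisible(list(summaries = summaries, comparisons = comparisons,
                 verification = verification, runs = runs, cfg = cfg))
}

# Phase series for inference: either the simulated (true) phases resampled
# to the inference step, or the estimated route through rendered signals.
pipeline_phases <- function(record, cfg) {
  if (cfg$phase$method == "true") {
    ph <- record$phases
    k <- round(cfg$phase$h_s / ph$h_s)
    idx <- seq(1, length(ph$phi1), by = k)
    new_phase_series(ph$h_s * k, ph$phi1[idx], ph$phi2[idx],
                     record$subject_id, record$condition)
  } else {
    sig <- render_signals(record$phases, fs_hz = cfg$phase$fs_hz)
    estimate_phases(sig, cfg$phase$resp_band, cfg$phase$h_s)
  }
}
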