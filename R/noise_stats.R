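#' Extract the noise and frequency trajectories from an inference run
#'
#' Window-centre time series of the inferred noise-matrix components E11
#' (respiration), E12 = E21 (cross) and E22 (cardiac), together with the
#' inferred respiration frequency omega1 (the constant-term coefficient
#' c_0^1). Non-converged windows are excluded and counted.
#'
#' @param run an \code{inference_run}.
#' @param subject_id,condition labels (default: taken from the run).
#' @return a \code{noise_trajectory}: data frame with columns
#'   \code{subject_id}, \code{condition}, \code{time_s} (window centres),
#'   \code{E11}, \code{E12}, \code{E22}, \code{omega1}; attribute
#'   \code{n_excluded} counts dropped windows.
#' @export
noise_trajectories <- function(run, subject_id = NULL, condition = NULL) {
  stopifnot(inherits(run, "inference_run"))
  tab <- run$table
  if (is.null(tab) || nrow(tab) < 3) stop("run has fewer than 3 windows")
  keep <- tab$converged
  n_excluded <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) < 3) stop("fewer than 3 usable (converged) windows")
  out <- data.frame(
    subject_id = subject_id %||% run$subject_id,
    condition = condition %||% run$condition,
    time_s = (tab$t_start_s + tab$t_end_s) / 2,
    E11 = tab$E11, E12 = tab$E12, E22 = tab$E22,
    omega1 = tab$omega1_rad_s)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("noise_trajectory", "data.frame")
  out
}

safe_cor <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Summarise one subject-condition noise trajectory
#'
#' Computes, per noise component, the sample standard deviation over windows
#' (the within-recording variability of the inferred noise level) and its
#' correlation with the inferred respiration frequency omega1. Zero-variance
#' series yield an NA (undefined) correlation, never a coerced 0.
#'
#' @param traj a [noise_trajectories()] result.
#' @param corr_method "spearman" (default, robust to the unknown marginal
#'   distribution of E) or "pearson".
#' @return one-row data frame: \code{subject_id}, \code{condition},
#'   \code{std_E11}, \code{std_E12}, \code{std_E22}, \code{corr_E11_omega1},
#'   \code{corr_E12_omega1}, \code{corr_E22_omega1}, \code{n_windows}.
#' @export
summarize_subject <- function(traj, corr_method = c("spearman", "pearson")) {
  corr_method <- match.arg(corr_method)
  if (nrow(traj) < 3) stop("need at least 3 windows to summarise")
  data.frame(
    subject_id = traj$subject_id[1], condition = traj$condition[1],
    std_E11 = stats::sd(traj$E11), std_E12 = stats::sd(traj$E12),
    std_E22 = stats::sd(traj$E22),
    corr_E11_omega1 = safe_cor(traj$E11, traj$omega1, corr_method),
    corr_E12_omega1 = safe_cor(traj$E12, traj$omega1, corr_method),
    corr_E22_omega1 = safe_cor(traj$E22, traj$omega1, corr_method),
    n_windows = nrow(traj))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Adjusts p-values to control the family-wise error rate: the i-th smallest
#' p-value is multiplied by (m - i + 1), the sorted sequence is made
#' monotone non-decreasing, capped at 1, and returned in the original order
#' (delegates to \code{stats::p.adjust(method = "holm")}, which implements
#' exactly this procedure).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Pairwise between-condition comparisons with Holm-Bonferroni correction
#'
#' For one noise component and one metric (per-subject std over windows, or
#' per-subject noise-frequency correlation), tests every pair of breathing
#' conditions with a paired two-sided test across subjects (default:
#' Wilcoxon signed-rank; the design is paired, the same subjects recorded
#' under every condition). The Holm-Bonferroni family is the set of pairwise
#' contrasts within this one component-metric panel.
#'
#' Degenerate signed-rank input (all paired differences zero) reports
#' p = 1 (no evidence of difference). Subjects with an undefined (NA) value
#' in either condition of a pair are excluded pairwise and counted.
#'
#' @param summaries data frame of [summarize_subject()] rows covering every
#'   subject under every condition.
#' @param metric "std" or "corr".
#' @param component "E11", "E12" or "E22".
#' @param test "wilcoxon" (paired signed-rank, default) or "ttest".
#' @param alpha significance level applied to adjusted p-values.
#' @return a data frame, one row per condition pair: \code{component},
#'   \code{metric}, \code{condition_a}, \code{condition_b}, \code{n_pairs},
#'   \code{n_excluded}, \code{p_raw}, \code{p_adjusted},
#'   \code{significant}.
#' @export
group_compare <- function(summaries, metric = c("std", "corr"),
                          component = c("E11", "E12", "E22"),
                          test = c("wilcoxon", "ttest"), alpha = 0.05) {
  metric <- match.arg(metric)
  component <- match.arg(component)
  test <- match.arg(test)
  col <- if (metric == "std") paste0("std_", component) else
    paste0("corr_", component, "_omega1")
  if (!col %in% names(summaries)) stop("column ", col, " missing from summaries")
  conditions <- unique(summaries$condition)
  subj_sets <- lapply(conditions, function(cc)
    sort(summaries$subject_id[summaries$condition == cc]))
  ref <- subj_sets[[1]]
  for (i in seq_along(conditions)) {
    if (!identical(subj_sets[[i]], ref)) {
      bad <- c(setdiff(ref, subj_sets[[i]]), setdiff(subj_sets[[i]], ref))
      stop("unpaired design: condition ", conditions[i],
           " differs in subjects ", paste(bad, collapse = ", "))
    }
  }
  pairs <- utils::combn(conditions, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    da <- summaries[summaries$condition == a, ]
    db <- summaries[summaries$condition == b, ]
    da <- da[order(da$subject_id), ]; db <- db[order(db$subject_id), ]
    x <- da[[col]]; y <- db[[col]]
    ok <- !is.na(x) & !is.na(y)
    n_excl <- sum(!ok)
    x <- x[ok]; y <- y[ok]
    p <- if (length(x) < 3 || all(x == y)) 1 else if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                          exact = FALSE)$p.value)
    } else {
      stats::t.test(x, y, paired = TRUE)$p.value
    }
    data.frame(component = component, metric = metric,
               condition_a = a, condition_b = b,
               n_pairs = length(x), n_excluded = n_excl, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_bonferroni(out$p_raw)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Simulate subject-level noise summaries directly
#'
#' Monte-Carlo generator for the statistical stage: draws per-subject,
#' per-condition summary values (std of each noise component over windows,
#' and noise-frequency correlations) from a paired subject-random-effect
#' model, without running the full simulation-inference route. Std values
#' are log-normal around condition-specific means with a shared subject
#' effect; correlations are Fisher-z normal around condition-specific means.
#' Used for null-calibration and power experiments of the group-comparison
#' stage at many replicates.
#'
#' @param n_subjects subjects per condition (paired across conditions).
#' @param conditions condition labels.
#' @param std_mean named list: per component ("E11", "E12", "E22") either a
#'   single mean std or a named per-condition vector.
#' @param corr_mean same structure for the noise-frequency correlations.
#' @param subject_sd log-scale SD of the shared subject random effect.
#' @param resid_sd log-scale SD of the residual (subject x condition) noise.
#' @param corr_sd Fisher-z SD of the correlation values.
#' @param seed integer seed.
#' @return data frame in the [summarize_subject()] layout.
#' @export
simulate_noise_summaries <- function(n_subjects = 20,
                                     conditions = c("free", "ramp", "sine",
                                                    "aperiodic"),
                                     std_mean = list(E11 = 0.02, E12 = 0.01,
                                                     E22 = 0.008),
                                     corr_mean = list(E11 = 0.3, E12 = 0.0,
                                                      E22 = 0.0),
                                     subject_sd = 0.3, resid_sd = 0.25,
                                     corr_sd = 0.25, seed = 1) {
  get_mean <- function(spec, cond) {
    if (length(spec) == 1 && is.null(names(spec))) return(spec)
    if (!is.null(names(spec)) && cond %in% names(spec)) return(spec[[cond]])
    spec[[1]]
  }
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      u <- stats::rnorm(3, 0, subject_sd) # per-component subject effect
      names(u) <- c("E11", "E12", "E22")
      for (cond in conditions) {
        vals <- vapply(c("E11", "E12", "E22"), function(comp) {
          exp(log(get_mean(std_mean[[comp]], cond)) + unname(u[comp]) +
                stats::rnorm(1, 0, resid_sd))
        }, numeric(1))
        cors <- vapply(c("E11", "E12", "E22"), function(comp) {
          z <- atanh(pmin(pmax(get_mean(corr_mean[[comp]], cond), -0.99), 0.99))
          tanh(z + stats::rnorm(1, 0, corr_sd))
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("S%02d", s), condition = cond,
          std_E11 = vals["E11"], std_E12 = vals["E12"], std_E22 = vals["E22"],
          corr_E11_omega1 = cors["E11"], corr_E12_omega1 = cors["E12"],
          corr_E22_omega1 = cors["E22"], n_windows = NA_integer_)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
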