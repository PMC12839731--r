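# Shared configuration for the analysis scripts.
#
# Study emulation: 20 subjects, four breathing conditions (free, ramp, sine,
# aperiodic). Record durations are scaled to one quarter of the original
# design (free 7.5 min, paced 5 min) — every stage of the analysis is
# exercised identically at this size. Each script regenerates what it needs
# deterministically from the master seed, so the scripts can be run
# independently and in any order after 01.

library(phasenoise)

cfg <- pipeline_config(
  n_subjects = 20,
  conditions = c("free", "ramp", "sine", "aperiodic"),
  duration_scale = 0.25,
  seed = 1
)

out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

build_cohort <- function(cfg) {
  make_cohort(cfg$n_subjects, cfg$conditions,
              phasenoise:::config_truth(cfg), cfg$truth$jitter,
              seed = cfg$seed, duration_scale = cfg$duration_scale,
              h_s = cfg$phase$sim_h_s)
}
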