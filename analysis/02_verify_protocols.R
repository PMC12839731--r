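# Verify protocol following: wavelet-ridge extract each subject's breathing
# frequency from the rendered respiration waveform and compare the
# across-subject mean against the protocol reference curve (the synthetic
# counterpart of the sine/ramp/aperiodic reference comparison).

source("analysis/00_config.R")

cohort <- build_cohort(cfg)
verification <- verify_protocol_following(cohort, cfg)

for (cond in names(verification)) {
  tab <- verification[[cond]]
  write.csv(tab, file.path(out_dir, paste0("verify_", cond, ".csv")),
            row.names = FALSE)
  cat(sprintf(
    "%-10s mean |mean extracted - reference| = %.4f Hz  (%d subjects, %d ridge failures)\n",
    cond, attr(tab, "mad_hz"), ncol(tab) - 3, attr(tab, "n_failed")))
}
cat("Per-subject ridges deviate most near the band extremes;",
    "the across-subject mean follows each reference closely.\n")
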