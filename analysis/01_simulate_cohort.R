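#!/usr/bin/env Rscript
# Simulate the two-group synthetic cohort used throughout the analysis:
# a visual-lead group (auditory response kernel peaking ~200 ms, visual
# ~50 ms, theta phase offset pi/2, tight phase concentration) and an
# auditory-lead group (kernel peaks reversed, offset pi, broad phase
# dispersion).  Writes the cohort manifest and ground-truth summary.

library(avtrack)

seed <- 1
n_per_group <- 5
duration_s <- 60
n_channels <- 16

dir.create("results", showWarnings = FALSE)
co <- gen_cohort(n_per_group, seed = seed, duration_s = duration_s,
                 n_channels = n_channels)

manifest <- do.call(rbind, lapply(seq_along(co), function(i) {
  s <- co[[i]]
  data.frame(subject = i, group = s$group_label, seed = s$seed,
             duration_s = duration_s, n_channels = n_channels,
             a_peak_ms = s$truth$a_peak_ms, v_peak_ms = s$truth$v_peak_ms,
             theta_phase_shift_rad = s$truth$theta_phase_shift_rad,
             snr_db = s$truth$snr_db)
}))
write.csv(manifest, "results/cohort_manifest.csv", row.names = FALSE)

cat("Simulated", nrow(manifest), "subjects (", n_per_group, "per group ).\n")
cat("Group A kernel peaks (A/V, ms):",
    round(mean(manifest$a_peak_ms[manifest$group == "A"])), "/",
    round(mean(manifest$v_peak_ms[manifest$group == "A"])), "\n")
cat("Group B kernel peaks (A/V, ms):",
    round(mean(manifest$a_peak_ms[manifest$group == "B"])), "/",
    round(mean(manifest$v_peak_ms[manifest$group == "B"])), "\n")
cat("Wrote results/cohort_manifest.csv\n")
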