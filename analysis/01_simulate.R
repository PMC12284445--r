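#!/usr/bin/env Rscript
# Stage 1: generate the synthetic crossover study.
#
# Emulates the experimental design (13 subjects x {placebo, carbamazepine,
# lacosamide} x {30, 60, 120} us x 11 intensities x 10 trials) with known
# ground-truth rheobase and strength-duration time constants, so every later
# stage can be checked against truth. Writes the trial table, the ground
# truth and the generating config under results/sim/.

library(sdtms)

out <- file.path("results", "sim")
cfg <- sim_config(seed = 1L)
study <- simulate_study(cfg)
write_simulation(study, out)

cat(sprintf("Simulated %d trials (%d subjects x %d conditions x %d widths).\n",
            nrow(study$trials), cfg$n_subjects, length(cfg$conditions),
            length(cfg$pulse_widths_us)))
tr <- study$truth
by_w <- tapply(tr$true_threshold_pct_mso, tr$pulse_width_us, mean)
cat("Mean true thresholds (%MSO):",
    paste(sprintf("%s us = %.1f", names(by_w), by_w), collapse = ", "), "\n")
cat(sprintf("Truncated sessions (top levels at the device ceiling): %d of %d\n",
            sum(tr$truncated), nrow(tr)))
cat("Wrote trials.csv, ground_truth.csv and sim_config.yaml to", out, "\n")
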