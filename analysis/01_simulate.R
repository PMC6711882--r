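#!/usr/bin/env Rscript

# Stage 1: simulate an experience-sampling EEG cohort.
#
# Each subject performs a SART and a visual search session (probe counts
# and mind-wandering rates configurable). Epoched EEG for the six
# pre-probe trials of every probe is written as an epoch container per
# session, plus probe and behavior tables.
#
#   Rscript analysis/01_simulate.R [--subjects 8] [--probes 30] [--seed 1]

suppressPackageStartupMessages(library(mweeg))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1) as.numeric(args[i + 1]) else default
}
n_subj <- arg("--subjects", 8)
n_probes <- arg("--probes", 30)
seed <- arg("--seed", 1)

out_root <- "results/01_sessions"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

# mind-wandering rates span the range observed in experience-sampling
# cohorts (0.16-0.82)
mw_rates <- seq(0.16, 0.82, length.out = n_subj)

probe_rows <- list(); behav_rows <- list()
for (s in seq_len(n_subj)) {
  gen <- gen_params(mw_rate = mw_rates[s])
  for (ti in 1:2) {
    task <- c("SART", "VS")[ti]
    sess <- simulate_session(task, gen,
                             seed = as.integer(seed * 7919 + s * 131 + ti),
                             design_args = list(n_probes = n_probes))
    dir <- file.path(out_root, sprintf("subj%02d_%s", s, task))
    write_epochs(sess$epochs, dir)
    pr <- sess$probes; pr$subject <- s; pr$task <- task
    probe_rows[[paste(s, task)]] <- pr
    bh <- sess$behavior[sess$behavior$state != "unlabeled", ]
    bh$subject <- s; bh$task <- task
    behav_rows[[paste(s, task)]] <- bh
  }
  message(sprintf("subject %02d (mw rate %.2f): sessions written", s,
                  mw_rates[s]))
}
probes <- do.call(rbind, probe_rows)
write.csv(probes, file.path(out_root, "probes.csv"), row.names = FALSE)
write.csv(do.call(rbind, behav_rows), file.path(out_root, "behavior.csv"),
          row.names = FALSE)
write.csv(data.frame(subject = seq_len(n_subj), mw_rate = mw_rates),
          file.path(out_root, "cohort.csv"), row.names = FALSE)

reported <- tapply(probes$latent == "mind_wandering",
                   probes$subject, mean)
message(sprintf(
  "cohort of %d subjects simulated; probed mind-wandering rates %.2f-%.2f (mean %.2f)",
  n_subj, min(reported), max(reported), mean(reported)))
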