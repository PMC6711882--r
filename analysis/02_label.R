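#!/usr/bin/env Rscript

# Stage 2: map probe responses to mental states and label the six
# pre-probe trials of every probe; apply the subject-level inclusion
# criterion (>= 30 clean labeled trials per task-state cell at full
# session length; scaled sessions use a proportional threshold).
#
#   Rscript analysis/02_label.R [--min-trials 10]

suppressPackageStartupMessages(library(mweeg))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1) as.numeric(args[i + 1]) else default
}
min_trials <- arg("--min-trials", 10)

in_root <- "results/01_sessions"
out_root <- "results/02_labels"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
probes <- read.csv(file.path(in_root, "probes.csv"))

label_rows <- list(); count_rows <- list()
for (key in unique(paste(probes$subject, probes$task))) {
  sub <- probes[paste(probes$subject, probes$task) == key, ]
  s <- sub$subject[1]; task <- sub$task[1]
  ep <- read_epochs(file.path(in_root, sprintf("subj%02d_%s", s, task)))
  design <- task_design(task, n_probes = nrow(sub))
  design$probe_trials <- sub$trial_index   # the simulated schedule
  labels <- select_trials(design, sub)
  clean <- labels[!ep$trials$artifact[match(labels$trial_id,
                                            ep$trials$trial_id)], ]
  clean$subject <- s; clean$task <- task
  label_rows[[key]] <- clean
  count_rows[[key]] <- data.frame(subject = s, task = task,
                                  state = names(table(clean$state)),
                                  n = as.integer(table(clean$state)))
}
labels <- do.call(rbind, label_rows)
counts <- do.call(rbind, count_rows)
inclusion <- apply_inclusion_criteria(counts, min_trials)

write.csv(labels, file.path(out_root, "labels.csv"), row.names = FALSE)
write.csv(counts, file.path(out_root, "label_counts.csv"),
          row.names = FALSE)
jsonlite::write_json(inclusion, file.path(out_root, "inclusion.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

excl_rate <- 1 - nrow(labels) / (6 * nrow(probes))
message(sprintf(
  "%d labeled trials from %d probes (%.1f%% of probe reports excluded as distraction/blanking)",
  nrow(labels), nrow(probes), 100 * excl_rate))
message(sprintf("inclusion: %d/%d subjects retained (>= %d trials per cell)",
                sum(inclusion$included), nrow(inclusion), min_trials))
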