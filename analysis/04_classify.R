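#!/usr/bin/env Rscript

# Stage 4: per-subject RBF-SVM classification.
#
# Within-task leave-one-out cross-validation, across-task transfer
# (train on one task, test on the other, both directions), and
# single-marker models on the pooled normalized data of both tasks.
# Training folds are always oversampled to class balance; markers are
# z-transformed per subject and task.
#
#   Rscript analysis/04_classify.R [--seed 1] [--full-grid]
#
# --full-grid uses the complete C x gamma search grid; the default uses
# a reduced grid to keep the stage in desktop minutes.

suppressPackageStartupMessages(library(mweeg))
args <- commandArgs(trailingOnly = TRUE)
seed <- { i <- which(args == "--seed"); if (length(i)) as.integer(args[i + 1]) else 1L }
full_grid <- "--full-grid" %in% args

in_feat <- "results/03_features"
in_lab <- "results/02_labels"
out_root <- "results/04_classification"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

erp <- read.csv(file.path(in_feat, "sterp_features.csv"))
spec_feats <- read.csv(file.path(in_feat, "spectral_features.csv"))
labels <- read.csv(file.path(in_lab, "labels.csv"))
inclusion <- jsonlite::read_json(file.path(in_lab, "inclusion.json"),
                                 simplifyVector = TRUE)
included <- as.integer(inclusion$subject[inclusion$included])

spec <- if (full_grid) model_spec() else
  model_spec(C_grid = 2^c(-1, 1, 3, 5), gamma_grid = 2^c(-9, -7, -5, -3))

tab_for <- function(s, task) {
  key <- erp$subject == s & erp$task == task
  keyl <- labels$subject == s & labels$task == task
  assemble_features(erp[key, ], spec_feats[spec_feats$subject == s &
                                             spec_feats$task == task, ],
                    data.frame(trial_id = labels$trial_id[keyl],
                               state = labels$state[keyl]))
}

metric_rows <- list(); pred_rows <- list()
for (s in included) {
  tabs <- list(SART = tab_for(s, "SART"), VS = tab_for(s, "VS"))
  for (task in names(tabs)) {
    set.seed(seed * 1000 + s * 10 + match(task, names(tabs)))
    res <- loocv(tabs[[task]], spec)
    metric_rows[[paste(s, task)]] <-
      data.frame(subject = s, scheme = paste0("loocv_", task),
                 t(res$metrics), C = res$C, gamma = res$gamma)
    pred_rows[[paste(s, task)]] <-
      cbind(subject = s, scheme = paste0("loocv_", task), res$predictions)
  }
  for (dir in 1:2) {
    tr <- c("SART", "VS")[dir]; te <- c("SART", "VS")[3 - dir]
    set.seed(seed * 1000 + s * 10 + 5 + dir)
    res <- cross_task_predict(tabs[[tr]], tabs[[te]], spec)
    metric_rows[[paste(s, tr, te)]] <-
      data.frame(subject = s, scheme = paste0("cross_", tr, "_", te),
                 t(res$metrics), C = res$C, gamma = res$gamma)
  }
  message(sprintf("subject %02d: LOOCV acc %.2f (SART) / %.2f (VS)", s,
                  metric_rows[[paste(s, "SART")]]$accuracy,
                  metric_rows[[paste(s, "VS")]]$accuracy))
}
metrics <- do.call(rbind, c(metric_rows, list(make.row.names = FALSE)))
write.csv(metrics, file.path(out_root, "metrics.csv"), row.names = FALSE)
write.csv(do.call(rbind, c(pred_rows, list(make.row.names = FALSE))),
          file.path(out_root, "predictions.csv"), row.names = FALSE)

# single-marker ranking on pooled tasks (subsampled for run time)
marker_rows <- list()
for (s in included) {
  pooled <- rbind(zscore_features(tab_for(s, "SART")),
                  zscore_features(tab_for(s, "VS")))
  set.seed(seed * 1000 + s)
  if (nrow(pooled) > 200)
    pooled <- pooled[sort(sample.int(nrow(pooled), 200)), ]
  sm <- single_marker_models(pooled, model_spec(C_grid = 2^c(0, 3),
                                                gamma_grid = 2^c(-5, -1)))
  sm$subject <- s
  marker_rows[[as.character(s)]] <- sm
  message(sprintf("subject %02d: single-marker models done", s))
}
markers <- do.call(rbind, c(marker_rows, list(make.row.names = FALSE)))
write.csv(markers, file.path(out_root, "single_markers.csv"),
          row.names = FALSE)

for (sch in unique(metrics$scheme))
  message(sprintf("%-16s mean accuracy %.3f", sch,
                  mean(metrics$accuracy[metrics$scheme == sch])))
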