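#!/usr/bin/env Rscript

# Stage 5: group-level evaluation.
#
# Tests classification accuracy against chance (one-sample t per scheme),
# correlates classifier bias (sensitivity/specificity) with each
# subject's mind-wandering rate, compares ERP markers between states with
# paired t tests (single-trial and traditional), runs the state-by-time
# RM-ANOVAs on the band markers, compares behavior between states, ranks
# single-marker models against the full model with equivalence tests, and
# writes the consolidated report.
#
#   Rscript analysis/05_evaluate.R

suppressPackageStartupMessages(library(mweeg))

out_root <- "results/05_report"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

metrics <- read.csv("results/04_classification/metrics.csv")
markers <- read.csv("results/04_classification/single_markers.csv")
erp <- read.csv("results/03_features/sterp_features.csv")
trad <- read.csv("results/03_features/traditional_erp.csv")
spec <- read.csv("results/03_features/spectral_features.csv")
behavior <- read.csv("results/01_sessions/behavior.csv")
cohort <- read.csv("results/01_sessions/cohort.csv")

group_tests <- list()
for (sch in unique(metrics$scheme)) {
  acc <- metrics$accuracy[metrics$scheme == sch]
  if (length(acc) >= 2 && sd(acc) > 0) {
    gt <- one_sample_t(acc, mu = 0.5)
    group_tests[[paste0("accuracy_vs_chance_", sch)]] <- gt
    message(sprintf("%s: mean acc %.3f vs chance, t(%d) = %.2f, p = %.4g, d = %.2f",
                    sch, mean(acc), gt["df"], gt["t"], gt["p"], gt["d"]))
  }
}

# classifier bias vs mind-wandering rate
corr_rows <- list()
for (sch in grep("^loocv", unique(metrics$scheme), value = TRUE)) {
  sub <- metrics[metrics$scheme == sch, ]
  mwr <- cohort$mw_rate[match(sub$subject, cohort$subject)]
  for (msr in c("sensitivity", "specificity")) {
    ok <- is.finite(sub[[msr]])
    if (sum(ok) >= 3 && sd(sub[[msr]][ok]) > 0) {
      sc <- spearman_cor(mwr[ok], sub[[msr]][ok])
      corr_rows[[paste(sch, msr)]] <-
        data.frame(measure = paste(sch, msr), rho = sc[["rho"]],
                   p = sc[["p"]], n = sc[["n"]])
      message(sprintf("mind-wandering rate vs %s (%s): rho = %.2f, p = %.4g",
                      msr, sch, sc["rho"], sc["p"]))
    }
  }
}
correlations <- do.call(rbind, c(corr_rows, list(make.row.names = FALSE)))

# ERP state comparisons (Table-1 style), both extraction methods
subj_state_means <- function(df) {
  ag <- aggregate(amplitude ~ subject + component + channel + state, df,
                  mean)
  ag
}
for (src in c("single_trial", "traditional")) {
  df <- if (src == "single_trial") erp else trad
  ag <- subj_state_means(df)
  for (cc in unique(paste(ag$component, ag$channel))) {
    sub <- ag[paste(ag$component, ag$channel) == cc, ]
    w <- merge(sub[sub$state == "mind_wandering", c("subject", "amplitude")],
               sub[sub$state == "on_task", c("subject", "amplitude")],
               by = "subject", suffixes = c("_mw", "_ot"))
    if (nrow(w) >= 2 && sd(w$amplitude_mw - w$amplitude_ot) > 0)
      group_tests[[paste("erp", src, cc)]] <-
        paired_t_d(w$amplitude_mw, w$amplitude_ot)
  }
}

# RM-ANOVA (state x time) per band marker of interest
anova_tabs <- list()
for (mk in list(c("power", "alpha", "A19"), c("power", "alpha", "C21"),
                c("ispc", "theta", "A10-A19"))) {
  sub <- spec[spec$kind == mk[1] & spec$band == mk[2] &
                spec$site_or_pair == mk[3], ]
  ag <- aggregate(value ~ subject + state + period, sub, mean)
  names(ag)[names(ag) == "period"] <- "time"
  tab <- rm_anova_ges(ag)
  anova_tabs[[paste(mk, collapse = " ")]] <- tab
  st <- tab[tab$effect == "state", ]
  message(sprintf("RM-ANOVA %s %s %s: state F(1,%d) = %.2f, p = %.4g, ges = %.2f",
                  mk[1], mk[2], mk[3], st$df2, st$F, st$p, st$ges))
}

# behavior: state effects on accuracy and RT per task
behavioral <- list()
for (task in unique(behavior$task)) {
  b <- behavior[behavior$task == task, ]
  acc <- aggregate(correct ~ subject + state, b, mean)
  rt <- aggregate(rt_ms ~ subject + state, b[b$correct, ], mean)
  for (msr in c("correct", "rt_ms")) {
    d <- if (msr == "correct") acc else rt
    w <- merge(d[d$state == "mind_wandering", c("subject", msr)],
               d[d$state == "on_task", c("subject", msr)],
               by = "subject", suffixes = c("_mw", "_ot"))
    if (nrow(w) >= 2 && sd(w[[2]] - w[[3]]) > 0)
      behavioral[[paste(task, msr)]] <- paired_t_d(w[[2]], w[[3]])
  }
}

# single-marker ranking + equivalence of the best marker with the full model
mk_mean <- aggregate(accuracy ~ marker, markers, mean)
mk_mean <- mk_mean[order(-mk_mean$accuracy), ]
message("top single markers by mean LOOCV accuracy:")
for (i in head(which(mk_mean$marker != "full_model"), 3))
  message(sprintf("  %-18s %.3f", mk_mean$marker[i], mk_mean$accuracy[i]))
full_acc <- markers$accuracy[markers$marker == "full_model"]
best <- mk_mean$marker[mk_mean$marker != "full_model"][1]
best_acc <- markers$accuracy[markers$marker == best]
equiv <- NULL
if (length(full_acc) >= 2 && sd(best_acc - full_acc) > 0) {
  equiv <- tost_equivalence(best_acc - full_acc, bounds = 0.1)
  message(sprintf(
    "equivalence of %s with the full model: mean diff %.3f, TOST CI [%.3f, %.3f] -> %s",
    best, equiv$mean_diff, equiv$ci[1], equiv$ci[2],
    if (equiv$equivalent) "equivalent" else "not equivalent"))
}

report <- build_report(
  classification = metrics, group_tests = group_tests,
  correlations = correlations,
  markers = merge(mk_mean, data.frame(marker = best,
                                      equivalent_to_full =
                                        if (is.null(equiv)) NA
                                        else equiv$equivalent),
                  all.x = TRUE),
  anova = anova_tabs, behavioral = behavioral,
  meta = list(n_subjects = length(unique(metrics$subject))))
write_report(report, out_root)
message("report written to ", out_root)
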