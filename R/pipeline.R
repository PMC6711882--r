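#' Default pipeline configuration
#'
#' A full run simulates a cohort of subjects, each performing both tasks
#' with 54 probes per task; per-subject mind-wandering rates are spread
#' evenly over the 0.16-0.82 range observed in experience-sampling
#' cohorts. All downstream choices (bands, search windows, classifier
#' grids) carry their documented defaults. The configuration is a plain
#' list and serializes to JSON, making a run a pure function of
#' (config, seed).
#'
#' @param n_subjects cohort size.
#' @param tasks tasks each subject performs.
#' @param seed master seed; per-subject/task seeds are derived from it.
#' @param n_probes probes per task session.
#' @param mw_rates per-subject mind-wandering rates (length
#'   `n_subjects`).
#' @param ... overrides for `design`, `gen`, `sterp`, `classifier`
#'   sub-lists.
#' @return A config list.
#' @export
default_config <- function(n_subjects = 18, tasks = c("SART", "VS"),
                           seed = 1, n_probes = 54,
                           mw_rates = seq(0.16, 0.82,
                                          length.out = n_subjects),
                           ...) {
  cfg <- list(
    n_subjects = n_subjects, tasks = tasks, seed = seed,
    mw_rates = mw_rates,
    design = list(n_blocks = 12, n_probes = n_probes,
                  probe_gaps = c(7, 24), fs = 256,
                  epoch_window = c(400, 1200)),
    gen = list(),                      # overrides onto gen_params()
    sterp = list(n1_hi_ms = 200, n_scales = 32),
    bands = list(alpha = c(8.5, 12), theta = c(4, 8)),
    classifier = list(C_grid = 2^seq(-5, 15, 2),
                      gamma_grid = 2^seq(-15, 3, 2),
                      inner_folds = 5, nested = FALSE,
                      scope = "global_per_subject_task"),
    min_trials_inclusion = 30,
    run_cross_task = TRUE,
    anova_markers = list(c("power", "alpha", "A19"),
                         c("power", "alpha", "C21"),
                         c("ispc", "theta", "A10-A19"))
  )
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every design/band/classifier invariant and returns the list of
#' violations (empty when the configuration is valid) rather than
#' stopping.
#'
#' @param config a config list as from [default_config()].
#' @return Character vector of violations with field paths.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$n_subjects) && config$n_subjects >= 1,
      "n_subjects: must be >= 1")
  chk(all(config$tasks %in% c("SART", "VS")),
      "tasks: must be a subset of {SART, VS}")
  chk(length(config$mw_rates) == config$n_subjects,
      "mw_rates: length must equal n_subjects")
  chk(all(config$mw_rates >= 0 & config$mw_rates <= 1),
      "mw_rates: must lie in [0, 1]")
  d <- config$design
  chk(d$probe_gaps[1] >= 7 && d$probe_gaps[2] <= 24 &&
        d$probe_gaps[1] <= d$probe_gaps[2],
      "design.probe_gaps: must be an increasing range within [7, 24]")
  chk(sum(d$epoch_window) == 1600,
      "design.epoch_window: must total 1600 ms")
  chk(d$n_probes >= 1, "design.n_probes: must be >= 1")
  for (bn in names(config$bands)) {
    b <- config$bands[[bn]]
    chk(b[1] < b[2], sprintf("bands.%s: lo < hi violated", bn))
    chk(d$fs > 2 * b[2] * 1.2,
        sprintf("bands.%s: sampling rate too low", bn))
  }
  cl <- config$classifier
  chk(all(cl$C_grid > 0), "classifier.C_grid: must be positive")
  chk(all(cl$gamma_grid > 0), "classifier.gamma_grid: must be positive")
  chk(cl$scope %in% c("global_per_subject_task", "train_fold_only"),
      "classifier.scope: unknown scope")
  if (length(config$gen)) {
    g <- do.call(gen_params, config$gen)  # errors -> violation
    chk(inherits(g, "gen_params"), "gen: invalid generator parameters")
  }
  v
}

derive_seed <- function(master, subject, task_idx) {
  as.integer((master * 7919 + subject * 131 + task_idx * 17) %% 2147483647L)
}

#' Run the full simulate-extract-label-classify-evaluate pipeline
#'
#' Executes every stage for a synthetic cohort and consolidates the
#' results: per-subject within-task LOOCV and across-task transfer
#' metrics, group tests of accuracy against chance, mind-wandering-rate
#' bias correlations, ERP state comparisons (single-trial and
#' traditional), and RM-ANOVAs on the configured band markers. When
#' `out_dir` is given, all stage outputs plus a manifest (config, seeds,
#' timing) are written there.
#'
#' @param config configuration list; see [default_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return An `eval_report` (invisibly when writing to disk).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid config:\n", paste("-", viol, collapse = "\n"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  timing <- list()
  tick <- function(stage) {
    timing[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    t0 <<- Sys.time()
  }

  spec <- model_spec(C_grid = config$classifier$C_grid,
                     gamma_grid = config$classifier$gamma_grid,
                     inner_folds = config$classifier$inner_folds,
                     nested = config$classifier$nested,
                     scope = config$classifier$scope)
  bands <- lapply(names(config$bands), function(bn)
    band_spec(bn, lo = config$bands[[bn]][1], hi = config$bands[[bn]][2]))
  scfg <- sterp_config(n1_hi_ms = config$sterp$n1_hi_ms,
                       n_scales = config$sterp$n_scales)

  subjects <- seq_len(config$n_subjects)
  tables <- list(); counts <- list(); behav <- list()
  erp_amp <- list(); trad_amp <- list(); spectral_all <- list()
  for (s in subjects) {
    gen <- do.call(gen_params,
                   utils::modifyList(config$gen,
                                     list(mw_rate = config$mw_rates[s])))
    for (ti in seq_along(config$tasks)) {
      task <- config$tasks[ti]
      sess <- simulate_session(task, gen,
                               seed = derive_seed(config$seed, s, ti),
                               design_args = config$design)
      lab <- label_session(sess)
      if (nrow(lab$labels) == 0)
        stop("labeling stage: no labeled trials for subject ", s,
             " task ", task)
      ef <- extract_erp_features(lab$epochs, scfg)
      sf <- extract_spectral_features(lab$epochs, bands)
      tab <- assemble_features(ef, sf,
                               data.frame(trial_id = lab$epochs$trials$trial_id,
                                          state = lab$epochs$trials$label))
      tab$subject <- s; tab$task <- task
      key <- paste(s, task)
      tables[[key]] <- tab
      counts[[key]] <- data.frame(subject = s, task = task,
                                  state = names(table(tab$state)),
                                  n = as.integer(table(tab$state)))
      bh <- sess$behavior[sess$behavior$state != "unlabeled", ]
      bh$subject <- s; bh$task <- task
      behav[[key]] <- bh
      ef$subject <- s; ef$task <- task
      ef$state <- lab$epochs$trials$label[match(ef$trial_id,
                                                lab$epochs$trials$trial_id)]
      erp_amp[[key]] <- ef
      tr <- traditional_erp(lab$epochs, lab$epochs$trials$label)$amplitudes
      tr$subject <- s; tr$task <- task
      tr$state <- lab$epochs$trials$label[match(tr$trial_id,
                                                lab$epochs$trials$trial_id)]
      trad_amp[[key]] <- tr
      sf$subject <- s; sf$task <- task
      sf$state <- lab$epochs$trials$label[match(sf$trial_id,
                                                lab$epochs$trials$trial_id)]
      spectral_all[[key]] <- sf
      say("simulated+extracted subject %d %s: %d labeled trials", s, task,
          nrow(tab))
    }
  }
  tick("simulate_extract")

  counts <- do.call(rbind, counts)
  inclusion <- apply_inclusion_criteria(counts, config$min_trials_inclusion)
  included <- as.integer(inclusion$subject[inclusion$included])
  if (length(included) == 0) stop("classification stage: no subject passes inclusion")
  say("inclusion: %d/%d subjects retained", length(included),
      config$n_subjects)
  tick("label_inclusion")

  cls <- list(); preds <- list()
  for (s in included) {
    for (task in config$tasks) {
      tab <- tables[[paste(s, task)]]
      set.seed(derive_seed(config$seed, s, 100 + match(task, config$tasks)))
      res <- loocv(tab, spec)
      cls[[paste(s, task, "loocv")]] <-
        data.frame(subject = s, scheme = paste0("loocv_", task),
                   t(res$metrics), C = res$C, gamma = res$gamma)
      preds[[paste(s, task, "loocv")]] <-
        cbind(subject = s, scheme = paste0("loocv_", task), res$predictions)
    }
    if (isTRUE(config$run_cross_task) && length(config$tasks) == 2) {
      for (dir in 1:2) {
        tr_task <- config$tasks[dir]; te_task <- config$tasks[3 - dir]
        set.seed(derive_seed(config$seed, s, 200 + dir))
        res <- cross_task_predict(tables[[paste(s, tr_task)]],
                                  tables[[paste(s, te_task)]], spec)
        nm <- paste0("cross_", tr_task, "_", te_task)
        cls[[paste(s, nm)]] <- data.frame(subject = s, scheme = nm,
                                          t(res$metrics), C = res$C,
                                          gamma = res$gamma)
        preds[[paste(s, nm)]] <- cbind(subject = s, scheme = nm,
                                       res$predictions)
      }
    }
    say("classified subject %d", s)
  }
  classification <- do.call(rbind, c(cls, list(make.row.names = FALSE)))
  predictions <- do.call(rbind, c(preds, list(make.row.names = FALSE)))
  tick("classify")

  # group tests: accuracy vs chance per scheme
  group_tests <- list()
  for (sch in unique(classification$scheme)) {
    acc <- classification$accuracy[classification$scheme == sch]
    if (length(acc) >= 2 && sd(acc) > 0)
      group_tests[[paste0("accuracy_vs_chance_", sch)]] <-
        one_sample_t(acc, mu = 0.5)
  }

  # bias correlations: mw rate vs sensitivity / specificity (LOOCV schemes)
  mwr <- vapply(included, function(s) {
    tab <- do.call(rbind, lapply(config$tasks,
                                 function(tk) tables[[paste(s, tk)]]))
    mean(tab$state == "mind_wandering")
  }, numeric(1))
  correlations <- NULL
  loocv_schemes <- grep("^loocv_", unique(classification$scheme),
                        value = TRUE)
  corr_rows <- list()
  for (sch in loocv_schemes) {
    sub <- classification[classification$scheme == sch, ]
    sub <- sub[match(included, sub$subject), ]
    for (msr in c("sensitivity", "specificity")) {
      ok <- is.finite(sub[[msr]])
      if (sum(ok) >= 3 && sd(sub[[msr]][ok]) > 0 && sd(mwr[ok]) > 0) {
        sc <- spearman_cor(mwr[ok], sub[[msr]][ok])
        corr_rows[[paste(sch, msr)]] <-
          data.frame(measure = paste(sch, msr), rho = sc["rho"],
                     p = sc["p"], n = sc["n"], row.names = NULL)
      }
    }
  }
  if (length(corr_rows)) correlations <- do.call(rbind, corr_rows)

  # ERP state comparisons across subjects (single-trial and traditional)
  erp_tests <- list()
  subj_means <- function(df, valcol) {
    ag <- stats::aggregate(df[[valcol]],
                           by = list(subject = df$subject,
                                     component = df$component,
                                     channel = df$channel,
                                     state = df$state), FUN = mean)
    names(ag)[5] <- "value"; ag
  }
  for (src in c("single_trial", "traditional")) {
    df <- do.call(rbind, if (src == "single_trial") erp_amp else trad_amp)
    df <- df[df$subject %in% included, ]
    ag <- subj_means(df, "amplitude")
    for (cc in unique(paste(ag$component, ag$channel))) {
      sub <- ag[paste(ag$component, ag$channel) == cc, ]
      w <- merge(sub[sub$state == "mind_wandering", c("subject", "value")],
                 sub[sub$state == "on_task", c("subject", "value")],
                 by = "subject", suffixes = c("_mw", "_ot"))
      if (nrow(w) >= 2 && sd(w$value_mw - w$value_ot) > 0)
        erp_tests[[paste(src, cc)]] <- paired_t_d(w$value_mw, w$value_ot)
    }
  }
  group_tests <- c(group_tests, erp_tests)

  # RM-ANOVA on configured band markers (state x time, within subjects)
  anova_tabs <- list()
  sp_all <- do.call(rbind, spectral_all)
  sp_all <- sp_all[sp_all$subject %in% included, ]
  for (mk in config$anova_markers) {
    sub <- sp_all[sp_all$kind == mk[[1]] & sp_all$band == mk[[2]] &
                    sp_all$site_or_pair == mk[[3]], ]
    if (nrow(sub) == 0) next
    ag <- stats::aggregate(value ~ subject + state + period, sub, mean)
    names(ag)[names(ag) == "period"] <- "time"
    if (length(unique(ag$subject)) >= 2)
      anova_tabs[[paste(mk[[1]], mk[[2]], mk[[3]])]] <- rm_anova_ges(ag)
  }

  # behavioral comparisons
  bh <- do.call(rbind, behav)
  bh <- bh[bh$subject %in% included, ]
  behavioral <- list()
  for (task in config$tasks) {
    b <- bh[bh$task == task, ]
    acc <- stats::aggregate(correct ~ subject + state, b, mean)
    rt <- stats::aggregate(rt_ms ~ subject + state, b[b$correct, ], mean)
    for (msr in c("correct", "rt_ms")) {
      d <- if (msr == "correct") acc else rt
      w <- merge(d[d$state == "mind_wandering", c("subject", msr)],
                 d[d$state == "on_task", c("subject", msr)],
                 by = "subject", suffixes = c("_mw", "_ot"))
      if (nrow(w) >= 2 && sd(w[[2]] - w[[3]]) > 0)
        behavioral[[paste(task, msr)]] <- paired_t_d(w[[2]], w[[3]])
    }
  }
  tick("evaluate")

  report <- build_report(
    classification = classification, group_tests = group_tests,
    correlations = correlations, anova = anova_tabs,
    behavioral = behavioral,
    meta = list(seed = config$seed, n_subjects = config$n_subjects,
                included = included, mw_rates = config$mw_rates,
                timing = timing))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(do.call(rbind, tables), file.path(out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(predictions, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    write.csv(counts, file.path(out_dir, "label_counts.csv"),
              row.names = FALSE)
    jsonlite::write_json(inclusion, file.path(out_dir, "inclusion.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    manifest <- list(package_version = as.character(utils::packageVersion("mweeg")),
                     r_version = R.version.string,
                     config_hash = unname(tools::md5sum(cfg_path)),
                     seed = config$seed, timing = timing)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_report(report, out_dir)
    return(invisible(report))
  }
  report
}
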