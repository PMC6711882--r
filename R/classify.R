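#' Canonical marker (feature) names
#'
#' The 25 classifier markers: 5 single-trial ERP amplitudes (P1 and N1 at
#' A10/B7, P3 at A19), 8 band powers (alpha/theta at the four sites) and
#' 12 ISPC values (alpha/theta for the six site pairs).
#'
#' @param include_ispc drop the ISPC block when `FALSE` (13 markers).
#' @return Character vector of column names in fixed order.
#' @export
marker_names <- function(include_ispc = TRUE) {
  erp <- c("P1_A10", "P1_B7", "N1_A10", "N1_B7", "P3_A19")
  pow <- as.vector(t(outer(c("alpha", "theta"), MWEEG_CHANNELS,
                           function(b, s) paste("pow", b, s, sep = "_"))))
  if (!include_ispc) return(c(erp, pow))
  pr <- mweeg_pairs()
  isp <- as.vector(t(outer(c("alpha", "theta"),
                           paste(pr$x, pr$y, sep = "_"),
                           function(b, p) paste("ispc", b, p, sep = "_"))))
  c(erp, pow, isp)
}

#' Assemble the per-trial feature table
#'
#' Joins single-trial ERP features, spectral features (after-stimulus-onset
#' period by default) and mental-state labels into one wide table: one row
#' per labeled trial, 25 marker columns in the fixed order of
#' [marker_names()], plus `trial_id` and `state`.
#'
#' @param erp_features output of [extract_erp_features()].
#' @param spectral_features output of [extract_spectral_features()].
#' @param labels data frame with `trial_id` and `state`
#'   (`"on_task"`/`"mind_wandering"`).
#' @param period which spectral period feeds the classifier (default
#'   `"aso"`).
#' @param include_ispc set `FALSE` to drop the ISPC block.
#' @return A `feature_table` data frame; `state` is a factor with
#'   mind-wandering as the second (positive) level.
#' @export
assemble_features <- function(erp_features, spectral_features, labels,
                              period = "aso", include_ispc = TRUE) {
  stopifnot(all(c("trial_id", "state") %in% names(labels)))
  ids <- labels$trial_id

  ef <- erp_features
  ef$marker <- paste(ef$component, ef$channel, sep = "_")
  sf <- spectral_features[spectral_features$period == period, , drop = FALSE]
  sf$marker <- ifelse(
    sf$kind == "power",
    paste("pow", sf$band, sf$site_or_pair, sep = "_"),
    paste("ispc", sf$band, gsub("-", "_", sf$site_or_pair), sep = "_"))

  long <- rbind(ef[, c("trial_id", "marker", "amplitude")],
                setNames(sf[, c("trial_id", "marker", "value")],
                         c("trial_id", "marker", "amplitude")))
  cols <- marker_names(include_ispc)
  tab <- data.frame(trial_id = ids)
  for (m in cols) {
    v <- long$amplitude[long$marker == m][match(ids, long$trial_id[long$marker == m])]
    tab[[m]] <- v
  }
  if (anyNA(tab))
    stop("labeled trial missing features: ",
         paste(head(ids[!stats::complete.cases(tab)]), collapse = ", "))
  tab$state <- factor(labels$state, levels = c("on_task", "mind_wandering"))
  if (anyNA(tab$state)) stop("labels must be on_task/mind_wandering")
  class(tab) <- c("feature_table", "data.frame")
  tab
}

feature_cols <- function(tab) setdiff(names(tab), c("trial_id", "state",
                                                    "subject", "task"))

#' Column z-transformation of a feature table
#'
#' Standardizes every marker column to mean 0, SD 1. Constant columns are
#' dropped with a warning. When `stats` is supplied (train-fold statistics)
#' those centers/scales are applied instead of the table's own, which is
#' how held-out rows are transformed under the `train_fold_only` scope.
#'
#' @param tab a feature table.
#' @param stats optional list with `center` and `scale` named vectors.
#' @return The standardized table, with the used statistics attached as
#'   attributes `center` and `scale`.
#' @export
zscore_features <- function(tab, stats = NULL) {
  cols <- feature_cols(tab)
  if (is.null(stats)) {
    center <- vapply(tab[cols], mean, numeric(1))
    scale <- vapply(tab[cols], sd, numeric(1))
    const <- scale == 0 | !is.finite(scale)
    if (any(const)) {
      warning("dropping zero-variance column(s): ",
              paste(cols[const], collapse = ", "))
      tab <- tab[, !names(tab) %in% cols[const], drop = FALSE]
      cols <- cols[!const]; center <- center[!const]; scale <- scale[!const]
    }
  } else {
    center <- stats$center[cols]; scale <- stats$scale[cols]
  }
  for (m in cols) tab[[m]] <- (tab[[m]] - center[m]) / scale[m]
  attr(tab, "center") <- center
  attr(tab, "scale") <- scale
  tab
}

#' Random oversampling to class balance
#'
#' Duplicates minority-class rows, sampled with replacement, until both
#' classes have equal counts; the majority class is untouched. Uses the
#' current RNG stream. Only ever applied to training data.
#'
#' @param tab a feature table with a two-level `state` factor.
#' @return The balanced table.
#' @export
oversample <- function(tab) {
  cnt <- table(tab$state)
  if (any(cnt == 0)) stop("both classes must be present")
  if (cnt[1] == cnt[2]) return(tab)
  minority <- names(cnt)[which.min(cnt)]
  idx <- which(tab$state == minority)
  extra <- idx[sample.int(length(idx), max(cnt) - min(cnt), replace = TRUE)]
  rbind(tab, tab[extra, , drop = FALSE])
}

#' Classifier specification
#'
#' @param C_grid,gamma_grid hyperparameter grids for the RBF-SVM search
#'   (defaults: `C` over `2^(-5..15)`, `gamma` over `2^(-15..3)`, steps of
#'   two octaves).
#' @param inner_folds folds of the inner cross-validation used by the grid
#'   search.
#' @param nested if `TRUE`, the grid search is re-run inside every LOOCV
#'   training fold; if `FALSE` (default) it is run once per model on the
#'   full data, as when tuning once per subject.
#' @param scope normalization scope: `"global_per_subject_task"` z-scores
#'   the whole table once (the table is one subject and task);
#'   `"train_fold_only"` re-estimates the statistics inside each training
#'   fold and applies them to the held-out row.
#' @return A `model_spec` list.
#' @export
model_spec <- function(C_grid = 2^seq(-5, 15, 2),
                       gamma_grid = 2^seq(-15, 3, 2),
                       inner_folds = 5, nested = FALSE,
                       scope = c("global_per_subject_task",
                                 "train_fold_only")) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0,
            all(C_grid > 0), all(gamma_grid > 0))
  scope <- match.arg(scope)
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 inner_folds = inner_folds, nested = nested, scope = scope),
            class = "model_spec")
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Inner stratified k-fold cross-validation over the `C x gamma` grid
#' (training folds are oversampled to balance); returns the point with the
#' highest inner accuracy, ties broken toward smaller `C`, then smaller
#' `gamma`.
#'
#' @param tab feature table (already normalized).
#' @param spec a [model_spec()].
#' @return list `C`, `gamma`, `accuracy` (inner-CV accuracy of the
#'   winner), `grid` (full results).
#' @export
grid_search <- function(tab, spec = model_spec()) {
  cols <- feature_cols(tab)
  if (min(table(tab$state)) < 2) stop("need >= 2 rows per class")
  k <- min(spec$inner_folds, min(table(tab$state)))
  fold <- integer(nrow(tab))
  for (cl in levels(tab$state)) {
    idx <- which(tab$state == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  grid <- expand.grid(C = spec$C_grid, gamma = spec$gamma_grid)
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- oversample(tab[fold != f, , drop = FALSE])
      fit <- rbf_svm(as.matrix(tr[cols]), tr$state,
                     C = grid$C[g], gamma = grid$gamma[g])
      pr <- predict(fit, as.matrix(tab[fold == f, cols, drop = FALSE]))
      correct <- correct + sum(pr == tab$state[fold == f])
    }
    grid$accuracy[g] <- correct / nrow(tab)
  }
  ord <- order(-grid$accuracy, grid$C, grid$gamma)
  best <- grid[ord[1], ]
  list(C = best$C, gamma = best$gamma, accuracy = best$accuracy, grid = grid)
}

#' Leave-one-out cross-validation of the per-subject RBF-SVM
#'
#' Each trial is predicted by a model trained on all remaining trials of
#' the same subject and task; random oversampling to class balance is
#' applied inside every training fold (never to the held-out trial).
#' Under the default scope the table is z-scored once up front and
#' hyperparameters come from a single [grid_search()] on the full table;
#' `scope = "train_fold_only"` (with `nested = TRUE` if desired) re-does
#' normalization (and tuning) inside each fold, at a leakage-free price.
#'
#' @param tab raw (un-normalized) feature table for one subject and task.
#' @param spec a [model_spec()].
#' @return list with `predictions` (data frame `trial_id`, `true`,
#'   `predicted`), `metrics` (accuracy/sensitivity/specificity),
#'   `C`, `gamma`.
#' @export
loocv <- function(tab, spec = model_spec()) {
  if (min(table(tab$state)) < 1 || nlevels(droplevels(tab$state)) < 2)
    stop("need both classes present")
  cols0 <- feature_cols(tab)
  n <- nrow(tab)
  global <- spec$scope == "global_per_subject_task"
  if (global) tab <- zscore_features(tab)
  cols <- feature_cols(tab)

  C <- gamma <- NA_real_
  if (!spec$nested) {
    if (length(spec$C_grid) == 1 && length(spec$gamma_grid) == 1) {
      C <- spec$C_grid; gamma <- spec$gamma_grid
    } else {
      gs <- grid_search(if (global) tab else zscore_features(tab), spec)
      C <- gs$C; gamma <- gs$gamma
    }
  }
  pred <- factor(rep(NA_character_, n), levels = levels(tab$state))
  for (i in seq_len(n)) {
    train <- tab[-i, , drop = FALSE]
    test <- tab[i, , drop = FALSE]
    if (!global) {
      train <- zscore_features(train)
      test <- zscore_features(test, stats = list(
        center = attr(train, "center"), scale = attr(train, "scale")))
      test <- test[, names(train), drop = FALSE]
    }
    present <- names(which(table(train$state) > 0))
    if (length(present) == 1) {      # degenerate fold: only class wins
      pred[i] <- present
      next
    }
    if (spec$nested) {
      gs <- grid_search(train, spec)
      C <- gs$C; gamma <- gs$gamma
    }
    train <- oversample(train)
    fcols <- feature_cols(train)
    fit <- rbf_svm(as.matrix(train[fcols]), train$state, C = C, gamma = gamma)
    pred[i] <- predict(fit, as.matrix(test[fcols]))
  }
  list(predictions = data.frame(trial_id = tab$trial_id, true = tab$state,
                                predicted = pred),
       metrics = confusion_metrics(tab$state, pred),
       C = C, gamma = gamma)
}

#' Across-task transfer prediction
#'
#' Fits one model on all (oversampled) trials of the training task and
#' evaluates it on every trial of the other task. Both tables are
#' normalized within their own task (same scope as the within-task
#' analysis).
#'
#' @param train_tab,test_tab feature tables of the two tasks (identical
#'   marker columns).
#' @param spec a [model_spec()].
#' @return list with `predictions`, `metrics`, `C`, `gamma`.
#' @export
cross_task_predict <- function(train_tab, test_tab, spec = model_spec()) {
  if (!identical(feature_cols(train_tab), feature_cols(test_tab)))
    stop("marker columns differ between tasks")
  train <- zscore_features(train_tab)
  test <- zscore_features(test_tab)
  test <- test[, names(train), drop = FALSE]
  gs <- grid_search(train, spec)
  train <- oversample(train)
  cols <- feature_cols(train)
  fit <- rbf_svm(as.matrix(train[cols]), train$state, C = gs$C,
                 gamma = gs$gamma)
  pred <- predict(fit, as.matrix(test[cols]))
  list(predictions = data.frame(trial_id = test$trial_id, true = test$state,
                                predicted = pred),
       metrics = confusion_metrics(test$state, pred),
       C = gs$C, gamma = gs$gamma)
}

#' Single-marker models
#'
#' To rank the contribution of each EEG marker, a separate RBF-SVM is
#' trained on every marker alone (plus the full model), on the pooled
#' normalized data of both tasks, each with its own grid search and
#' validated by LOOCV.
#'
#' @param pooled_tab feature table pooling both tasks, already normalized
#'   within task (e.g. `rbind` of two [zscore_features()] outputs).
#' @param spec a [model_spec()]; the pooled table is not re-normalized
#'   (scope is forced to global with an identity transform).
#' @param markers which markers to test (default: all feature columns).
#' @return Data frame: one row per marker plus `"full_model"`, with
#'   accuracy, sensitivity, specificity, chosen `C` and `gamma`.
#' @export
single_marker_models <- function(pooled_tab, spec = model_spec(),
                                 markers = feature_cols(pooled_tab)) {
  keep <- c("trial_id", "state")
  run_one <- function(cols, label) {
    sub <- pooled_tab[, c(keep, cols), drop = FALSE]
    # already normalized: reuse loocv machinery without re-scaling
    res <- loocv_prenormalized(sub, spec)
    data.frame(marker = label, accuracy = res$metrics["accuracy"],
               sensitivity = res$metrics["sensitivity"],
               specificity = res$metrics["specificity"],
               C = res$C, gamma = res$gamma, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  out <- lapply(markers, function(m) run_one(m, m))
  out[[length(out) + 1L]] <- run_one(markers, "full_model")
  do.call(rbind, out)
}

# LOOCV on a table that is already normalized (pooled-task path)
loocv_prenormalized <- function(tab, spec) {
  cols <- feature_cols(tab)
  gs <- grid_search(tab, spec)
  n <- nrow(tab)
  pred <- factor(rep(NA_character_, n), levels = levels(tab$state))
  for (i in seq_len(n)) {
    train <- oversample(tab[-i, , drop = FALSE])
    fit <- rbf_svm(as.matrix(train[cols]), train$state, C = gs$C,
                   gamma = gs$gamma)
    pred[i] <- predict(fit, as.matrix(tab[i, cols, drop = FALSE]))
  }
  list(predictions = data.frame(trial_id = tab$trial_id, true = tab$state,
                                predicted = pred),
       metrics = confusion_metrics(tab$state, pred),
       C = gs$C, gamma = gs$gamma)
}
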