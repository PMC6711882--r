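#' Classification metrics from a confusion table
#'
#' Mind-wandering is the positive class: sensitivity is the proportion of
#' mind-wandering trials detected as such (true positive rate),
#' specificity the proportion of on-task trials detected as such. When a
#' class is absent from the true labels the corresponding metric is
#' undefined and reported as `NA` (never 0), so that group averages are
#' not biased.
#'
#' @param truth,pred vectors of true and predicted labels.
#' @param positive label of the positive class.
#' @param negative label of the negative class (default: the other level).
#' @return Named numeric: `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(truth, pred, positive = "mind_wandering",
                              negative = NULL) {
  if (length(truth) != length(pred)) stop("length mismatch")
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(negative)) {
    negative <- setdiff(unique(c(truth, pred)), positive)
    if (length(negative) != 1) negative <- "on_task"
  }
  is_pos <- truth == positive
  is_neg <- truth == negative
  c(accuracy = mean(pred == truth),
    sensitivity = if (any(is_pos)) mean(pred[is_pos] == positive) else NA_real_,
    specificity = if (any(is_neg)) mean(pred[is_neg] == negative) else NA_real_)
}

#' One-sample t test with Cohen's d
#'
#' Tests the mean of `values` against `mu` (two-sided by default; used for
#' testing classification accuracy against the 0.5 chance level).
#' `d = (mean - mu) / sd`.
#'
#' @param values numeric vector, `n >= 2`.
#' @param mu null value.
#' @param alternative passed to [stats::t.test()].
#' @return Named numeric: `t`, `df`, `p`, `d`, `mean`.
#' @export
one_sample_t <- function(values, mu = 0.5, alternative = "two.sided") {
  if (length(values) < 2) stop("need n >= 2")
  if (sd(values) == 0) stop("zero variance")
  tt <- t.test(values, mu = mu, alternative = alternative)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, d = (mean(values) - mu) / sd(values),
    mean = mean(values))
}

#' Paired t test with Cohen's d
#'
#' Test on the paired differences `a - b`; `d = mean(diff) / sd(diff)`.
#'
#' @param a,b paired numeric vectors of equal length (`n >= 2`).
#' @param alternative passed to [stats::t.test()].
#' @return Named numeric: `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
paired_t_d <- function(a, b, alternative = "two.sided") {
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  if (length(d) < 2) stop("need n >= 2")
  if (sd(d) == 0) stop("zero-variance differences")
  tt <- t.test(a, b, paired = TRUE, alternative = alternative)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, d = mean(d) / sd(d), mean_diff = mean(d))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value by the
#' t-approximation (two-sided).
#'
#' @param x,y numeric vectors (`n >= 3`).
#' @return Named numeric: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Declares the paired difference statistically equivalent to zero when
#' both one-sided tests against the bounds reject at `alpha`, i.e. when
#' the TOST confidence interval (the two-sided `1 - 2 alpha` interval)
#' lies entirely within the bounds.
#'
#' @param diffs paired differences (`n >= 2`).
#' @param bounds either a single positive number (symmetric `+/- bounds`)
#'   or `c(lo, hi)`.
#' @param alpha one-sided level (default 0.05, giving the 90% two-sided /
#'   "95% TOST" interval).
#' @return list: `mean_diff`, `ci` (TOST interval), `p_lower`, `p_upper`,
#'   `equivalent`, `bounds`.
#' @export
tost_equivalence <- function(diffs, bounds, alpha = 0.05) {
  if (length(diffs) < 2) stop("need n >= 2")
  if (sd(diffs) == 0) stop("zero variance")
  if (length(bounds) == 1) bounds <- c(-abs(bounds), abs(bounds))
  stopifnot(bounds[1] < bounds[2])
  n <- length(diffs); m <- mean(diffs); se <- sd(diffs) / sqrt(n)
  df <- n - 1
  p_lower <- pt((m - bounds[1]) / se, df, lower.tail = FALSE)
  p_upper <- pt((m - bounds[2]) / se, df, lower.tail = TRUE)
  ci <- m + c(-1, 1) * qt(1 - alpha, df) * se
  list(mean_diff = m, ci = ci, p_lower = p_lower, p_upper = p_upper,
       equivalent = p_lower < alpha && p_upper < alpha, bounds = bounds)
}

#' Two-way repeated-measures ANOVA with generalized eta squared
#'
#' A 2 x 2 fully within-subject design with factors state (mind-wandering
#' vs on-task) and time (baseline vs after stimulus onset). Each effect
#' is tested against its own subject-by-effect interaction;
#' effect sizes use the generalized eta squared of Olejnik & Algina:
#' `SS_effect / (SS_effect + sum of all subject-related SS)`.
#'
#' @param df long data frame with columns `subject`, `state`, `time`,
#'   `value`; one observation per cell (replicates are averaged).
#' @return Data frame: `effect`, `df1`, `df2`, `F`, `p`, `ges`.
#' @export
rm_anova_ges <- function(df) {
  stopifnot(all(c("subject", "state", "time", "value") %in% names(df)))
  df$subject <- factor(df$subject); df$state <- factor(df$state)
  df$time <- factor(df$time)
  if (nlevels(df$state) != 2 || nlevels(df$time) != 2)
    stop("state and time must each have exactly two levels")
  cells <- stats::aggregate(value ~ subject + state + time, df, mean)
  n <- nlevels(df$subject)
  if (nrow(cells) != n * 4) stop("design not complete/balanced")

  y <- cells$value
  m <- mean(y)
  mi <- tapply(y, cells$subject, mean)           # subject
  mj <- tapply(y, cells$state, mean)             # state
  mk <- tapply(y, cells$time, mean)              # time
  mij <- tapply(y, list(cells$subject, cells$state), mean)
  mik <- tapply(y, list(cells$subject, cells$time), mean)
  mjk <- tapply(y, list(cells$state, cells$time), mean)

  i <- as.integer(cells$subject); j <- as.integer(cells$state)
  k <- as.integer(cells$time)
  ss_subj <- 4 * sum((mi - m)^2)
  ss_A <- 2 * n * sum((mj - m)^2)
  ss_B <- 2 * n * sum((mk - m)^2)
  ss_AB <- n * sum((mjk - outer(mj - m, mk - m, "+") - m)^2)
  ss_AS <- 2 * sum((mij - outer(mi, mj, "+") + m)^2)
  ss_BS <- 2 * sum((mik - outer(mi, mk, "+") + m)^2)
  fitted <- mij[cbind(i, j)] + mik[cbind(i, k)] + mjk[cbind(j, k)] -
    mi[i] - mj[j] - mk[k] + m
  ss_ABS <- sum((y - fitted)^2)

  denom_err <- ss_subj + ss_AS + ss_BS + ss_ABS
  mk_row <- function(effect, ss, ss_err, df1, df2) {
    Fv <- (ss / df1) / (ss_err / df2)
    data.frame(effect = effect, df1 = df1, df2 = df2, F = Fv,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               ges = ss / (ss + denom_err), stringsAsFactors = FALSE)
  }
  rbind(mk_row("state", ss_A, ss_AS, 1, n - 1),
        mk_row("time", ss_B, ss_BS, 1, n - 1),
        mk_row("state:time", ss_AB, ss_ABS, 1, n - 1))
}

#' Consolidate pipeline outputs into an evaluation report
#'
#' @param classification data frame of per-subject, per-scheme metrics
#'   (must be non-empty; columns `subject`, `task`/`scheme`, `accuracy`,
#'   `sensitivity`, `specificity`).
#' @param group_tests named list of group-level test results.
#' @param correlations optional mind-wandering-rate bias correlations.
#' @param markers optional single-marker ranking.
#' @param anova optional list of RM-ANOVA tables.
#' @param behavioral optional behavioral comparison results.
#' @param meta run metadata (seeds, config hash, ...).
#' @return An `eval_report` list.
#' @export
build_report <- function(classification, group_tests = list(),
                         correlations = NULL, markers = NULL,
                         anova = NULL, behavioral = NULL, meta = list()) {
  if (is.null(classification) || nrow(classification) == 0)
    stop("classification section is required")
  structure(list(classification = classification, group_tests = group_tests,
                 correlations = correlations, markers = markers,
                 anova = anova, behavioral = behavioral, meta = meta),
            class = "eval_report")
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (the full structure) and a human-readable
#' `report.md` summary; tabular sections are additionally written as CSV.
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  write.csv(report$classification, file.path(dir, "classification.csv"),
            row.names = FALSE)
  if (!is.null(report$markers))
    write.csv(report$markers, file.path(dir, "single_markers.csv"),
              row.names = FALSE)
  md <- c("# Mind-wandering detection report", "",
          "## Per-subject classification (mean by scheme)", "")
  agg <- stats::aggregate(accuracy ~ scheme, report$classification, mean)
  md <- c(md, sprintf("- %s: mean accuracy %.3f", agg$scheme, agg$accuracy))
  if (length(report$group_tests)) {
    md <- c(md, "", "## Group tests", "")
    for (nm in names(report$group_tests)) {
      gt <- report$group_tests[[nm]]
      if (all(c("t", "p") %in% names(gt)))
        md <- c(md, sprintf("- %s: t(%g) = %.2f, p = %.3g", nm,
                            gt["df"], gt["t"], gt["p"]))
    }
  }
  if (!is.null(report$correlations)) {
    md <- c(md, "", "## Mind-wandering-rate bias correlations", "")
    cr <- report$correlations
    md <- c(md, sprintf("- %s: rho = %.2f, p = %.3g", cr$measure, cr$rho,
                        cr$p))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
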