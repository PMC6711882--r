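test_that("confusion metrics treat mind-wandering as the positive class", {
  mw <- "mind_wandering"; ot <- "on_task"
  expect_equal(confusion_metrics(c(mw, ot), c(mw, ot)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  # everything called MW: perfect sensitivity, zero specificity
  expect_equal(confusion_metrics(c(mw, mw, ot, ot), rep(mw, 4)),
               c(accuracy = 0.5, sensitivity = 1, specificity = 0))
  # hand-counted mixed case
  expect_equal(confusion_metrics(c(mw, mw, ot, ot), c(mw, ot, ot, ot)),
               c(accuracy = 0.75, sensitivity = 0.5, specificity = 1))
  # absent class -> NA, never zero
  m <- confusion_metrics(c(ot, ot), c(ot, mw))
  expect_true(is.na(m["sensitivity"]))
  expect_equal(unname(m["specificity"]), 0.5)
  expect_error(confusion_metrics(c(mw), c(mw, ot)), "mismatch")
})

test_that("one-sample t matches a brute-force formula evaluation", {
  v <- c(0.58, 0.61, 0.55, 0.65, 0.62, 0.59)
  res <- one_sample_t(v, mu = 0.5)
  # independent evaluation from first principles
  t_ref <- (mean(v) - 0.5) / (sd(v) / sqrt(6))
  expect_equal(unname(res["t"]), t_ref, tolerance = 1e-12)
  expect_equal(unname(res["df"]), 5)
  expect_equal(unname(res["p"]), 2 * pt(-abs(t_ref), 5), tolerance = 1e-12)
  expect_equal(unname(res["d"]), (mean(v) - 0.5) / sd(v), tolerance = 1e-12)

  sym <- 0.5 + c(-0.1, 0.1, -0.2, 0.2)
  expect_equal(unname(one_sample_t(sym, 0.5)["t"]), 0)
  expect_error(one_sample_t(rep(0.6, 5), 0.5), "zero variance")
  expect_error(one_sample_t(0.6, 0.5), "n >= 2")
})

test_that("paired t with Cohen's d follows the difference-score formulas", {
  a <- c(444, 460, 430, 455, 448)
  b <- c(462, 470, 450, 461, 459)
  res <- paired_t_d(a, b)
  d <- a - b
  expect_equal(unname(res["t"]), mean(d) / (sd(d) / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(unname(res["d"]), mean(d) / sd(d), tolerance = 1e-12)
  expect_lt(res["t"], 0)
  # zero-variance differences (including a == b) cannot be tested
  expect_error(paired_t_d(b, b), "zero-variance")
  expect_error(paired_t_d(1:4, 0:3), "zero-variance")
})

test_that("Spearman correlation reproduces hand-computed ranks", {
  expect_equal(unname(spearman_cor(1:6, (1:6)^3)["rho"]), 1)
  expect_equal(unname(spearman_cor(1:6, -(1:6))["rho"]), -1)
  # 5-point set with a tie, hand-ranked: x ranks 1,2.5,2.5,4,5
  x <- c(10, 20, 20, 30, 40)
  y <- c(3, 1, 4, 2, 5)
  rho_hand <- cor(c(1, 2.5, 2.5, 4, 5), c(3, 1, 4, 2, 5))
  expect_equal(unname(spearman_cor(x, y)["rho"]), rho_hand,
               tolerance = 1e-12)
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
})

test_that("TOST equivalence reproduces the two one-sided tests", {
  set.seed(60)
  diffs <- rnorm(20, 0, 0.01)
  res <- tost_equivalence(diffs, bounds = 0.05)
  expect_true(res$equivalent)
  expect_true(res$ci[1] > -0.05 && res$ci[2] < 0.05)
  # brute-force the one-sided p-values with t.test
  p_lo <- t.test(diffs, mu = -0.05, alternative = "greater")$p.value
  p_hi <- t.test(diffs, mu = 0.05, alternative = "less")$p.value
  expect_equal(res$p_lower, p_lo, tolerance = 1e-12)
  expect_equal(res$p_upper, p_hi, tolerance = 1e-12)
  # the TOST interval is the 90% two-sided CI
  ci_ref <- t.test(diffs, conf.level = 0.9)$conf.int
  expect_equal(res$ci, as.numeric(ci_ref), tolerance = 1e-12)

  far <- rnorm(20, 0.4, 0.01)
  expect_false(tost_equivalence(far, bounds = 0.05)$equivalent)
  expect_error(tost_equivalence(rep(0, 5), 0.05), "zero variance")
})

test_that("the repeated-measures ANOVA matches aov and bounds its effect sizes", {
  set.seed(61)
  n <- 12
  df <- expand.grid(subject = factor(1:n),
                    state = c("mind_wandering", "on_task"),
                    time = c("baseline", "aso"))
  df$value <- rnorm(nrow(df)) + rep(rnorm(n), 4) +
    ifelse(df$state == "mind_wandering", 0.8, 0)

  res <- rm_anova_ges(df)
  fit <- summary(stats::aov(value ~ state * time +
                              Error(subject / (state * time)), df))
  f_ref <- c(fit[["Error: subject:state"]][[1]]["state", "F value"],
             fit[["Error: subject:time"]][[1]]["time", "F value"],
             fit[["Error: subject:state:time"]][[1]]["state:time", "F value"])
  expect_equal(res$F, unname(f_ref), tolerance = 1e-10)
  expect_gt(res$F[res$effect == "state"], res$F[res$effect == "state:time"])
  expect_lt(res$p[res$effect == "state"], 0.05)

  # generalized eta squared stays inside [0, 1] on arbitrary data
  for (seed in 1:20) {
    set.seed(seed)
    df$value <- rnorm(nrow(df))
    r <- rm_anova_ges(df)
    expect_true(all(r$ges >= 0 & r$ges <= 1))
    expect_true(all(r$F >= 0))
    expect_true(all(r$p >= 0 & r$p <= 1))
  }
  expect_error(rm_anova_ges(df[-1, ]), "complete")
})

test_that("reports require classification results and serialize deterministically", {
  cls <- data.frame(subject = 1:3, scheme = "loocv_SART",
                    accuracy = c(0.7, 0.65, 0.72),
                    sensitivity = c(0.6, 0.5, 0.7),
                    specificity = c(0.8, 0.75, 0.74))
  rep1 <- build_report(cls, group_tests = list(
    accuracy_vs_chance_loocv_SART = one_sample_t(cls$accuracy, 0.5)))
  expect_s3_class(rep1, "eval_report")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  write_report(rep1, d2)
  expect_true(file.exists(file.path(d1, "report.json")))
  expect_true(file.exists(file.path(d1, "report.md")))
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_error(build_report(cls[0, ]), "required")
})
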