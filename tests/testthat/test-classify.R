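make_session_table <- function(seed, mw_rate = 0.5, task = "SART",
                               n_probes = 10) {
  sess <- simulate_session(task, gen_params(mw_rate = mw_rate, leak = 0),
                           seed = seed,
                           design_args = list(n_probes = n_probes))
  lab <- label_session(sess)
  ef <- extract_erp_features(lab$epochs)
  sf <- extract_spectral_features(lab$epochs)
  assemble_features(ef, sf,
                    data.frame(trial_id = lab$epochs$trials$trial_id,
                               state = lab$epochs$trials$label))
}

test_that("the feature table holds the 25 documented markers", {
  tab <- make_session_table(50)
  cols <- setdiff(names(tab), c("trial_id", "state"))
  expect_length(cols, 25)
  expect_identical(cols, marker_names())
  # the parietal - left occipital theta coherence marker is present
  expect_true("ispc_theta_A10_A19" %in% cols)
  expect_false(anyNA(tab))
  expect_identical(levels(tab$state), c("on_task", "mind_wandering"))
  expect_length(marker_names(include_ispc = FALSE), 13)

  # a labeled trial without features is an error
  sess <- simulate_session("SART", gen_params(), seed = 51,
                           design_args = list(n_probes = 6))
  lab <- label_session(sess)
  ef <- extract_erp_features(lab$epochs)
  sf <- extract_spectral_features(lab$epochs)
  bad_labels <- data.frame(trial_id = c(lab$epochs$trials$trial_id, 99999),
                           state = c(lab$epochs$trials$label, "on_task"))
  expect_error(assemble_features(ef, sf, bad_labels), "missing features")
})

test_that("z-transformation standardizes, drops constants, applies train stats", {
  tab <- data.frame(trial_id = 1:3, f1 = c(1, 2, 3), f2 = c(5, 5, 5),
                    state = factor(c("on_task", "mind_wandering", "on_task"),
                                   levels = c("on_task", "mind_wandering")))
  expect_warning(z <- zscore_features(tab), "zero-variance")
  expect_false("f2" %in% names(z))
  expect_equal(z$f1, c(-1, 0, 1))

  # held-out rows use training statistics
  train <- data.frame(trial_id = 1:4, f1 = c(0, 2, 4, 6),
                      state = factor(rep(c("on_task", "mind_wandering"), 2)))
  ztr <- zscore_features(train)
  test <- data.frame(trial_id = 5, f1 = 3,
                     state = factor("on_task",
                                    levels = levels(train$state)))
  zte <- zscore_features(test, stats = list(center = attr(ztr, "center"),
                                            scale = attr(ztr, "scale")))
  expect_equal(zte$f1, (3 - 3) / sd(c(0, 2, 4, 6)))
})

test_that("oversampling balances classes without touching the majority", {
  mk <- function(n_mw, n_ot) {
    data.frame(trial_id = seq_len(n_mw + n_ot),
               f1 = rnorm(n_mw + n_ot),
               state = factor(rep(c("mind_wandering", "on_task"),
                                  c(n_mw, n_ot)),
                              levels = c("on_task", "mind_wandering")))
  }
  set.seed(52)
  b <- oversample(mk(70, 30))
  expect_equal(as.vector(table(b$state)), c(70, 70))
  expect_identical(b[b$state == "mind_wandering" &
                       as.integer(rownames(b)) <= 100, "trial_id"], 1:70)

  even <- mk(50, 50)
  expect_identical(oversample(even), even)

  b2 <- oversample(mk(10, 1))
  expect_equal(as.vector(table(b2$state)), c(10, 10))
  expect_true(all(b2$trial_id[b2$state == "on_task"] == 11))

  one_class <- mk(5, 0)
  one_class$state <- droplevels(one_class$state)
  expect_error(oversample(mk(5, 0)), "both classes")
})

test_that("grid search picks the best point with deterministic tie-breaks", {
  tab <- make_blob_table(20, 4, sep = 4, seed = 53)
  single <- model_spec(C_grid = 8, gamma_grid = 0.125)
  set.seed(1)
  gs <- grid_search(tab, single)
  expect_equal(gs$C, 8)
  expect_equal(gs$gamma, 0.125)

  spec <- model_spec(C_grid = 2^c(0, 2), gamma_grid = 2^c(-4, -2))
  set.seed(2); g1 <- grid_search(tab, spec)
  set.seed(2); g2 <- grid_search(tab, spec)
  expect_identical(g1, g2)            # reproducible under a seed
  expect_equal(g1$accuracy, 1)        # separable blobs
  # ties go to the smallest C then smallest gamma
  top <- g1$grid[g1$grid$accuracy == max(g1$grid$accuracy), ]
  expect_equal(g1$C, min(top$C))
})

test_that("LOOCV predicts separable data and satisfies the metrics identity", {
  tab <- make_blob_table(15, 4, sep = 4, seed = 54)
  spec <- model_spec(C_grid = 1, gamma_grid = 0.25)
  set.seed(3)
  res <- loocv(tab, spec)
  expect_gte(res$metrics["accuracy"], 0.95)
  expect_equal(nrow(res$predictions), 30)

  n_mw <- sum(tab$state == "mind_wandering")
  n_ot <- sum(tab$state == "on_task")
  expect_equal(unname(res$metrics["accuracy"]),
               unname((res$metrics["sensitivity"] * n_mw +
                         res$metrics["specificity"] * n_ot) / (n_mw + n_ot)))

  # smallest valid input: one row per class
  tiny <- make_blob_table(1, 3, sep = 5, seed = 55)
  set.seed(4)
  res_tiny <- loocv(tiny, spec)
  expect_equal(nrow(res_tiny$predictions), 2)

  # train_fold_only scope runs and scores comparably
  set.seed(5)
  res_tf <- loocv(tab, model_spec(C_grid = 1, gamma_grid = 0.25,
                                  scope = "train_fold_only"))
  expect_gte(res_tf$metrics["accuracy"], 0.95)
})

test_that("across-task transfer matches within-task accuracy for exchangeable tasks", {
  tab_a <- make_session_table(56, task = "SART", n_probes = 12)
  tab_b <- make_session_table(57, task = "VS", n_probes = 12)
  spec <- model_spec(C_grid = 1, gamma_grid = 1 / 25)
  set.seed(6)
  cross <- cross_task_predict(tab_a, tab_b, spec)
  expect_equal(nrow(cross$predictions), nrow(tab_b))
  set.seed(6)
  within_b <- loocv(tab_b, spec)
  expect_lt(abs(cross$metrics["accuracy"] - within_b$metrics["accuracy"]),
            0.15)

  # destroying the test task's features drops transfer to chance
  tab_shuf <- tab_b
  set.seed(7)
  tab_shuf$state <- sample(tab_shuf$state)
  shuf <- cross_task_predict(tab_a, tab_shuf, spec)
  expect_lt(abs(shuf$metrics["accuracy"] - 0.5), 0.2)

  expect_error(cross_task_predict(tab_a, tab_a[, -3], spec), "differ")
})

test_that("single-marker models rank an effect-bearing marker above chance", {
  tab <- make_session_table(58, n_probes = 14)
  pooled <- zscore_features(tab)
  spec <- model_spec(C_grid = 1, gamma_grid = 1)
  set.seed(8)
  res <- single_marker_models(pooled, spec,
                              markers = c("pow_alpha_A19", "P3_A19",
                                          "pow_theta_C21"))
  expect_equal(nrow(res), 4)
  expect_equal(res$marker[4], "full_model")
  expect_gt(res$accuracy[res$marker == "pow_alpha_A19"], 0.5)
})
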