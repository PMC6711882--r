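test_that("mexican hat evaluates its closed form", {
  expect_identical(mexican_hat(0), 1)
  expect_equal(mexican_hat(0.25), 0)
  expect_equal(mexican_hat(0.5), -3 * exp(-2), tolerance = 1e-14)
  expect_equal(mexican_hat(-0.5), mexican_hat(0.5))  # even symmetry
})

test_that("wavelet cross-covariance is linear and matches the direct sum", {
  t_ms <- epoch_time_axis()
  sg <- exp(seq(log(200), log(1400), length.out = 6))
  tg <- t_ms[t_ms >= 250 & t_ms <= 600]

  z <- wavelet_cross_covariance(numeric(length(t_ms)), t_ms, sg, tg)
  expect_true(all(z$W == 0))

  set.seed(8)
  f <- rnorm(length(t_ms))
  m_fft <- wavelet_cross_covariance(f, t_ms, sg, tg, method = "fft")
  m_dir <- wavelet_cross_covariance(f, t_ms, sg, tg, method = "direct")
  expect_lt(max(abs(m_fft$W - m_dir$W)) / max(abs(m_dir$W)), 1e-10)

  # scaling equivariance
  m3 <- wavelet_cross_covariance(3 * f, t_ms, sg, tg)
  expect_equal(m3$W, 3 * m_fft$W, tolerance = 1e-12)

  expect_error(wavelet_cross_covariance(numeric(0), numeric(0), sg, tg),
               "empty")
  expect_error(wavelet_cross_covariance(f, t_ms, c(-100, 200), tg),
               "positive")
})

test_that("an embedded template is recovered at its own lag and scale", {
  t_ms <- epoch_time_axis()
  f <- 5 * mexican_hat((t_ms - 450) / 300)
  sg <- exp(seq(log(200), log(1400), length.out = 32))
  tg <- t_ms[t_ms >= 250 & t_ms <= 600]
  m <- wavelet_cross_covariance(f, t_ms, sg, tg)
  # brute-force argmax over the whole grid
  idx <- which(m$W == max(m$W), arr.ind = TRUE)
  dt <- 1000 / 256
  expect_lte(abs(m$t_grid[idx[2]] - 450), dt)
  s_step <- exp(diff(log(range(sg))) / 31)
  expect_lte(m$s_grid[idx[1]] / 300, s_step)
  expect_gte(m$s_grid[idx[1]] / 300, 1 / s_step)
})

test_that("component detection flags interior extremes and degraded maps", {
  t_ms <- epoch_time_axis()
  sg <- exp(seq(log(200), log(1400), length.out = 16))
  tg <- t_ms[t_ms >= 250 & t_ms <= 600]

  f <- 5 * mexican_hat((t_ms - 450) / 300)
  m <- wavelet_cross_covariance(f, t_ms, sg, tg)
  det <- detect_component(m, c(250, 600), "+")
  expect_equal(det$found, "ok")
  expect_lte(abs(det$t_ms - 450), 1000 / 256)
  expect_gt(det$amplitude, 0)

  z <- wavelet_cross_covariance(numeric(length(t_ms)), t_ms, sg, tg)
  dz <- detect_component(z, c(250, 600), "+")
  expect_equal(dz$amplitude, 0)
  expect_equal(dz$found, "degraded")

  # negative component found by "-" polarity with negative amplitude
  dn <- detect_component(wavelet_cross_covariance(-f, t_ms, sg, tg),
                         c(250, 600), "-")
  expect_lt(dn$amplitude, 0)
  expect_equal(dn$found, "ok")

  expect_error(detect_component(m, c(2000, 3000), "+"), "window")
})

test_that("per-trial feature extraction yields 5 features and the designed P3 effect", {
  set.seed(9)
  d <- task_design("SART", n_blocks = 2, n_probes = 10)
  gen <- quiet_gen(mw_rate = 0.5, leak = 0)
  st <- simulate_states(d, gen)
  ep <- synthesize_epochs(st, d, gen)
  feats <- extract_erp_features(ep)
  expect_equal(nrow(feats), 5 * dim(ep)[1])
  expect_setequal(unique(paste(feats$component, feats$channel)),
                  c("P1 A10", "P1 B7", "N1 A10", "N1 B7", "P3 A19"))

  p3 <- feats[feats$component == "P3", ]
  p3$state <- ep$trials$state[match(p3$trial_id, ep$trials$trial_id)]
  expect_lt(mean(p3$amplitude[p3$state == "mind_wandering"]),
            mean(p3$amplitude[p3$state == "on_task"]))
  # N1 detections are negative
  n1 <- feats[feats$component == "N1", ]
  expect_true(all(n1$amplitude < 0))

  ep_sub <- ep
  ep_sub$channels[2] <- "XX"
  dimnames(ep_sub$data)[[2]] <- ep_sub$channels
  expect_error(extract_erp_features(ep_sub), "missing channel")
})

test_that("a widened N1 window can capture late peaks", {
  t_ms <- epoch_time_axis()
  # N1-like negativity centered at 220 ms, outside the default window
  ep <- make_epochs(2, fun = function(ch, t)
    if (ch %in% c("A10", "B7")) -4 * mexican_hat((t - 220) / 140)
    else numeric(length(t)))
  f_default <- extract_erp_features(ep, sterp_config(n1_hi_ms = 200))
  f_wide <- extract_erp_features(ep, sterp_config(n1_hi_ms = 230))
  n1d <- f_default[f_default$component == "N1", ]
  n1w <- f_wide[f_wide$component == "N1", ]
  expect_true(all(n1d$t_ms <= 200))
  expect_true(all(n1w$t_ms > 200))
  expect_lt(mean(n1w$amplitude), mean(n1d$amplitude))  # better match
})

test_that("traditional ERP averages and window means behave", {
  t_ms <- epoch_time_axis()
  shape <- function(ch, t) 2 * mexican_hat((t - 450) / 300)
  ep <- make_epochs(4, fun = shape,
                    states = rep(c("on_task", "mind_wandering"), 2))
  tr <- traditional_erp(ep, ep$trials$state)
  # identical epochs -> averaged waveform equals any single epoch
  wf <- tr$waveforms[tr$waveforms$state == "on_task" &
                       tr$waveforms$channel == "A19", ]
  expect_equal(wf$value, shape("A19", t_ms), tolerance = 1e-12)

  ep1 <- make_epochs(2, fun = function(ch, t) rep(1, length(t)))
  tr1 <- traditional_erp(ep1, rep("on_task", 2),
                         keep_states = "on_task")
  expect_true(all(abs(tr1$amplitudes$amplitude - 1) < 1e-12))

  expect_error(traditional_erp(ep, rep("on_task", 4)), "empty state class")
})
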