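test_that("FIR designs satisfy the plateau-shaped gate", {
  for (bn in c("alpha", "theta")) {
    filt <- design_filter(band_spec(bn), fs = 256)
    expect_equal(filt$length %% 2, 1)
    expect_lt(filt$sse, 1)
    expect_gt(filt$gain_mid, 0.95)
    expect_lt(filt$gain_mid, 1.05)
    expect_lte(filt$gain_dc, 0.05)
  }
  # three cycles of 4 Hz at 256 Hz = 192 samples minimum
  th <- design_filter(band_spec("theta"), fs = 256)
  expect_gte(th$length, 192)
  expect_error(design_filter(band_spec("alpha"), fs = 20), "too low")
  expect_error(band_spec("x", lo = 12, hi = 8.5))
})

test_that("analytic signal reproduces amplitude and instantaneous frequency", {
  fs <- 256
  t <- (0:1023) / fs
  x <- cos(2 * pi * 10 * t)
  z <- analytic_signal(x)
  expect_equal(Re(z), x, tolerance = 1e-10)
  core <- 103:921  # exclude 10% edges
  expect_true(all(abs(Mod(z[core]) - 1) < 0.02))
  # unwrapped phase slope ~ 2*pi*10 rad/s
  dphi <- diff(Arg(z[core]))
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(dphi) * fs, 2 * pi * 10, tolerance = 0.01)

  expect_equal(analytic_signal(numeric(8)), complex(real = rep(0, 8)))
  expect_error(analytic_signal(numeric(0)), "empty")
})

test_that("band power follows the closed-form sinusoid oracle", {
  fs <- 256
  t <- (0:511) / fs
  z <- analytic_signal(3 * cos(2 * pi * 10 * t))
  core <- 52:460
  expect_equal(band_power(z, core), 9, tolerance = 0.02 * 9)
  expect_equal(band_power(analytic_signal(2 * 3 * cos(2 * pi * 10 * t)), core),
               4 * band_power(z, core), tolerance = 1e-9)
  expect_equal(band_power(analytic_signal(numeric(16))), 0)
  expect_error(band_power(z, integer(0)), "empty period")
})

test_that("ISPC boundary cases are exact", {
  fs <- 256
  t <- (0:511) / fs
  zx <- analytic_signal(cos(2 * pi * 6 * t))
  expect_equal(ispc(zx, zx), 1, tolerance = 1e-12)
  zy <- analytic_signal(cos(2 * pi * 6 * t - pi / 3))
  expect_equal(ispc(zx, zy), 1, tolerance = 1e-6)
  expect_equal(ispc(zy, zx), ispc(zx, zy))
  # four orthogonal phasors cancel exactly
  z1 <- exp(1i * c(0, pi / 2, pi, 3 * pi / 2))
  z0 <- complex(real = rep(1, 4))
  expect_equal(ispc(z1, z0), 0, tolerance = 1e-12)
  expect_error(ispc(zx, zx[1:10]), "mismatch")
})

test_that("zero-phase filtering matches the reference epoch filter", {
  set.seed(10)
  filt <- design_filter(band_spec("theta"), fs = 256)
  m <- matrix(rnorm(3 * 410), 3)
  fm <- filter_rows(m, filt)
  for (i in 1:3)
    expect_equal(fm[i, ], filter_epoch(m[i, ], filt), tolerance = 1e-10)
  expect_error(filter_epoch(rnorm(100), filt), "shorter")
})

test_that("per-trial spectral features have the documented shape and ranges", {
  set.seed(11)
  d <- task_design("SART", n_blocks = 2, n_probes = 8)
  gen <- gen_params(mw_rate = 0.5)
  st <- simulate_states(d, gen)
  ep <- synthesize_epochs(st, d, gen)
  sf <- extract_spectral_features(ep)
  expect_equal(nrow(sf), 40 * dim(ep)[1])
  expect_all_finite(sf$value)
  expect_true(all(sf$value[sf$kind == "ispc"] >= 0 &
                    sf$value[sf$kind == "ispc"] <= 1))
  expect_true(all(sf$value[sf$kind == "power"] >= 0))
  expect_setequal(unique(sf$period), c("baseline", "aso"))

  # DC-offset invariance: the filters suppress 0 Hz
  ep_dc <- ep
  ep_dc$data <- ep$data + 50
  sf_dc <- extract_spectral_features(ep_dc)
  expect_equal(sf_dc$value, sf$value, tolerance = 0.02)
})

test_that("pure alpha oscillation yields A^2 power through the full path", {
  A <- 2.5
  ep <- make_epochs(3, fun = function(ch, t)
    A * cos(2 * pi * 10 * t / 1000 + 0.4))
  sf <- extract_spectral_features(ep)
  pw <- sf$value[sf$kind == "power" & sf$band == "alpha" &
                   sf$period == "aso"]
  expect_equal(mean(pw), A^2, tolerance = 0.02 * A^2)
  # theta band barely sees the 10 Hz signal
  pw_th <- sf$value[sf$kind == "power" & sf$band == "theta" &
                      sf$period == "aso"]
  expect_lt(mean(pw_th), 0.05 * A^2)
})

test_that("state-dependent alpha amplitude separates MW from OT", {
  set.seed(12)
  d <- task_design("SART", n_blocks = 3, n_probes = 16)
  gen <- gen_params(mw_rate = 0.5, leak = 0)
  st <- simulate_states(d, gen)
  ep <- synthesize_epochs(st, d, gen)
  sf <- extract_spectral_features(ep)
  al <- sf[sf$kind == "power" & sf$band == "alpha" & sf$period == "aso", ]
  al$state <- ep$trials$state[match(al$trial_id, ep$trials$trial_id)]
  expect_gt(mean(al$value[al$state == "mind_wandering"]),
            mean(al$value[al$state == "on_task"]))
})

test_that("filtered white-noise power matches the band-fraction oracle", {
  set.seed(13)
  sigma <- 2
  ep <- make_epochs(40, fun = function(ch, t) rnorm(length(t), 0, sigma))
  sf <- extract_spectral_features(ep, bands = list(band_spec("theta")))
  pw <- mean(sf$value[sf$kind == "power"])
  # equivalent noise bandwidth of the trapezoid: passband + transition/3
  bw <- (8 - 4) + (0.8 + 1.6) / 3
  expected <- 2 * sigma^2 * bw / 128
  expect_gt(pw / expected, 0.8)
  expect_lt(pw / expected, 1.2)
})

test_that("von Mises coupling concentrates the theta phase difference", {
  set.seed(14)
  d <- task_design("SART", n_blocks = 4, n_probes = 20)
  mk <- function(kappa) {
    gen <- gen_params(mw_rate = 0, leak = 0, kappa_ot = kappa,
                      alpha_amp_ot = 0, alpha_amp_mw = 0,
                      noise_sd = 0.5, pink_sd = 0,
                      erp = within(default_erp_components(),
                                   {amp_ot <- 0; amp_mw <- 0}))
    st <- simulate_states(d, gen)
    synthesize_epochs(st, d, gen)
  }
  ep_hi <- mk(50)
  r_hi <- ispc_pooled(ep_hi, band_spec("theta"), c("A19", "A10"))
  expect_gt(r_hi, 0.95)  # near-locked phases
  ep2 <- mk(2)
  r2 <- ispc_pooled(ep2, band_spec("theta"), c("A19", "A10"))
  expect_lt(abs(r2 - besselI(2, 1) / besselI(2, 0)), 0.07)
})
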