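#' Build an experience-sampling task design
#'
#' Lays out one task session: block structure, trial counts and a random
#' probe schedule. The sustained attention to response task (SART) uses
#' 135 trials per block and the visual search task (VS) 140; by default a
#' task comprises 12 blocks and 54 thought probes, consecutive probes
#' separated by 7-24 trials. In the SART the probed trial is always a
#' no-go trial.
#'
#' The probe schedule is drawn from the current RNG stream: set a seed
#' before calling for reproducibility.
#'
#' @param task `"SART"` or `"VS"`.
#' @param n_blocks number of blocks in the session.
#' @param n_probes total number of thought probes.
#' @param probe_gaps integer range `c(lo, hi)` of trials between consecutive
#'   probes (and before the first); must lie within 7-24.
#' @param fs sampling rate (Hz) for synthesized epochs.
#' @param epoch_window `c(pre_ms, post_ms)` epoch extent around stimulus
#'   onset; must total 1600 ms.
#'
#' @return A `task_design` object: the above fields plus `trials_per_block`,
#'   `n_trials`, `probe_trials` (index of the trial immediately preceding
#'   each probe) and a per-trial `stim_type` vector.
#' @export
task_design <- function(task = c("SART", "VS"), n_blocks = 12, n_probes = 54,
                        probe_gaps = c(7, 24), fs = 256,
                        epoch_window = c(400, 1200)) {
  task <- match.arg(task)
  trials_per_block <- switch(task, SART = 135, VS = 140)
  if (length(probe_gaps) != 2 || probe_gaps[1] > probe_gaps[2])
    stop("probe_gaps must be c(lo, hi) with lo <= hi")
  if (probe_gaps[1] < 7 || probe_gaps[2] > 24)
    stop("probe gaps must lie within [7, 24] trials")
  if (sum(epoch_window) != 1600)
    stop("epoch window must total 1600 ms")
  n_trials <- n_blocks * trials_per_block
  if (n_probes * probe_gaps[1] > n_trials)
    stop("probe gaps infeasible for the trials available")

  probe_trials <- NULL
  for (attempt in 1:100) {
    gaps <- probe_gaps[1] +
      sample.int(probe_gaps[2] - probe_gaps[1] + 1L, n_probes,
                 replace = TRUE) - 1L
    pos <- cumsum(gaps)
    if (pos[n_probes] <= n_trials) { probe_trials <- pos; break }
  }
  if (is.null(probe_trials))
    stop("probe gaps infeasible for the trials available")

  stim_type <- if (task == "SART") {
    st <- ifelse(runif(n_trials) < 0.11, "nogo", "go")
    st[probe_trials] <- "nogo"  # probes always follow a no-go trial
    st
  } else {
    ifelse(runif(n_trials) < 0.5, "present", "absent")
  }

  structure(
    list(task = task, n_blocks = n_blocks, trials_per_block = trials_per_block,
         n_trials = n_trials, n_probes = n_probes, probe_gaps = probe_gaps,
         probe_trials = probe_trials, stim_type = stim_type, fs = fs,
         epoch_window = epoch_window,
         time_ms = epoch_time_axis(fs, epoch_window[1], epoch_window[2])),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %s: %d blocks x %d trials, %d probes (gaps %d-%d)\n",
              x$task, x$n_blocks, x$trials_per_block, x$n_probes,
              x$probe_gaps[1], x$probe_gaps[2]))
  invisible(x)
}

#' Generator parameters for synthetic EEG sessions
#'
#' Defaults encode the state effects the pipeline is built to detect:
#' mind-wandering (MW) attenuates the P1/N1/P3 components to 70% of their
#' on-task (OT) amplitude (perceptual and cognitive decoupling), raises
#' occipito-parietal alpha amplitude (2 -> 3 uV), and tightens theta phase
#' coupling on the A19-A10 (parietal - left occipital) pair
#' (kappa 0.5 -> 2). The mean mind-wandering rate defaults to 0.4 and 16%
#' of probe reports leak into the excluded categories (distraction /
#' mind-blanking), matching typical experience-sampling studies.
#'
#' @param mw_rate probability that a probe reports mind-wandering.
#' @param leak probability that a probe response falls in the excluded
#'   categories (4 or 6) irrespective of the latent state.
#' @param erp data frame describing the embedded components (one row per
#'   component x channel): `component`, `channel`, `latency_ms`,
#'   `jitter_sd_ms`, `scale_ms`, `amp_ot`, `amp_mw` (uV, signed).
#' @param amp_cv coefficient of variation of the multiplicative per-trial
#'   ERP amplitude jitter (0 disables it).
#' @param alpha_freq,theta_freq oscillation frequencies (Hz).
#' @param alpha_amp_ot,alpha_amp_mw,theta_amp_ot,theta_amp_mw oscillation
#'   amplitudes (uV) per state.
#' @param osc_sdlog SD of the log-normal per-trial, per-channel amplitude
#'   multiplier applied to the alpha and theta oscillations (0 disables).
#'   Band power across trials is roughly log-normal in real EEG; the
#'   default 0.5 makes single-trial state discrimination imperfect, as in
#'   recordings.
#' @param theta_pair the two channels carrying the coupled theta pair.
#' @param kappa_ot,kappa_mw von Mises concentration of the theta
#'   phase-difference process per state (larger = tighter coupling).
#' @param phase_block_len length in samples of the piecewise-constant
#'   blocks over which the theta phase offset is held before being redrawn.
#' @param noise_sd white noise SD (uV).
#' @param pink_sd pink (1/f) noise SD (uV).
#' @param pink_exponent spectral exponent of the pink noise.
#'
#' @return A `gen_params` list.
#' @export
gen_params <- function(mw_rate = 0.4, leak = 0.16,
                       erp = default_erp_components(),
                       amp_cv = 0.2,
                       alpha_freq = 10, alpha_amp_ot = 2, alpha_amp_mw = 3,
                       theta_freq = 6, theta_amp_ot = 1.5, theta_amp_mw = 1.5,
                       osc_sdlog = 0.5,
                       theta_pair = c("A19", "A10"),
                       kappa_ot = 0.5, kappa_mw = 2, phase_block_len = 86,
                       noise_sd = 2, pink_sd = 2, pink_exponent = 1) {
  stopifnot(mw_rate >= 0, mw_rate <= 1, leak >= 0, leak <= 1,
            amp_cv >= 0, osc_sdlog >= 0, kappa_ot >= 0, kappa_mw >= 0,
            noise_sd >= 0, pink_sd >= 0,
            alpha_amp_ot >= 0, alpha_amp_mw >= 0,
            theta_amp_ot >= 0, theta_amp_mw >= 0,
            all(theta_pair %in% MWEEG_CHANNELS))
  structure(as.list(environment()), class = "gen_params")
}

#' @rdname gen_params
#' @export
default_erp_components <- function() {
  data.frame(
    component = c("P1", "P1", "N1", "N1", "P3"),
    channel   = c("A10", "B7", "A10", "B7", "A19"),
    latency_ms = c(120, 120, 180, 180, 450),
    jitter_sd_ms = c(20, 20, 20, 20, 20),
    scale_ms  = c(100, 100, 140, 140, 600),
    amp_ot    = c(3, 3, -3, -3, 5),
    amp_mw    = c(2.1, 2.1, -2.1, -2.1, 3.5),
    stringsAsFactors = FALSE
  )
}

#' Simulate latent attentional states and probe responses
#'
#' Each probe draws a latent state (mind-wandering with probability
#' `mw_rate`); the six trials up to and including the probed trial share
#' that state (attentional states persist over multiple trials). Probe
#' responses follow the six-option experience-sampling scale: on-task
#' states report 1 or 2, mind-wandering 3 or 5; with probability `leak`
#' the report falls in the excluded categories 4 or 6 instead.
#'
#' @param design a `task_design`.
#' @param gen a `gen_params` list.
#' @return list with `states` (per-trial character vector: `"on_task"`,
#'   `"mind_wandering"` or `"unlabeled"` filler) and `probes` (data frame
#'   `probe_index`, `trial_index`, `response`, `latent`).
#' @export
simulate_states <- function(design, gen = gen_params()) {
  stopifnot(inherits(design, "task_design"))
  states <- rep("unlabeled", design$n_trials)
  np <- design$n_probes
  latent <- ifelse(runif(np) < gen$mw_rate, "mind_wandering", "on_task")
  response <- integer(np)
  for (i in seq_len(np)) {
    tr <- design$probe_trials[i]
    states[max(1, tr - 5):tr] <- latent[i]
    response[i] <- if (runif(1) < gen$leak) {
      sample(c(4L, 6L), 1)
    } else if (latent[i] == "on_task") {
      sample(1:2, 1)
    } else {
      sample(c(3L, 5L), 1)
    }
  }
  list(states = states,
       probes = data.frame(probe_index = seq_len(np),
                           trial_index = design$probe_trials,
                           response = response, latent = latent,
                           stringsAsFactors = FALSE))
}

#' Synthesize epoched EEG for a simulated session
#'
#' Builds each epoch as the sum of (i) Mexican-hat shaped ERP components
#' (P1/N1 at A10 and B7, P3 at A19) with state-dependent amplitude and
#' latency jitter, (ii) alpha oscillations with independent phase per
#' channel and state-dependent amplitude, (iii) theta oscillations, with
#' the configured channel pair sharing a common oscillator whose phase
#' offset follows a piecewise-constant von Mises process of state-dependent
#' concentration, and (iv) pink plus white noise. By default only the
#' pre-probe (labeled) trials receive epochs; filler trials carry metadata
#' only.
#'
#' @param states output of [simulate_states()].
#' @param design a `task_design`.
#' @param gen a `gen_params` list.
#' @param which `"labeled"` (default) synthesizes the six pre-probe trials
#'   of every probe; `"all"` synthesizes every trial.
#' @return An [epoch_set()] whose trial table carries block, stimulus type,
#'   latent state and source probe.
#' @export
synthesize_epochs <- function(states, design, gen = gen_params(),
                              which = c("labeled", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(design, "task_design"))
  if (!all(is.finite(unlist(gen[c("noise_sd", "pink_sd", "alpha_amp_ot",
                                  "alpha_amp_mw", "theta_amp_ot",
                                  "theta_amp_mw", "kappa_ot", "kappa_mw")]))))
    stop("non-finite generator parameters")

  probe_of_trial <- rep(NA_integer_, design$n_trials)
  for (i in seq_len(design$n_probes)) {
    tr <- design$probe_trials[i]
    probe_of_trial[max(1, tr - 5):tr] <- i
  }
  sel <- if (which == "labeled") which(!is.na(probe_of_trial))
         else seq_len(design$n_trials)

  t_ms <- design$time_ms
  ns <- length(t_ms)
  nc <- length(MWEEG_CHANNELS)
  tsec <- t_ms / 1000
  data <- array(0, dim = c(length(sel), nc, ns))
  pair <- match(gen$theta_pair, MWEEG_CHANNELS)
  others <- setdiff(seq_len(nc), pair)

  for (k in seq_along(sel)) {
    tr <- sel[k]
    st <- states$states[tr]
    mw <- identical(st, "mind_wandering")
    ep <- matrix(0, nc, ns)

    # ERP components
    for (r in seq_len(nrow(gen$erp))) {
      cm <- gen$erp[r, ]
      amp <- if (mw) cm$amp_mw else cm$amp_ot
      if (gen$amp_cv > 0) amp <- amp * max(0.1, rnorm(1, 1, gen$amp_cv))
      lat <- cm$latency_ms +
        if (cm$jitter_sd_ms > 0) rnorm(1, 0, cm$jitter_sd_ms) else 0
      ch <- match(cm$channel, MWEEG_CHANNELS)
      ep[ch, ] <- ep[ch, ] + amp * mexican_hat((t_ms - lat) / cm$scale_ms)
    }

    amp_mult <- function() {
      if (gen$osc_sdlog > 0) stats::rlnorm(1, 0, gen$osc_sdlog) else 1
    }

    # alpha: independent phase per channel
    a_amp <- if (mw) gen$alpha_amp_mw else gen$alpha_amp_ot
    if (a_amp > 0) {
      for (ch in seq_len(nc))
        ep[ch, ] <- ep[ch, ] + a_amp * amp_mult() *
          cos(2 * pi * gen$alpha_freq * tsec + runif(1, -pi, pi))
    }

    # theta: coupled pair + independent elsewhere
    t_amp <- if (mw) gen$theta_amp_mw else gen$theta_amp_ot
    if (t_amp > 0) {
      kappa <- if (mw) gen$kappa_mw else gen$kappa_ot
      phi0 <- runif(1, -pi, pi)
      nb <- ceiling(ns / gen$phase_block_len)
      delta <- rep(rvonmises(nb, kappa), each = gen$phase_block_len)[1:ns]
      carrier <- 2 * pi * gen$theta_freq * tsec
      ep[pair[1], ] <- ep[pair[1], ] +
        t_amp * amp_mult() * cos(carrier + phi0)
      ep[pair[2], ] <- ep[pair[2], ] +
        t_amp * amp_mult() * cos(carrier + phi0 + delta)
      for (ch in others)
        ep[ch, ] <- ep[ch, ] +
          t_amp * amp_mult() * cos(carrier + runif(1, -pi, pi))
    }

    # noise
    if (gen$noise_sd > 0 || gen$pink_sd > 0) {
      for (ch in seq_len(nc)) {
        nz <- rnorm(ns, 0, gen$noise_sd)
        if (gen$pink_sd > 0)
          nz <- nz + gen$pink_sd * pink_noise(ns, gen$pink_exponent)
        ep[ch, ] <- ep[ch, ] + nz
      }
    }
    data[k, , ] <- ep
  }

  trials <- data.frame(
    trial_id = sel,
    block = (sel - 1) %/% design$trials_per_block + 1L,
    trial_in_block = (sel - 1) %% design$trials_per_block + 1L,
    stim_type = design$stim_type[sel],
    state = states$states[sel],
    probe_index = probe_of_trial[sel],
    artifact = FALSE,
    stringsAsFactors = FALSE
  )
  epoch_set(data, design$fs, t_ms, MWEEG_CHANNELS, trials)
}

#' Simulate behavioral performance
#'
#' Draws per-trial accuracy and response time conditional on the latent
#' attentional state. Response times are only recorded for correct trials.
#' Defaults follow typical values for the two tasks: in visual search,
#' mind-wandering lowers accuracy (0.95 vs 0.97) and slows responses
#' (687 vs 654 ms); in the SART accuracy drops (0.93 vs 0.95) while
#' responses are slightly faster (444 vs 462 ms), the classic sign of
#' mindless responding. Filler (unlabeled) trials use on-task parameters.
#'
#' @param states output of [simulate_states()].
#' @param design a `task_design`.
#' @param behav list with `acc_ot`, `acc_mw` (probabilities) and
#'   `rt_mean_ot`, `rt_mean_mw`, `rt_sd` (ms); defaults via
#'   [behav_params()].
#' @return Data frame `trial_id`, `state`, `correct`, `rt_ms` (NA when
#'   incorrect).
#' @export
simulate_behavior <- function(states, design, behav = behav_params(design$task)) {
  stopifnot(behav$acc_ot >= 0, behav$acc_ot <= 1,
            behav$acc_mw >= 0, behav$acc_mw <= 1)
  st <- states$states
  mw <- st == "mind_wandering"
  n <- length(st)
  p <- ifelse(mw, behav$acc_mw, behav$acc_ot)
  correct <- runif(n) < p
  mu <- ifelse(mw, behav$rt_mean_mw, behav$rt_mean_ot)
  rt <- rnorm(n, mu, behav$rt_sd)
  rt[!correct] <- NA_real_
  data.frame(trial_id = seq_len(n), state = st, correct = correct,
             rt_ms = rt, stringsAsFactors = FALSE)
}

#' @rdname simulate_behavior
#' @param task `"SART"` or `"VS"`.
#' @export
behav_params <- function(task = c("SART", "VS")) {
  task <- match.arg(task)
  if (task == "SART") {
    list(acc_ot = 0.95, acc_mw = 0.93,
         rt_mean_ot = 462, rt_mean_mw = 444, rt_sd = 100)
  } else {
    list(acc_ot = 0.97, acc_mw = 0.95,
         rt_mean_ot = 654, rt_mean_mw = 687, rt_sd = 150)
  }
}

#' Simulate one complete task session
#'
#' Convenience wrapper: design, latent states, epochs and behavior in one
#' call under one seed.
#'
#' @param task `"SART"` or `"VS"`.
#' @param gen a `gen_params` list.
#' @param seed integer seed; all randomness in the session derives from it.
#' @param design_args extra arguments passed to [task_design()].
#' @param which which trials receive epochs, see [synthesize_epochs()].
#' @return list of class `mw_session`: `design`, `states`, `probes`,
#'   `epochs`, `behavior`.
#' @export
simulate_session <- function(task = "SART", gen = gen_params(), seed = 1,
                             design_args = list(), which = "labeled") {
  set.seed(seed)
  design <- do.call(task_design, c(list(task = task), design_args))
  st <- simulate_states(design, gen)
  epochs <- synthesize_epochs(st, design, gen, which = which)
  behavior <- simulate_behavior(st, design)
  structure(list(design = design, states = st, probes = st$probes,
                 epochs = epochs, behavior = behavior, seed = seed),
            class = "mw_session")
}

#' von Mises random deviates
#'
#' Best & Fisher (1979) rejection sampler; `kappa = 0` falls back to the
#' circular uniform.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0).
#' @param mu mean direction (radians).
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-10) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f) + mu
      out[i] <- atan2(sin(theta), cos(theta))
      i <- i + 1L
    }
  }
  out
}

#' Pink (1/f^exponent) noise via spectral shaping
#'
#' White Gaussian noise is Fourier transformed, its amplitude spectrum
#' scaled by `f^(-exponent/2)` (DC removed) and transformed back; the
#' result is standardized to unit SD.
#'
#' @param n length in samples.
#' @param exponent spectral exponent (1 = classic pink).
#' @return Numeric vector, mean ~0, SD 1.
#' @export
pink_noise <- function(n, exponent = 1) {
  w <- rnorm(n)
  X <- fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)          # two-sided frequency index
  scale <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(X * scale, inverse = TRUE) / n)
  x / sd(x)
}
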