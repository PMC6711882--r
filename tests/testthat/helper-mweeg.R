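# shared fixtures, all generated in code

# two-class Gaussian feature table; `sep` is the between-class mean shift
# in SD units on every feature
make_blob_table <- function(n_per_class = 30, n_features = 5, sep = 4,
                            seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * n_features, 0), n_per_class),
             matrix(rnorm(n_per_class * n_features, sep), n_per_class))
  tab <- as.data.frame(x)
  names(tab) <- paste0("f", seq_len(n_features))
  tab <- cbind(trial_id = seq_len(2 * n_per_class), tab)
  tab$state <- factor(rep(c("on_task", "mind_wandering"), each = n_per_class),
                      levels = c("on_task", "mind_wandering"))
  tab
}

# minimal epoch_set built from an explicit channel builder function
# fun(channel, time_ms) -> one epoch row; same signal for every trial
make_epochs <- function(n_trials = 4, fs = 256,
                        fun = function(ch, t_ms) numeric(length(t_ms)),
                        states = rep("on_task", n_trials)) {
  t_ms <- epoch_time_axis(fs)
  chans <- c("A10", "A19", "B7", "C21")
  data <- array(0, dim = c(n_trials, length(chans), length(t_ms)))
  for (ci in seq_along(chans))
    for (tr in seq_len(n_trials))
      data[tr, ci, ] <- fun(chans[ci], t_ms)
  epoch_set(data, fs, t_ms, chans,
            data.frame(trial_id = seq_len(n_trials), state = states))
}

# quiet generator: deterministic epochs (template sum only)
quiet_gen <- function(...) {
  gen_params(amp_cv = 0, osc_sdlog = 0, alpha_amp_ot = 0, alpha_amp_mw = 0,
             theta_amp_ot = 0, theta_amp_mw = 0, noise_sd = 0, pink_sd = 0,
             erp = within(default_erp_components(), jitter_sd_ms <- 0), ...)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
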