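#' Mexican-hat template waveform
#'
#' The idealized ERP waveform used for single-trial template matching:
#' `psi(u) = (1 - 16 u^2) exp(-8 u^2)`. Its peak is 1 at `u = 0`, with zero
#' crossings at `u = +/- 1/4`; the argument is the lag normalized by the
#' scale, `u = (tau - t) / s`, so `s` is approximately the wavelength of
#' the bump in the same units as `tau`.
#'
#' @param u numeric vector.
#' @return `psi(u)`, same shape as `u`.
#' @export
mexican_hat <- function(u) {
  stopifnot(is.numeric(u))
  (1 - 16 * u^2) * exp(-8 * u^2)
}

#' Wavelet cross-covariance map of a single-trial signal
#'
#' Template matching of one epoch against Mexican-hat waveforms over a grid
#' of time lags `t` and scales `s`:
#' `W(s, t) = s^(-1/2) * sum_tau f(tau) psi((tau - t)/s) dtau`,
#' discretized as a Riemann sum over the epoch samples (`dtau = 1000/fs`
#' ms) with zero contribution outside the epoch's support. The local
#' extreme of `W` locates the best-matching template; `W` there measures
#' the single-trial component amplitude.
#'
#' @param signal numeric vector, one channel of one epoch (uV).
#' @param time_ms sample times of `signal` in ms.
#' @param s_grid_ms scales in ms (all > 0).
#' @param t_grid_ms lags in ms.
#' @param method `"fft"` (fast convolution, default; exploits the even
#'   symmetry of the template, so cross-correlation equals convolution)
#'   or `"direct"` (per-grid-point Riemann sums, the reference route).
#'   Both evaluate the identical discretized integral; with lags on the
#'   sample grid they agree to numerical precision. The `"fft"` route
#'   evaluates at the sample lag nearest each requested lag.
#' @return A `wavelet_map`: list with `W` (scales x lags matrix), `s_grid`,
#'   `t_grid`.
#' @export
wavelet_cross_covariance <- function(signal, time_ms, s_grid_ms, t_grid_ms,
                                     method = c("fft", "direct")) {
  method <- match.arg(method)
  if (length(signal) == 0) stop("empty signal")
  if (length(signal) != length(time_ms))
    stop("signal and time_ms lengths differ")
  if (length(s_grid_ms) == 0 || length(t_grid_ms) == 0)
    stop("empty scale or lag grid")
  if (any(s_grid_ms <= 0)) stop("scales must be positive")
  n <- length(signal)
  dt <- mean(diff(time_ms))

  W <- matrix(NA_real_, length(s_grid_ms), length(t_grid_ms))
  if (method == "direct") {
    for (si in seq_along(s_grid_ms)) {
      s <- s_grid_ms[si]
      for (ti in seq_along(t_grid_ms))
        W[si, ti] <- sum(signal *
                           mexican_hat((time_ms - t_grid_ms[ti]) / s)) *
          dt / sqrt(s)
    }
  } else {
    # W at every sample lag by circular convolution on a zero-padded grid;
    # psi is even, so correlation with the template equals convolution
    li <- vapply(t_grid_ms, function(t0) which.min(abs(time_ms - t0)),
                 integer(1))
    N <- stats::nextn(2 * n, 2)
    fpad <- c(signal, numeric(N - n))
    Ff <- fft(fpad)
    for (si in seq_along(s_grid_ms)) {
      s <- s_grid_ms[si]
      g <- mexican_hat((0:(n - 1)) * dt / s)
      kern <- numeric(N)
      kern[1:n] <- g
      kern[N - (1:(n - 1)) + 1] <- g[-1]        # wrap negative lags
      conv <- Re(fft(Ff * fft(kern), inverse = TRUE)) / N
      W[si, ] <- conv[li] * dt / sqrt(s)
    }
  }
  structure(list(W = W, s_grid = s_grid_ms, t_grid = t_grid_ms),
            class = "wavelet_map")
}

# batch form: signals in rows -> array (trials x scales x lags)
wcc_batch <- function(signals, time_ms, s_grid_ms, t_grid_ms) {
  dt <- mean(diff(time_ms))
  out <- array(NA_real_,
               dim = c(nrow(signals), length(s_grid_ms), length(t_grid_ms)))
  for (si in seq_along(s_grid_ms)) {
    s <- s_grid_ms[si]
    Psi <- mexican_hat(outer(time_ms, t_grid_ms, "-") / s)
    out[, si, ] <- (signals %*% Psi) * dt / sqrt(s)
  }
  out
}

#' Detect a component in a wavelet map
#'
#' Returns the polarity-signed grid extreme of `W` over lags inside the
#' search window, across all scales. Ties are broken toward the earliest
#' lag, then the smallest scale. The detection is flagged `"ok"` when the
#' extreme is strictly interior to the search region (not on the window or
#' scale-grid boundary) and has the expected sign; otherwise the boundary
#' extreme is returned flagged `"degraded"`.
#'
#' @param map a `wavelet_map`.
#' @param window `c(lo_ms, hi_ms)` lag search window.
#' @param polarity `"+"` (positive component, e.g. P1/P3) or `"-"` (N1).
#' @return One-row data frame: `amplitude` (signed `W`), `t_ms`, `s_ms`,
#'   `found` (`"ok"`/`"degraded"`).
#' @export
detect_component <- function(map, window, polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(map, "wavelet_map"), length(window) == 2)
  in_win <- which(map$t_grid >= window[1] & map$t_grid <= window[2])
  if (length(in_win) == 0) stop("window outside the map's lag grid")
  sgn <- if (polarity == "+") 1 else -1
  V <- sgn * map$W[, in_win, drop = FALSE]
  hits <- which(V == max(V), arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]  # earliest t, smallest s
  si <- hits[1, 1]; ti <- hits[1, 2]
  interior <- ti > 1 && ti < length(in_win) &&
    si > 1 && si < nrow(map$W) && V[si, ti] > 0
  data.frame(amplitude = map$W[si, in_win[ti]],
             t_ms = map$t_grid[in_win[ti]],
             s_ms = map$s_grid[si],
             found = if (interior) "ok" else "degraded",
             stringsAsFactors = FALSE)
}

#' Component search configuration for single-trial ERP extraction
#'
#' P1 is the positive extreme between 50 and 150 ms at the lateral
#' occipital channels A10 and B7, N1 the negative extreme between 100 and
#' 200 ms at the same channels, and P3 the positive extreme between 250
#' and 600 ms at the parietal channel A19. The N1 upper bound can be
#' raised (e.g. to 230 ms) when the default window clips late N1 peaks.
#' Scale grids are logarithmic with `n_scales` steps, spanning 50-400 ms
#' for the narrow early components and 200-1400 ms for the broad P3.
#'
#' @param n1_hi_ms upper bound of the N1 search window (default 200).
#' @param n_scales number of logarithmic scale steps per component.
#' @return Data frame with one row per component x channel.
#' @export
sterp_config <- function(n1_hi_ms = 200, n_scales = 32) {
  data.frame(
    component = c("P1", "P1", "N1", "N1", "P3"),
    channel   = c("A10", "B7", "A10", "B7", "A19"),
    lo_ms = c(50, 50, 100, 100, 250),
    hi_ms = c(150, 150, n1_hi_ms, n1_hi_ms, 600),
    polarity = c("+", "+", "-", "-", "+"),
    s_lo = c(50, 50, 50, 50, 200),
    s_hi = c(400, 400, 400, 400, 1400),
    n_scales = n_scales,
    stringsAsFactors = FALSE
  )
}

#' Extract single-trial ERP features from an epoch set
#'
#' Runs the wavelet template matching for every trial and every configured
#' component x channel combination (by default P1 at A10/B7, N1 at A10/B7,
#' P3 at A19: five features per trial).
#'
#' @param epochs an [epoch_set()].
#' @param config component table from [sterp_config()].
#' @return Long data frame: `trial_id`, `component`, `channel`,
#'   `amplitude`, `t_ms`, `s_ms`, `found` (5 rows per trial with the
#'   default config).
#' @export
extract_erp_features <- function(epochs, config = sterp_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  missing_ch <- setdiff(unique(config$channel), epochs$channels)
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  time_ms <- epochs$time_ms
  out <- vector("list", nrow(config))
  for (r in seq_len(nrow(config))) {
    cfg <- config[r, ]
    s_grid <- exp(seq(log(cfg$s_lo), log(cfg$s_hi), length.out = cfg$n_scales))
    t_grid <- time_ms[time_ms >= cfg$lo_ms & time_ms <= cfg$hi_ms]
    sig <- channel_matrix(epochs, cfg$channel)
    A <- wcc_batch(sig, time_ms, s_grid, t_grid)
    sgn <- if (cfg$polarity == "+") 1 else -1
    n_s <- length(s_grid); n_t <- length(t_grid); n_tr <- nrow(sig)
    V <- matrix(sgn * A, n_tr, n_s * n_t)  # column = (t-1)*n_s + s
    best <- max.col(V, ties.method = "first")  # earliest t, then smallest s
    ti <- (best - 1L) %/% n_s + 1L
    si <- (best - 1L) %% n_s + 1L
    amp <- sgn * V[cbind(seq_len(n_tr), best)]
    interior <- ti > 1 & ti < n_t & si > 1 & si < n_s & sgn * amp > 0
    out[[r]] <- data.frame(
      trial_id = epochs$trials$trial_id,
      component = cfg$component, channel = cfg$channel,
      amplitude = amp, t_ms = t_grid[ti], s_ms = s_grid[si],
      found = ifelse(interior, "ok", "degraded"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res[order(res$trial_id), , drop = FALSE]
}

#' Traditional (trial-averaged) ERP measures
#'
#' The conventional counterpart of the single-trial method: per-state
#' averaged waveforms, and per-trial amplitudes as the mean voltage over a
#' fixed narrow window (defaults P1 120-130 ms, N1 195-205 ms, P3
#' 400-500 ms at the same channels as the single-trial analysis).
#'
#' @param epochs an [epoch_set()].
#' @param states per-trial state labels (defaults to the epoch metadata);
#'   trials with states outside `keep_states` are ignored for waveforms.
#' @param windows named list of `c(lo_ms, hi_ms)` per component.
#' @param keep_states states to average over; each must be non-empty.
#' @return list with `waveforms` (long data frame: state, channel,
#'   time_ms, value) and `amplitudes` (long data frame: trial_id,
#'   component, channel, amplitude).
#' @export
traditional_erp <- function(epochs, states = epochs$trials$state,
                            windows = list(P1 = c(120, 130),
                                           N1 = c(195, 205),
                                           P3 = c(400, 500)),
                            keep_states = c("on_task", "mind_wandering")) {
  stopifnot(inherits(epochs, "epoch_set"),
            length(states) == n_trials(epochs))
  comp_ch <- data.frame(
    component = c("P1", "P1", "N1", "N1", "P3"),
    channel = c("A10", "B7", "A10", "B7", "A19"),
    stringsAsFactors = FALSE
  )
  wf <- list()
  for (st in keep_states) {
    idx <- which(states == st)
    if (length(idx) == 0) stop("empty state class: ", st)
    for (ch in epochs$channels) {
      m <- channel_matrix(epochs, ch)[idx, , drop = FALSE]
      wf[[paste(st, ch)]] <- data.frame(
        state = st, channel = ch, time_ms = epochs$time_ms,
        value = colMeans(m), stringsAsFactors = FALSE)
    }
  }
  amp <- list()
  for (r in seq_len(nrow(comp_ch))) {
    comp <- comp_ch$component[r]; ch <- comp_ch$channel[r]
    win <- windows[[comp]]
    cols <- epochs$time_ms >= win[1] & epochs$time_ms <= win[2]
    m <- channel_matrix(epochs, ch)
    amp[[r]] <- data.frame(
      trial_id = epochs$trials$trial_id, component = comp, channel = ch,
      amplitude = rowMeans(m[, cols, drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  list(waveforms = do.call(rbind, wf), amplitudes = do.call(rbind, amp))
}
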