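#' Frequency band specification
#'
#' Default bands: alpha 8.5-12 Hz and theta 4-8 Hz, with 20% transition
#' widths on each band edge and a filter long enough for at least three
#' cycles of the band's lowest frequency.
#'
#' @param name `"alpha"` or `"theta"` (or any label when `lo`/`hi` given).
#' @param lo,hi passband edges in Hz (defaults by band name).
#' @param transition_frac transition width as a fraction of each edge
#'   frequency.
#' @param min_cycles minimum admissible filter length in cycles of `lo`.
#' @param cycles designed filter length in cycles of `lo` (never below
#'   `min_cycles`); the default 5 is what a flat plateau requires at
#'   typical EEG sampling rates, where the three-cycle floor alone leaves
#'   visible passband ripple.
#' @return A `band_spec` list.
#' @export
band_spec <- function(name = c("alpha", "theta"), lo = NULL, hi = NULL,
                      transition_frac = 0.2, min_cycles = 3, cycles = 5) {
  if (is.null(lo) || is.null(hi)) {
    name <- match.arg(name)
    lo <- switch(name, alpha = 8.5, theta = 4)
    hi <- switch(name, alpha = 12, theta = 8)
  }
  stopifnot(lo > 0, lo < hi, transition_frac > 0, transition_frac < 1,
            min_cycles >= 1, cycles >= 1)
  structure(list(name = as.character(name), lo = lo, hi = hi,
                 transition_frac = transition_frac, min_cycles = min_cycles,
                 cycles = max(cycles, min_cycles)),
            class = "band_spec")
}

#' Design a plateau-shaped least-squares FIR band-pass filter
#'
#' Linear-phase (type I) FIR designed by least squares against the ideal
#' "plateau-shaped" response: 1 across the passband, 0 in the stopbands,
#' with linear transition ramps of width `transition_frac` times each band
#' edge. The kernel length covers at least `min_cycles` cycles of the
#' band's lowest frequency (rounded up to an odd sample count). The design
#' is validated by the sum of squared errors (SSE) between the realized
#' amplitude response and the ideal on a 1000-point grid from 0 Hz to
#' Nyquist; a design with SSE >= 1 is rejected.
#'
#' @param band a [band_spec()].
#' @param fs sampling rate (Hz); must exceed twice the upper stopband edge.
#' @return A `fir_filter`: kernel `h`, `length`, `sse`, `gain_mid`
#'   (realized gain at the passband midpoint), `gain_dc`, plus the band
#'   and `fs`.
#' @export
design_filter <- function(band, fs) {
  stopifnot(inherits(band, "band_spec"))
  stop_lo <- band$lo * (1 - band$transition_frac)
  stop_hi <- band$hi * (1 + band$transition_frac)
  if (fs <= 2 * stop_hi)
    stop("sampling rate too low for this band")
  L <- ceiling(max(band$cycles, band$min_cycles) / band$lo * fs)
  if (L %% 2 == 0) L <- L + 1L
  M <- (L - 1L) / 2L

  ideal <- function(f_hz) {
    approx(c(0, stop_lo, band$lo, band$hi, stop_hi, fs / 2),
           c(0, 0, 1, 1, 0, 0), xout = f_hz, rule = 2)$y
  }
  # dense-grid least squares on the cosine amplitude basis; transition
  # bands are don't-care regions, the passband is weighted 4:1 over the
  # stopband (amplitude fidelity in-band matters more than stopband depth
  # for power features), and the response is constrained to be exactly
  # zero at DC (eliminate b0 via b0 = -sum(b_k)), so a constant offset in
  # the data cannot leak into band power
  w <- seq(0, pi, length.out = 16 * L)
  f_w <- w * fs / (2 * pi)
  care <- f_w <= stop_lo | (f_w >= band$lo & f_w <= band$hi) |
    f_w >= stop_hi
  D <- ideal(f_w)[care]
  wt <- ifelse(D > 0, 2, 1)          # sqrt of the 4:1 weight
  B2 <- (cos(outer(w[care], 1:M)) - 1) * wt
  bk <- qr.solve(B2, D * wt)
  b <- c(-sum(bk), bk)
  h <- c(rev(b[-1] / 2), b[1], b[-1] / 2)

  resp <- function(f_hz) {               # realized amplitude response
    as.numeric(cos(outer(2 * pi * f_hz / fs, 0:M)) %*% b)
  }
  f_grid <- seq(0, fs / 2, length.out = 1000)
  sse <- sum((resp(f_grid) - ideal(f_grid))^2)
  gain_mid <- resp((band$lo + band$hi) / 2)
  gain_dc <- abs(resp(0))
  if (sse >= 1)
    stop(sprintf("filter design rejected: SSE = %.3g >= 1", sse))
  structure(list(h = h, length = L, band = band, fs = fs, sse = sse,
                 gain_mid = gain_mid, gain_dc = gain_dc, resp = resp),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter> %s %g-%g Hz @ %g Hz, %d taps; SSE %.2g, mid gain %.3f, DC %.2g\n",
              x$band$name, x$band$lo, x$band$hi, x$fs, x$length,
              x$sse, x$gain_mid, x$gain_dc))
  invisible(x)
}

#' Zero-phase FIR filtering of one epoch
#'
#' Applies the symmetric kernel centered (zero phase). The epoch is
#' mirror-padded by one kernel length on each side to suppress edge
#' transients before convolution.
#'
#' @param x numeric vector (one epoch channel).
#' @param filt a `fir_filter` (or a bare numeric kernel of odd length).
#' @return Filtered signal, same length as `x`.
#' @export
filter_epoch <- function(x, filt) {
  h <- if (inherits(filt, "fir_filter")) filt$h else filt
  L <- length(h)
  if (L %% 2 == 0) stop("kernel length must be odd")
  if (L > length(x)) stop("epoch shorter than the filter kernel")
  n <- length(x)
  xp <- c(rev(x[1:L]), x, rev(x[(n - L + 1):n]))
  y <- stats::filter(xp, h, sides = 2)
  as.numeric(y[(L + 1):(L + n)])
}

# batch zero-phase filtering of a trials-by-samples matrix via FFT
filter_rows <- function(m, filt) {
  h <- if (inherits(filt, "fir_filter")) filt$h else filt
  L <- length(h)
  n <- ncol(m)
  if (L > n) stop("epoch shorter than the filter kernel")
  pad <- cbind(m[, L:1, drop = FALSE], m, m[, n:(n - L + 1), drop = FALSE])
  np <- ncol(pad)
  N <- stats::nextn(np + L - 1, 2)
  H <- fft(c(h, numeric(N - L)))
  X <- stats::mvfft(t(cbind(pad, matrix(0, nrow(m), N - np))))
  Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / N
  # conv output aligned so original sample j sits at row L + j + (L-1)/2
  t(Y[(L + (L - 1) / 2 + 1):(L + (L - 1) / 2 + n), , drop = FALSE])
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: positive frequencies doubled, negative zeroed. The
#' real part of the result equals the input; magnitude and phase give the
#' instantaneous envelope and phase angle.
#'
#' @param x real numeric vector (a band-limited epoch channel).
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty input")
  X <- fft(x)
  mult <- numeric(n)
  mult[1] <- 1
  if (n %% 2 == 0) {
    mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[2:((n + 1) / 2)] <- 2
  }
  fft(X * mult, inverse = TRUE) / n
}

# rows of a matrix at once
analytic_rows <- function(m) {
  n <- ncol(m)
  mult <- numeric(n)
  mult[1] <- 1
  if (n %% 2 == 0) {
    mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[2:((n + 1) / 2)] <- 2
  }
  t(stats::mvfft(stats::mvfft(t(m)) * mult, inverse = TRUE) / n)
}

#' Mean band power of an analytic signal over a period
#'
#' @param z complex analytic signal.
#' @param idx sample indices (or logical mask) of the period.
#' @return Mean of `|z|^2` over the period (uV^2).
#' @export
band_power <- function(z, idx = seq_along(z)) {
  if (length(z) == 0) stop("empty input")
  zi <- z[idx]
  if (length(zi) == 0) stop("empty period")
  mean(Mod(zi)^2)
}

#' Intersite phase clustering (phase-locking value)
#'
#' `ISPC = | n^-1 sum_t exp(i (phi_x(t) - phi_y(t))) |` over the period
#' samples: 1 for perfectly locked phases (any constant offset), 0 for
#' uniformly scattered phase differences.
#'
#' @param zx,zy complex analytic signals of equal length.
#' @param idx sample indices (or logical mask) of the period.
#' @return Value in `[0, 1]`.
#' @export
ispc <- function(zx, zy, idx = seq_along(zx)) {
  if (length(zx) != length(zy)) stop("length mismatch")
  pd <- Arg(zx[idx]) - Arg(zy[idx])
  if (length(pd) == 0) stop("empty period")
  Mod(mean(exp(1i * pd)))
}

#' Spectral feature periods
#'
#' @param time_ms epoch time axis.
#' @return list of logical masks: `baseline` (-400-0 ms) and `aso`
#'   (after stimulus onset, 0-600 ms).
#' @export
spectral_periods <- function(time_ms) {
  list(baseline = time_ms >= -400 & time_ms < 0,
       aso = time_ms >= 0 & time_ms <= 600)
}

#' Extract band power and ISPC features per trial
#'
#' For each band (alpha, theta), each epoch channel is band-pass filtered
#' and Hilbert transformed; band power is averaged per period at each of
#' the four sites and ISPC computed for each of the six site pairs, over
#' the baseline (-400-0 ms) and after-stimulus-onset (0-600 ms) periods:
#' 40 values per trial.
#'
#' @param epochs an [epoch_set()] containing channels A10, A19, B7, C21.
#' @param bands list of [band_spec()]s.
#' @return Long data frame: `trial_id`, `kind` (`"power"`/`"ispc"`),
#'   `band`, `site_or_pair` (site, or `"X-Y"` in canonical channel order),
#'   `period`, `value`.
#' @export
extract_spectral_features <- function(epochs,
                                      bands = list(band_spec("alpha"),
                                                   band_spec("theta"))) {
  stopifnot(inherits(epochs, "epoch_set"))
  missing_ch <- setdiff(MWEEG_CHANNELS, epochs$channels)
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  periods <- spectral_periods(epochs$time_ms)
  pairs <- mweeg_pairs()
  ids <- epochs$trials$trial_id
  out <- list()
  for (band in bands) {
    filt <- design_filter(band, epochs$fs)
    Z <- lapply(MWEEG_CHANNELS, function(ch)
      analytic_rows(filter_rows(channel_matrix(epochs, ch), filt)))
    names(Z) <- MWEEG_CHANNELS
    for (per in names(periods)) {
      msk <- periods[[per]]
      for (ch in MWEEG_CHANNELS) {
        pw <- rowMeans(Mod(Z[[ch]][, msk, drop = FALSE])^2)
        out[[length(out) + 1L]] <- data.frame(
          trial_id = ids, kind = "power", band = band$name,
          site_or_pair = ch, period = per, value = pw,
          stringsAsFactors = FALSE)
      }
      for (pr in seq_len(nrow(pairs))) {
        zx <- Z[[pairs$x[pr]]][, msk, drop = FALSE]
        zy <- Z[[pairs$y[pr]]][, msk, drop = FALSE]
        v <- Mod(rowMeans(exp(1i * (Arg(zx) - Arg(zy)))))
        out[[length(out) + 1L]] <- data.frame(
          trial_id = ids, kind = "ispc", band = band$name,
          site_or_pair = paste(pairs$x[pr], pairs$y[pr], sep = "-"),
          period = per, value = v, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Pooled phase-coupling estimate across trials
#'
#' Concatenates the per-sample phase-angle differences of a channel pair
#' across all trials and takes a single resultant length. Unlike the mean
#' of per-trial ISPCs (whose finite-sample floor biases it upward), this
#' estimates the marginal concentration of the phase-difference
#' distribution: for a von Mises phase-offset process with concentration
#' kappa it converges to `I1(kappa)/I0(kappa)`.
#'
#' @param epochs an [epoch_set()].
#' @param band a [band_spec()].
#' @param pair character vector of two channel names.
#' @param period `"aso"` or `"baseline"`.
#' @return Scalar in `[0, 1]`.
#' @export
ispc_pooled <- function(epochs, band, pair, period = "aso") {
  stopifnot(length(pair) == 2, all(pair %in% epochs$channels))
  filt <- design_filter(band, epochs$fs)
  msk <- spectral_periods(epochs$time_ms)[[period]]
  zx <- analytic_rows(filter_rows(channel_matrix(epochs, pair[1]), filt))
  zy <- analytic_rows(filter_rows(channel_matrix(epochs, pair[2]), filt))
  pd <- Arg(zx[, msk]) - Arg(zy[, msk])
  Mod(mean(exp(1i * pd)))
}
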