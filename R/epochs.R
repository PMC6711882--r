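#' Epoched EEG container
#'
#' `epoch_set()` is the central data structure of the pipeline: a dense
#' `trials x channels x samples` array of epoched EEG together with its time
#' axis, sampling rate and per-trial metadata. Epochs are time-locked to
#' stimulus onset (time 0).
#'
#' @param data numeric array, `trials x channels x samples` (microvolts).
#' @param fs sampling rate in Hz.
#' @param time_ms numeric vector of sample times in ms relative to stimulus
#'   onset; length must equal `dim(data)[3]`.
#' @param channels character vector of channel names; length must equal
#'   `dim(data)[2]`.
#' @param trials data frame of per-trial metadata with at least a `trial_id`
#'   column; one row per epoch.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, time_ms, channels, trials) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(channels))
    stop("channel dimension does not match `channels`")
  if (dim(data)[3] != length(time_ms))
    stop("sample dimension does not match `time_ms`")
  if (!is.data.frame(trials) || nrow(trials) != dim(data)[1])
    stop("`trials` must be a data frame with one row per epoch")
  if (!"trial_id" %in% names(trials))
    stop("`trials` must contain a `trial_id` column")
  if (anyDuplicated(trials$trial_id))
    stop("duplicated trial_id in `trials`")
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, fs = fs, time_ms = as.numeric(time_ms),
         channels = as.character(channels), trials = trials),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g ms; channels: %s\n",
              min(x$time_ms), max(x$time_ms),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

#' Subset an epoch set by trial
#'
#' @param x an `epoch_set`.
#' @param i trial indices (row indices into `x$trials`) or a logical vector.
#' @return An `epoch_set` containing the selected trials.
#' @export
subset_trials <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$fs, x$time_ms, x$channels,
            x$trials[i, , drop = FALSE])
}

#' Extract one channel as a trials-by-samples matrix
#'
#' @param x an `epoch_set`.
#' @param channel channel name.
#' @return Numeric matrix, trials in rows.
#' @export
channel_matrix <- function(x, channel) {
  if (!channel %in% x$channels) stop("channel not present: ", channel)
  m <- x$data[, channel, , drop = FALSE]
  dim(m) <- dim(x$data)[c(1, 3)]
  m
}

#' Default epoch time axis
#'
#' Sample times for an epoch window of `pre_ms` before to `post_ms` after
#' stimulus onset at sampling rate `fs`; the first sample sits at `-pre_ms`.
#'
#' @param fs sampling rate (Hz).
#' @param pre_ms,post_ms window extent in ms (positive numbers).
#' @return Numeric vector of times in ms.
#' @export
epoch_time_axis <- function(fs = 256, pre_ms = 400, post_ms = 1200) {
  n <- round((pre_ms + post_ms) * fs / 1000)
  -pre_ms + (seq_len(n) - 1) * 1000 / fs
}

#' Write / read an epoch container directory
#'
#' The on-disk container is a directory holding `meta.json` (sampling rate,
#' channels, time axis and the trial table) and `epochs.f32`, a flat
#' little-endian 32-bit float binary in trial-major, then channel-major,
#' then sample order. The trial table is additionally written as
#' `trials.csv` for convenience.
#'
#' @param x an `epoch_set`.
#' @param dir directory to create/read.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` returns
#'   an `epoch_set`. Note float32 storage rounds to ~7 significant digits.
#' @export
write_epochs <- function(x, dir) {
  stopifnot(inherits(x, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    fs = x$fs, channels = x$channels, time_ms = x$time_ms,
    n_trials = n_trials(x),
    order = "trial,channel,sample", dtype = "float32le",
    trials = x$trials
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  # flatten with sample fastest, then channel, then trial
  flat <- as.vector(aperm(x$data, c(3, 2, 1)))
  con <- file(file.path(dir, "epochs.f32"), "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 4, endian = "little")
  write.csv(x$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  nt <- meta$n_trials; nc <- length(meta$channels); ns <- length(meta$time_ms)
  con <- file(file.path(dir, "epochs.f32"), "rb")
  on.exit(close(con))
  flat <- readBin(con, "numeric", n = nt * nc * ns, size = 4,
                  endian = "little")
  if (length(flat) != nt * nc * ns) stop("epochs.f32 truncated")
  data <- aperm(array(flat, dim = c(ns, nc, nt)), c(3, 2, 1))
  epoch_set(data, meta$fs, meta$time_ms, meta$channels,
            as.data.frame(meta$trials))
}
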