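#' Map a thought-probe response to a mental-state class
#'
#' Six-option experience-sampling scale: responses 1 (fully on task) and
#' 2 (evaluating the task) are task-related mental activity; 3 (personal
#' matters) and 5 (daydreaming) are self-generated task-unrelated thought,
#' i.e. mind-wandering; 4 (external distraction) and 6 (mind-blanking)
#' fit neither class and are excluded.
#'
#' @param code integer vector of probe responses (1-6).
#' @return Character vector: `"on_task"`, `"mind_wandering"` or
#'   `"excluded"`.
#' @export
map_probe_response <- function(code) {
  if (any(!code %in% 1:6)) stop("probe response out of range 1-6")
  c("on_task", "on_task", "mind_wandering", "excluded",
    "mind_wandering", "excluded")[code]
}

#' Label the six pre-probe trials of each probe
#'
#' The six trials immediately preceding each probe screen (the probed
#' trial is the last of the six) inherit the probe's mental-state class.
#' Probes whose response maps to the excluded class contribute no labeled
#' trials.
#'
#' @param design a [task_design()].
#' @param probes data frame with `probe_index`, `trial_index`, `response`
#'   (as produced by [simulate_states()]).
#' @return Data frame `trial_id`, `state`, `source_probe`, one row per
#'   labeled trial (6 per non-excluded probe).
#' @export
select_trials <- function(design, probes) {
  stopifnot(inherits(design, "task_design"),
            all(c("probe_index", "trial_index", "response") %in% names(probes)))
  if (any(probes$trial_index < 6))
    stop("probe earlier than trial 6: no full pre-probe window")
  if (any(probes$trial_index > design$n_trials))
    stop("probe beyond session bounds")
  if (nrow(probes) > 1 && any(diff(sort(probes$trial_index)) < 6))
    stop("overlapping pre-probe windows")
  cls <- map_probe_response(probes$response)
  keep <- which(cls != "excluded")
  if (length(keep) == 0)
    return(data.frame(trial_id = integer(), state = character(),
                      source_probe = integer(), stringsAsFactors = FALSE))
  out <- lapply(keep, function(i) {
    tr <- probes$trial_index[i]
    data.frame(trial_id = (tr - 5L):tr, state = cls[i],
               source_probe = probes$probe_index[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Apply the subject-level inclusion criterion
#'
#' A subject is retained only if every task-by-state cell holds at least
#' `min_trials` clean (artifact-free) labeled trials.
#'
#' @param counts data frame with columns `subject`, `task`, `state`, `n`
#'   (clean labeled trial counts; artifact-rejected trials must already be
#'   removed).
#' @param min_trials inclusion threshold per cell (default 30).
#' @return Data frame `subject`, `included`, `min_cell` (the subject's
#'   smallest cell).
#' @export
apply_inclusion_criteria <- function(counts, min_trials = 30) {
  stopifnot(all(c("subject", "task", "state", "n") %in% names(counts)))
  split_counts <- split(counts$n, counts$subject)
  subj <- names(split_counts)
  min_cell <- vapply(split_counts, min, numeric(1))
  data.frame(subject = subj, included = min_cell >= min_trials,
             min_cell = min_cell, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Label a simulated session
#'
#' Applies [select_trials()] to a session's probes and attaches the labels
#' to the epoch metadata, dropping artifact-flagged trials.
#'
#' @param session an `mw_session` from [simulate_session()].
#' @return list with `labels` (labeled-trial data frame) and `epochs`
#'   (epoch set restricted to clean labeled trials, with a `label`
#'   column).
#' @export
label_session <- function(session) {
  labels <- select_trials(session$design, session$probes)
  ep <- session$epochs
  idx <- match(labels$trial_id, ep$trials$trial_id)
  if (anyNA(idx)) stop("labeled trial missing from the epoch set")
  keep <- !ep$trials$artifact[idx]
  ep2 <- subset_trials(ep, idx[keep])
  ep2$trials$label <- labels$state[keep]
  list(labels = labels[keep, , drop = FALSE], epochs = ep2)
}
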