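#' Assemble a validated spike-train table
#'
#' The atomic input of every analysis stage is a table with one row per
#' neuron: sorted spike times (seconds, list-column), the recording duration
#' and the recording condition. This constructor validates the invariants
#' that the rest of the pipeline relies on: spike times strictly increasing
#' and contained in `[0, duration]`, durations positive, known condition
#' labels.
#'
#' @param neuron_id Character vector of unique neuron identifiers.
#' @param spikes List of numeric vectors of spike times in seconds.
#' @param duration Numeric vector of recording durations in seconds.
#' @param condition `"anesthetized"` or `"awake"` (recycled if length 1).
#' @param anesthetic `"ketamine_xylazine"`, `"isoflurane"` or `"none"`.
#' @return A tibble with columns `neuron_id`, `condition`, `anesthetic`,
#'   `duration`, `n_spikes` and the `spikes` list-column.
#' @export
#' @examples
#' spike_trains("n1", list(c(0.1, 0.5, 2)), duration = 10)
spike_trains <- function(neuron_id, spikes, duration,
                         condition = "anesthetized", anesthetic = "none") {
  if (!is.list(spikes)) spikes <- list(spikes)
  n <- length(neuron_id)
  stopifnot(length(spikes) == n, length(duration) %in% c(1L, n))
  if (length(duration) == 1L) duration <- rep(duration, n)
  if (length(condition) == 1L) condition <- rep(condition, n)
  if (length(anesthetic) == 1L) anesthetic <- rep(anesthetic, n)
  out <- tibble::tibble(
    neuron_id = as.character(neuron_id),
    condition = condition,
    anesthetic = anesthetic,
    duration = as.numeric(duration),
    n_spikes = vapply(spikes, length, integer(1)),
    spikes = lapply(spikes, as.numeric)
  )
  validate_spike_trains(out)
  out
}

conditions_allowed <- c("anesthetized", "awake")
anesthetics_allowed <- c("ketamine_xylazine", "isoflurane", "none")

#' Validate a spike-train table
#'
#' Checks the container invariants and fails with a message naming the first
#' offending neuron. Called by [spike_trains()] and the dataset reader;
#' exported so externally assembled tables can be checked too.
#'
#' @param x A tibble as produced by [spike_trains()].
#' @return `x`, invisibly, if all checks pass.
#' @export
validate_spike_trains <- function(x) {
  need <- c("neuron_id", "condition", "anesthetic", "duration", "spikes")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(x$neuron_id))
    abort(paste0("duplicated neuron_id: ", x$neuron_id[duplicated(x$neuron_id)][1]))
  bad_cond <- !x$condition %in% conditions_allowed
  if (any(bad_cond))
    abort(sprintf("neuron '%s': unknown condition label '%s'",
                  x$neuron_id[bad_cond][1], x$condition[bad_cond][1]))
  bad_an <- !x$anesthetic %in% anesthetics_allowed
  if (any(bad_an))
    abort(sprintf("neuron '%s': unknown anesthetic label '%s'",
                  x$neuron_id[bad_an][1], x$anesthetic[bad_an][1]))
  if (any(!is.finite(x$duration) | x$duration <= 0)) {
    i <- which(!is.finite(x$duration) | x$duration <= 0)[1]
    abort(sprintf("neuron '%s': duration must be a positive number", x$neuron_id[i]))
  }
  for (i in seq_len(nrow(x))) {
    s <- x$spikes[[i]]
    if (!length(s)) next
    if (any(!is.finite(s)))
      abort(sprintf("neuron '%s': non-finite spike times", x$neuron_id[i]))
    if (any(s < 0) || any(s > x$duration[i]))
      abort(sprintf("neuron '%s': spike times outside [0, duration]", x$neuron_id[i]))
    if (any(diff(s) <= 0))
      abort(sprintf("neuron '%s': spike times must be strictly increasing", x$neuron_id[i]))
  }
  invisible(x)
}

#' Assemble a stimulus-trial table
#'
#' One row per neuron with the stimulus onset times of its trial block.
#' Onsets must be ascending and spaced at least one stimulus duration apart.
#'
#' @param neuron_id Character vector of neuron identifiers.
#' @param onsets List of numeric vectors of stimulus onset times (s).
#' @param stim_duration Stimulus duration in seconds (default 0.5).
#' @return Tibble with columns `neuron_id`, `stim_duration`, `n_trials`,
#'   `onsets` (list-column).
#' @export
trial_sets <- function(neuron_id, onsets, stim_duration = 0.5) {
  if (!is.list(onsets)) onsets <- list(onsets)
  stopifnot(length(neuron_id) == length(onsets))
  for (i in seq_along(onsets)) {
    o <- onsets[[i]]
    if (length(o) > 1 && any(diff(o) < stim_duration))
      abort(sprintf("neuron '%s': trial onsets closer than the stimulus duration",
                    neuron_id[i]))
  }
  tibble::tibble(
    neuron_id = as.character(neuron_id),
    stim_duration = stim_duration,
    n_trials = vapply(onsets, length, integer(1)),
    onsets = lapply(onsets, as.numeric)
  )
}

#' Assemble a motion-energy trace table
#'
#' Facial motion energy is a regularly sampled nonnegative scalar series per
#' session; stored long with one row per sample.
#'
#' @param session_id Session identifier (length 1).
#' @param energy Numeric vector of motion-energy samples.
#' @param sample_rate Sampling rate in Hz.
#' @return Tibble with columns `session_id`, `time`, `energy` and the
#'   sampling rate stored in attribute `"sample_rate"`.
#' @export
motion_trace <- function(session_id, energy, sample_rate) {
  stopifnot(length(session_id) == 1, sample_rate > 0)
  if (any(!is.finite(energy))) abort("motion energy must be finite")
  if (any(energy < 0)) abort("motion energy must be nonnegative")
  out <- tibble::tibble(
    session_id = as.character(session_id),
    time = (seq_along(energy) - 1) / sample_rate,
    energy = as.numeric(energy)
  )
  attr(out, "sample_rate") <- sample_rate
  out
}
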