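#' Peristimulus time histogram
#'
#' Trial-averaged firing rate around stimulus onset: counts pooled over
#' trials divided by `n_trials * bin_width`. The z-scored rate uses the
#' pre-stimulus bins of the window as baseline by default (the 1 s FSMI
#' baseline is available via `z_baseline = "1s"`). Trials whose window
#' extends beyond the recording are dropped with a warning.
#'
#' @param spikes Sorted spike times (s).
#' @param onsets Stimulus onset times (s).
#' @param duration Recording duration (s).
#' @param window PSTH window around onset (s), default `c(-0.2, 1.3)`.
#' @param bin_width Bin width (s), default 0.02 (75 bins at defaults).
#' @param z_baseline `"window"` (pre-stimulus PSTH bins) or `"1s"`.
#' @return Tibble with `time` (bin centers relative to onset), `rate` (Hz)
#'   and `z` (`NA` if the baseline is degenerate); attribute `n_trials`.
#' @export
compute_psth <- function(spikes, onsets, duration,
                         window = hab_defaults()$psth_window,
                         bin_width = hab_defaults()$psth_bin_width,
                         z_baseline = c("window", "1s")) {
  z_baseline <- match.arg(z_baseline)
  usable <- onsets[onsets + window[1] >= 0 & onsets + window[2] <= duration]
  if (length(usable) < length(onsets))
    warn(sprintf("dropping %d trial(s) truncated by recording edges",
                 length(onsets) - length(usable)))
  if (!length(usable)) abort("no usable trials")
  edges <- seq(window[1], window[2], by = bin_width)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  for (on in usable) {
    rel <- spikes[spikes >= on + window[1] & spikes < on + window[2]] - on
    idx <- pmin(floor((rel - window[1]) / bin_width), n_bins - 1L) + 1L
    counts <- counts + tabulate(idx, nbins = n_bins)
  }
  rate <- counts / (length(usable) * bin_width)
  mids <- edges[-length(edges)] + bin_width / 2
  base <- if (z_baseline == "window") rate[mids < 0] else {
    br <- vapply(usable, function(on)
      sum(spikes >= on - 1 & spikes < on), numeric(1))
    br  # per-trial 1 s counts; z uses their mean/sd converted to Hz
  }
  mu <- mean(base); s <- sd(base)
  z <- if (is.na(s) || s == 0) rep(NA_real_, n_bins) else (rate - mu) / s
  out <- tibble::tibble(time = mids, rate = rate, z = z)
  attr(out, "n_trials") <- length(usable)
  attr(out, "bin_width") <- bin_width
  out
}

#' Foot-shock modulation index of one neuron
#'
#' `FSMI = (FR_stim - FR_base) / (FR_stim + FR_base)`, with the baseline
#' rate from the 1 s before each onset and the stimulus rate from the
#' stimulus window, both pooled over trials. Neurons whose spontaneous rate
#' is below `min_rate` (1 Hz) are flagged `excluded` and get `NA`.
#'
#' @param spikes Sorted spike times (s).
#' @param onsets Stimulus onset times (s).
#' @param duration Recording duration (s).
#' @param stim_duration Stimulus window length (s), default 0.5.
#' @param baseline Baseline window length (s), default 1.
#' @param min_rate Spontaneous-rate exclusion threshold (Hz), default 1.
#' @return One-row tibble: `fr_baseline`, `fr_stimulus`, `fsmi`,
#'   `excluded`, `n_trials`.
#' @export
compute_fsmi <- function(spikes, onsets, duration,
                         stim_duration = hab_defaults()$stim_duration,
                         baseline = hab_defaults()$fs_baseline,
                         min_rate = hab_defaults()$fs_min_rate) {
  usable <- onsets[onsets - baseline >= 0 & onsets + stim_duration <= duration]
  spont <- length(spikes) / duration
  if (spont < min_rate || !length(usable)) {
    return(tibble::tibble(fr_baseline = NA_real_, fr_stimulus = NA_real_,
                          fsmi = NA_real_, excluded = TRUE,
                          n_trials = length(usable)))
  }
  nb <- sum(vapply(usable, function(on)
    sum(spikes >= on - baseline & spikes < on), numeric(1)))
  ns <- sum(vapply(usable, function(on)
    sum(spikes >= on & spikes < on + stim_duration), numeric(1)))
  fr_b <- nb / (length(usable) * baseline)
  fr_s <- ns / (length(usable) * stim_duration)
  fsmi <- if (fr_b + fr_s == 0) NA_real_ else (fr_s - fr_b) / (fr_s + fr_b)
  tibble::tibble(fr_baseline = fr_b, fr_stimulus = fr_s, fsmi = fsmi,
                 excluded = FALSE, n_trials = length(usable))
}

#' Sustained-response area under the curve
#'
#' Integrates the z-scored PSTH over the first 300 ms after stimulus onset
#' (sum of the bin z-scores times the bin width; 15 bins at defaults).
#'
#' @param psth Output of [compute_psth()].
#' @param response_window Integration end (s), default 0.3.
#' @return Scalar AUC (z * s), or `NA` if the baseline was degenerate.
#' @export
compute_auc300 <- function(psth, response_window = 0.3) {
  bw <- attr(psth, "bin_width")
  idx <- psth$time > 0 & psth$time < response_window
  if (all(is.na(psth$z[idx]))) return(NA_real_)
  sum(psth$z[idx]) * bw
}

#' Foot-shock modulation of a dataset
#'
#' Per-neuron FSMI and 300 ms response AUC for every neuron that has a
#' trial block.
#'
#' @param neurons Spike-train tibble.
#' @param trials Trial tibble ([trial_sets()]).
#' @param ... Passed to [compute_fsmi()] and [compute_psth()].
#' @return Tibble with one row per neuron: the FSMI fields plus `auc_300`.
#' @export
shock_modulation <- function(neurons, trials, ...) {
  validate_spike_trains(neurons)
  ids <- intersect(neurons$neuron_id, trials$neuron_id)
  purrr::map_dfr(ids, function(id) {
    i <- match(id, neurons$neuron_id); j <- match(id, trials$neuron_id)
    s <- neurons$spikes[[i]]; on <- trials$onsets[[j]]
    rec <- compute_fsmi(s, on, neurons$duration[i],
                        stim_duration = trials$stim_duration[j])
    auc <- if (rec$excluded) NA_real_ else {
      psth <- suppressWarnings(compute_psth(s, on, neurons$duration[i]))
      compute_auc300(psth)
    }
    dplyr::bind_cols(tibble::tibble(neuron_id = id), rec,
                     tibble::tibble(auc_300 = auc))
  })
}
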