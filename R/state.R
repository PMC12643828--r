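#' Partition a session into active and quiet epochs
#'
#' The motion-energy trace is lightly smoothed (0.5 s moving average) and
#' thresholded sample-wise at its empirical 80th/20th percentiles: samples
#' above the 80th percentile are "active", below the 20th "quiet",
#' everything in between belongs to neither. Adjacent same-state samples
#' are merged into epochs; epochs shorter than `min_epoch` are dropped.
#' Thresholds are rank-based, hence invariant to monotone rescaling.
#'
#' @param motion Motion-trace tibble ([motion_trace()]); >= 60 s advised.
#' @param active_percentile,quiet_percentile Percentile cuts (0.8 / 0.2).
#' @param smooth Moving-average width (s) before thresholding.
#' @param min_epoch Minimum epoch length (s).
#' @return Tibble of epochs: `state` ("active"/"quiet"), `start`, `end`
#'   (s, half-open `[start, end)`), with the thresholds in attributes.
#' @export
partition_states <- function(motion,
                             active_percentile = hab_defaults()$active_percentile,
                             quiet_percentile = hab_defaults()$quiet_percentile,
                             smooth = hab_defaults()$motion_smooth,
                             min_epoch = hab_defaults()$min_epoch) {
  sr <- attr(motion, "sample_rate")
  if (is.null(sr)) {
    dt <- diff(motion$time)
    sr <- 1 / stats::median(dt)
  }
  e <- motion$energy
  if (max(e) == min(e))
    abort("constant motion trace: percentile thresholds coincide")
  es <- smooth_ma(e, max(1L, round(smooth * sr)))
  thr_hi <- quantile(es, active_percentile, names = FALSE)
  thr_lo <- quantile(es, quiet_percentile, names = FALSE)
  if (thr_hi <= thr_lo)
    abort("degenerate trace: active and quiet thresholds coincide")
  state <- ifelse(es > thr_hi, "active", ifelse(es < thr_lo, "quiet", "mid"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  dt <- 1 / sr
  out <- tibble::tibble(
    state = r$values,
    start = (starts - 1) * dt,
    end = ends * dt
  )
  out <- out[out$state != "mid" & (out$end - out$start) >= min_epoch, ]
  attr(out, "thresholds") <- c(quiet = thr_lo, active = thr_hi)
  attr(out, "sample_rate") <- sr
  out
}

#' Behavioral-state modulation index of one neuron
#'
#' `BSMI = (FR_active - FR_quiet) / (FR_active + FR_quiet)` with the rates
#' computed from total spikes over total time in each state. The per-epoch
#' rate vectors are retained for the significance test.
#'
#' @param spikes Sorted spike times (s).
#' @param epochs Epoch tibble from [partition_states()].
#' @param min_state_time Minimum total time (s) per state (default 10).
#' @return One-row tibble: `fr_active`, `fr_quiet`, `bsmi`, `flagged`
#'   (insufficient data or both rates zero), and list-columns
#'   `active_rates`, `quiet_rates` of per-epoch rates.
#' @export
compute_bsmi <- function(spikes, epochs,
                         min_state_time = hab_defaults()$min_state_time) {
  ep_rate <- function(st) {
    ep <- epochs[epochs$state == st, ]
    if (!nrow(ep)) return(list(time = 0, n = 0, rates = numeric(0)))
    counts <- vapply(seq_len(nrow(ep)), function(i)
      sum(spikes >= ep$start[i] & spikes < ep$end[i]), numeric(1))
    lens <- ep$end - ep$start
    list(time = sum(lens), n = sum(counts), rates = counts / lens)
  }
  a <- ep_rate("active"); q <- ep_rate("quiet")
  enough <- a$time >= min_state_time && q$time >= min_state_time
  fr_a <- if (a$time > 0) a$n / a$time else NA_real_
  fr_q <- if (q$time > 0) q$n / q$time else NA_real_
  bsmi <- if (!enough || (isTRUE(fr_a + fr_q == 0))) NA_real_ else
    (fr_a - fr_q) / (fr_a + fr_q)
  tibble::tibble(fr_active = fr_a, fr_quiet = fr_q, bsmi = bsmi,
                 flagged = !enough || isTRUE(fr_a + fr_q == 0),
                 active_rates = list(a$rates), quiet_rates = list(q$rates))
}

#' Classify a neuron's state modulation
#'
#' Two-sample rank test (unpaired Wilcoxon/Mann-Whitney) on the per-epoch
#' rates of the two states. The category is "increase"/"decrease" by the
#' sign of the rate difference when p < alpha, "no_change" otherwise.
#' With fewer than `min_epochs` per state the neuron is "no_change" with
#' an insufficient-data flag.
#'
#' @param record One-row tibble from [compute_bsmi()].
#' @param alpha Significance level (default 0.05).
#' @param min_epochs Minimum epochs per state (default 3).
#' @return The record with `category`, `p_value` and `insufficient` added.
#' @export
classify_modulation <- function(record, alpha = hab_defaults()$alpha,
                                min_epochs = hab_defaults()$min_epochs_test) {
  a <- record$active_rates[[1]]; q <- record$quiet_rates[[1]]
  if (length(a) < min_epochs || length(q) < min_epochs) {
    record$category <- "no_change"; record$p_value <- NA_real_
    record$insufficient <- TRUE
    return(record)
  }
  p <- if (isTRUE(all.equal(sort(a), sort(q)))) 1 else
    suppressWarnings(wilcox.test(a, q, exact = FALSE)$p.value)
  record$category <- if (is.na(p) || p >= alpha) "no_change"
    else if (mean(a) > mean(q)) "increase" else "decrease"
  record$p_value <- p
  record$insufficient <- FALSE
  record
}

#' Behavioral-state modulation of a dataset
#'
#' Per-neuron state partition, BSMI and significance category for every
#' neuron with a paired motion trace (matched by id = session).
#'
#' @param neurons Spike-train tibble.
#' @param motion Motion-trace tibble (possibly several sessions stacked).
#' @param ... Passed to [partition_states()].
#' @param alpha Significance level for the per-neuron test.
#' @return Tibble with one row per neuron: BSMI fields plus `category`,
#'   `p_value`.
#' @export
state_modulation <- function(neurons, motion, ..., alpha = hab_defaults()$alpha) {
  validate_spike_trains(neurons)
  sr <- attr(motion, "sample_rate")
  ids <- intersect(neurons$neuron_id, unique(motion$session_id))
  purrr::map_dfr(ids, function(id) {
    i <- match(id, neurons$neuron_id)
    m <- motion[motion$session_id == id, ]
    attr(m, "sample_rate") <- sr
    ep <- partition_states(m, ...)
    rec <- compute_bsmi(neurons$spikes[[i]], ep)
    rec <- classify_modulation(rec, alpha = alpha)
    dplyr::bind_cols(tibble::tibble(neuron_id = id), rec)
  })
}
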