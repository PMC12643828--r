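#' Scalar firing statistics of one spike train
#'
#' Rate = spike count / duration; CV = population SD of the ISIs over their
#' mean; burst index = fraction of ISIs shorter than 25 ms. CV and burst
#' index need at least two ISIs (three spikes) and are `NA` otherwise.
#'
#' @param spikes Numeric vector of sorted spike times (s).
#' @param duration Recording duration (s).
#' @param burst_isi_max Burst criterion (s), default 0.025.
#' @return One-row tibble: `rate`, `cv`, `burst_index`, `n_spikes`.
#' @export
#' @examples
#' spike_stats(c(0, 0.010, 0.020, 0.520, 1.020), duration = 2)
spike_stats <- function(spikes, duration,
                        burst_isi_max = hab_defaults()$burst_isi_max) {
  n <- length(spikes)
  isi <- diff(spikes)
  if (length(isi) >= 2) {
    pop_sd <- sd(isi) * sqrt((length(isi) - 1) / length(isi))
    cv <- pop_sd / mean(isi)
    bi <- mean(isi < burst_isi_max)
  } else {
    cv <- NA_real_; bi <- NA_real_
  }
  tibble::tibble(rate = n / duration, cv = cv, burst_index = bi, n_spikes = n)
}

#' Interspike-interval histogram
#'
#' Distribution of ISIs over `[0, max_isi]`, normalized by the *total* ISI
#' count (intervals beyond the range fall outside the histogram but stay in
#' the denominator, so the in-range mass keeps the rate information).
#'
#' @param spikes Sorted spike times (s); needs >= 2 spikes.
#' @param bin_width Bin width (s), default 5 ms.
#' @param max_isi Histogram range (s), default 0.5.
#' @return Tibble with `bin_mid` and `mass` (fraction of all ISIs per bin).
#' @export
isi_histogram <- function(spikes, bin_width = hab_defaults()$isi_bin_width,
                          max_isi = hab_defaults()$isi_max) {
  if (length(spikes) < 2) abort("need at least 2 spikes for an ISI histogram")
  isi <- diff(spikes)
  edges <- seq(0, max_isi, by = bin_width)
  idx <- findInterval(isi, edges, rightmost.closed = FALSE, left.open = TRUE)
  # interval (edges[i], edges[i+1]]; ISIs above max_isi get index > n_bins
  n_bins <- length(edges) - 1L
  counts <- tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  tibble::tibble(
    bin_mid = edges[-length(edges)] + bin_width / 2,
    mass = counts / length(isi)
  )
}

#' Spike-train autocorrelogram
#'
#' Histogram of all ordered spike-pair lags within `[-max_lag, max_lag]`,
#' zero-lag self-pairs excluded, normalized by the number of spikes. The
#' result is symmetric by the pair-counting identity.
#'
#' @param spikes Sorted spike times (s); needs >= 2 spikes.
#' @param bin_width Bin width (s), default 2 ms.
#' @param max_lag Maximum lag (s), default 0.1.
#' @return Tibble with `lag_mid` and `count_per_spike`.
#' @export
spike_acg <- function(spikes, bin_width = hab_defaults()$acg_bin_width,
                      max_lag = hab_defaults()$acg_max_lag) {
  if (length(spikes) < 2) abort("need at least 2 spikes for an autocorrelogram")
  n_side <- round(max_lag / bin_width)
  pos <- numeric(n_side)
  n <- length(spikes)
  k <- 2L
  for (i in seq_len(n - 1L)) {
    if (k <= i) k <- i + 1L
    while (k <= n && spikes[k] - spikes[i] <= max_lag) k <- k + 1L
    if (k > i + 1L) {
      d <- spikes[(i + 1L):(k - 1L)] - spikes[i]
      b <- pmin(floor(d / bin_width), n_side - 1L) + 1L
      pos <- pos + tabulate(b, nbins = n_side)
    }
  }
  ctr <- seq_len(n_side) * bin_width - bin_width / 2
  tibble::tibble(
    lag_mid = c(-rev(ctr), ctr),
    count_per_spike = c(rev(pos), pos) / n
  )
}

#' Per-neuron spontaneous-activity features
#'
#' Computes the scalar statistics, ISI histogram and autocorrelogram for
#' every neuron of a spike-train table. Neurons with fewer than
#' `min_spikes` spikes are kept in the output with `included = FALSE`
#' (their rate is reported but they are excluded from clustering).
#'
#' @param neurons Spike-train tibble ([spike_trains()]).
#' @param isi_bin_width,acg_bin_width Histogram bin widths (s).
#' @param min_spikes Minimum spikes for clustering inclusion (default 10).
#' @return Tibble with `neuron_id`, scalar features, `included`, and
#'   list-columns `isi` and `acg` holding the per-neuron histograms.
#' @export
#' @examples
#' pop <- simulate_population(n_per_type = 2, duration = 60, seed = 1)
#' compute_features(pop$neurons)
compute_features <- function(neurons,
                             isi_bin_width = hab_defaults()$isi_bin_width,
                             acg_bin_width = hab_defaults()$acg_bin_width,
                             min_spikes = hab_defaults()$min_spikes) {
  validate_spike_trains(neurons)
  purrr::map2_dfr(neurons$spikes, seq_len(nrow(neurons)), function(s, i) {
    st <- spike_stats(s, neurons$duration[i])
    ok <- length(s) >= max(min_spikes, 2L)
    dplyr::bind_cols(
      tibble::tibble(neuron_id = neurons$neuron_id[i]),
      st,
      tibble::tibble(
        included = ok && !is.na(st$cv),
        isi = list(if (ok) isi_histogram(s, isi_bin_width) else NULL),
        acg = list(if (ok) spike_acg(s, acg_bin_width) else NULL)
      )
    )
  })
}

# stack the per-neuron histogram list-column into a matrix (neurons x bins)
feature_bank <- function(features, which = c("isi", "acg")) {
  which <- match.arg(which)
  f <- features[features$included, ]
  if (!nrow(f)) abort("no included neurons")
  valcol <- if (which == "isi") "mass" else "count_per_spike"
  m <- do.call(rbind, lapply(f[[which]], function(h) h[[valcol]]))
  rownames(m) <- f$neuron_id
  m
}
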