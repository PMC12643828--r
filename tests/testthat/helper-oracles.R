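# Independent oracles and fixture builders used across the suite.

# naive O(n^2) pair-enumeration autocorrelogram (bin-for-bin reference)
oracle_acg <- function(spikes, bin_width = 0.002, max_lag = 0.1) {
  n_side <- round(max_lag / bin_width)
  pos <- numeric(n_side)
  n <- length(spikes)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- spikes[j] - spikes[i]
    if (d > 0 && d <= max_lag) {
      b <- min(floor(d / bin_width), n_side - 1) + 1
      pos[b] <- pos[b] + 1
    }
  }
  c(rev(pos), pos) / n
}

# naive ISI histogram, total-ISI denominator, bins (left, right]
oracle_isi_hist <- function(spikes, bin_width = 0.005, max_isi = 0.5) {
  isi <- diff(spikes)
  n_bins <- round(max_isi / bin_width)
  counts <- numeric(n_bins)
  for (x in isi) {
    b <- ceiling(x / bin_width)
    if (x > 0 && b >= 1 && b <= n_bins && x <= b * bin_width &&
        x > (b - 1) * bin_width)
      counts[b] <- counts[b] + 1
  }
  counts / length(isi)
}

# random irregular spike train with occasional near-coincident spikes
random_train <- function(n_spikes, duration = 10) {
  t <- sort(runif(n_spikes, 0, duration))
  t[diff(c(-1, t)) > 1e-6]
}

# directly assembled PSTH tibble for AUC arithmetic checks
fake_psth <- function(z, bin_width = 0.02, window = c(-0.2, 1.3)) {
  mids <- seq(window[1], window[2] - bin_width, by = bin_width) + bin_width / 2
  out <- tibble::tibble(time = mids, rate = 0, z = z)
  attr(out, "bin_width") <- bin_width
  out
}

# wrap an arbitrary n x 19 matrix as a feature table (for clustering tests
# that need full control of the geometry)
fake_feature_table <- function(x) {
  stopifnot(ncol(x) == 19)
  colnames(x) <- c("rate", "cv", "burst_index",
                   paste0("isi_pc", 1:8), paste0("acg_pc", 1:8))
  tab <- dplyr::bind_cols(
    tibble::tibble(neuron_id = sprintf("m%03d", seq_len(nrow(x)))),
    tibble::as_tibble(x))
  structure(tab,
            scaling = list(center = colMeans(x), scale = apply(x, 2, sd)),
            class = c("hab_features", class(tab)))
}
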