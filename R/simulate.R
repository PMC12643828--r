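# ---- renewal-process calibration -------------------------------------------
#
# The generator is a refractory gamma renewal process with probabilistic
# burst insertion. Each base event starts, with probability p, a run of
# extra spikes at uniform intra-burst ISIs; the renewal clock restarts after
# the last spike of the burst. With
#   f  = expected fraction of ISIs that are intra-burst,
#   mu_s = mean intra-burst ISI,  mu_g = mean base gap,
# the spike rate, the ISI mixture mean and second moment have closed forms,
# so (rate, cv, burst_index) targets map to (p, mu_g, gamma shape) directly.
# The refractory offset keeps base gaps above the 25 ms burst criterion, so
# the burst index is controlled by f alone except at very high rates, where
# a short fixed-point iteration absorbs the base-gap contribution.
calibrate_renewal <- function(rate, cv, burst, burst_len = 2,
                              intra = c(0.003, 0.015), refractory = 0.026,
                              shape_range = c(0.05, 500)) {
  if (!is.finite(rate) || rate <= 0) abort("target rate must be positive")
  if (cv < 0 || burst < 0 || burst >= 1) abort("invalid cv or burst target")
  mu_s <- mean(intra)
  var_s <- diff(range(intra))^2 / 12
  f <- burst
  mu_g <- 1 / rate; t0 <- refractory; shape <- 1; mu_p <- mu_g
  for (it in 1:6) {
    pm <- f / (1 - f)
    mu_g <- (1 + pm) / rate - pm * mu_s
    mu_g <- max(mu_g, 0.004)
    t0 <- min(refractory, 0.6 * mu_g)
    mu_p <- mu_g - t0
    mu <- 1 / rate
    ex2 <- (1 + cv^2) * mu^2
    ex2_base <- (ex2 - f * (var_s + mu_s^2)) / (1 - f)
    var_g <- ex2_base - mu_g^2
    shape <- if (var_g <= 0) shape_range[2] else
      min(max(mu_p^2 / var_g, shape_range[1]), shape_range[2])
    p_short <- if (t0 >= 0.025) 0 else
      pgamma(0.025 - t0, shape = shape, scale = mu_p / shape)
    f_new <- max(0, (burst - p_short) / (1 - p_short))
    if (abs(f_new - f) < 1e-7) { f <- f_new; break }
    f <- f_new
  }
  pm <- f / (1 - f)
  m <- burst_len
  p <- if (m > 0) pm / m else 0
  if (p > 0.95) { m <- min(8, pm / 0.95); p <- pm / m }
  list(p = min(p, 1), burst_len = m, mu_g = mu_g, refractory = t0,
       gap_mean = mu_p, shape = shape)
}

#' Simulate one spontaneous spike train
#'
#' Generates a spike train whose firing rate, ISI coefficient of variation
#' and burst index match the requested targets. The base process is a
#' gamma renewal process with an absolute refractory offset; bursts are
#' inserted after base events with geometric lengths and uniform intra-burst
#' ISIs, all below the 25 ms burst-index criterion. Calibration is
#' closed-form (see the methods vignette) and typically lands within a few
#' percent of the targets for recordings of a minute or more.
#'
#' @param rate Target mean firing rate (Hz), > 0.
#' @param cv Target ISI coefficient of variation.
#' @param burst_index Target fraction of ISIs < 25 ms, in `[0, 1)`.
#' @param duration Recording length in seconds (>= 60 s recommended).
#' @param seed Optional integer seed for reproducibility.
#' @param burst_len Mean number of extra spikes per burst.
#' @param intra Intra-burst ISI range (s); must stay below 25 ms.
#' @param refractory Minimum base interspike interval (s).
#' @return Numeric vector of sorted spike times in `(0, duration]`.
#' @export
#' @examples
#' s <- simulate_spike_train(5, 1, 0.1, duration = 60, seed = 1)
#' length(s) / 60  # close to 5 Hz
simulate_spike_train <- function(rate, cv, burst_index, duration,
                                 seed = NULL, burst_len = 2,
                                 intra = c(0.003, 0.015), refractory = 0.026) {
  if (duration <= 0) abort("duration must be positive")
  if (max(intra) >= 0.025)
    warn("intra-burst ISIs reach the 25 ms criterion; burst index will undershoot")
  run <- function() {
    cb <- calibrate_renewal(rate, cv, burst_index, burst_len, intra, refractory)
    chunk <- ceiling(rate * duration * 1.5) + 50L
    t <- 0; out <- numeric(0)
    repeat {
      gaps <- cb$refractory +
        rgamma(chunk, shape = cb$shape, scale = cb$gap_mean / cb$shape)
      for (g in gaps) {
        t <- t + g
        if (t > duration) break
        out <- c(out, t)
        if (cb$p > 0 && runif(1) < cb$p) {
          nb <- 1L + rgeom(1, prob = 1 / cb$burst_len)
          tt <- t + cumsum(runif(nb, intra[1], intra[2]))
          tt <- tt[tt <= duration]
          out <- c(out, tt)
          if (length(tt)) t <- tt[length(tt)]
        }
      }
      if (t > duration) break
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# truncated-normal draw and density on [lo, hi]
rtnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}
dtnorm <- function(x, mean, sd, lo, hi) {
  if (sd <= 0) return(as.numeric(x == min(max(mean, lo), hi)))
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  ifelse(x >= lo & x <= hi, dnorm(x, mean, sd) / z, 0)
}

param_bounds <- list(rate = c(0.25, 80), cv = c(0.05, 3.2), burst = c(0, 0.88))

# draw (rate, cv, burst) for one neuron of a given type, keeping only draws
# whose own type is the maximum-likelihood generator (classification-
# consistent sampling; mirrors the hard assignment that produced the
# published per-cluster statistics)
draw_type_params <- function(type, presets, dispersion_scale = 0.3,
                             max_tries = 300L) {
  b <- param_bounds
  pp <- presets[presets$type == type, ]
  loglik_type <- function(v, row) {
    log(dtnorm(v[1], row$rate, row$rate_sd * dispersion_scale, b$rate[1], b$rate[2]) + 1e-300) +
    log(dtnorm(v[2], row$cv, row$cv_sd * dispersion_scale, b$cv[1], b$cv[2]) + 1e-300) +
    log(dtnorm(v[3], row$burst, row$burst_sd * dispersion_scale, b$burst[1], b$burst[2]) + 1e-300)
  }
  for (i in seq_len(max_tries)) {
    v <- c(rtnorm1(pp$rate, pp$rate_sd * dispersion_scale, b$rate[1], b$rate[2]),
           rtnorm1(pp$cv, pp$cv_sd * dispersion_scale, b$cv[1], b$cv[2]),
           rtnorm1(pp$burst, pp$burst_sd * dispersion_scale, b$burst[1], b$burst[2]))
    ll <- vapply(seq_len(nrow(presets)),
                 function(j) loglik_type(v, presets[j, ]), numeric(1))
    if (presets$type[which.max(ll)] == type) return(v)
  }
  v
}

#' Simulate a population of typed spike trains
#'
#' Draws `n_per_type` neurons from each firing-phenotype preset, simulates
#' their spontaneous activity and returns the shuffled population together
#' with the planted type labels (stored separately, as ground truth for
#' recovery experiments).
#'
#' Per-neuron targets are drawn from truncated normals centred on the preset
#' means with SDs scaled by `dispersion_scale`, and a draw is accepted only
#' if its own type is the maximum-likelihood generator among all presets.
#' See the methods vignette for why the published SDs are not used verbatim
#' as independent dispersions.
#'
#' @param presets Preset tibble, e.g. [lhb_type_presets()]; >= 2 rows.
#' @param n_per_type Neurons per type (>= 1).
#' @param duration Recording length per neuron (s).
#' @param seed Integer seed; the whole population is reproducible from it.
#' @param dispersion_scale Multiplier on the preset SDs (default 0.3).
#' @param condition Condition label stamped on the neurons.
#' @return A list with `neurons` (spike-train tibble) and `labels`
#'   (tibble of `neuron_id`, `type`, plus the drawn per-neuron targets).
#' @export
#' @examples
#' pop <- simulate_population(n_per_type = 3, duration = 60, seed = 1)
#' nrow(pop$neurons)
simulate_population <- function(presets = lhb_type_presets(),
                                n_per_type = 70, duration = 120, seed = NULL,
                                dispersion_scale = 0.3,
                                condition = c("anesthetized", "awake")) {
  condition <- match.arg(condition)
  if (nrow(presets) < 2) abort("need at least two type presets")
  if (n_per_type < 1) abort("n_per_type must be >= 1")
  run <- function() {
    rows <- list(); labs <- list()
    idx <- 0L
    for (j in seq_len(nrow(presets))) {
      pp <- presets[j, ]
      for (i in seq_len(n_per_type)) {
        idx <- idx + 1L
        v <- draw_type_params(pp$type, presets, dispersion_scale)
        s <- simulate_spike_train(v[1], v[2], v[3], duration,
                                  burst_len = pp$burst_len,
                                  intra = c(pp$intra_min, pp$intra_max))
        rows[[idx]] <- s
        labs[[idx]] <- tibble::tibble(type = pp$type, rate_target = v[1],
                                      cv_target = v[2], burst_target = v[3])
      }
    }
    ord <- sample(idx)
    ids <- sprintf("sim%03d", seq_len(idx))
    neurons <- spike_trains(ids, rows[ord], duration, condition = condition)
    labels <- dplyr::bind_rows(labs[ord])
    labels$neuron_id <- ids
    labels <- dplyr::relocate(labels, "neuron_id")
    list(neurons = neurons, labels = labels)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# two alpha-shaped kernels peaking at the short and long response latencies,
# normalized to unit mean over the stimulus window so that the planted gain
# equals the expected stimulus-window rate multiplier
shock_kernel <- function(t, short_peak = 0.04, long_peak = 0.21,
                         mix = c(1, 1), stim_duration = 0.5) {
  alpha <- function(t, tau) ifelse(t > 0, (t / tau) * exp(1 - t / tau), 0)
  raw <- function(t) mix[1] * alpha(t, short_peak) + mix[2] * alpha(t, long_peak)
  tt <- seq(0, stim_duration, length.out = 2001)
  norm <- mean(raw(tt))
  raw(t) / norm
}

#' Simulate a foot-shock stimulation session
#'
#' Spikes are drawn from an inhomogeneous Poisson process whose intensity is
#' the baseline rate times `1 + (gain - 1) * kernel(t - onset)` for excited
#' responses (two alpha-shaped components peaking at the short and long
#' latencies), or times `inhib_factor` during the stimulus window for
#' inhibited responses. The kernel is normalized so that the expected rate
#' over the stimulus window equals `gain * rate`, hence the foot-shock
#' modulation index converges to `(gain - 1) / (gain + 1)`.
#'
#' @param rate Baseline firing rate (Hz).
#' @param kind `"excited"`, `"inhibited"` or `"none"`.
#' @param gain Stimulus-window rate multiplier for excited responses.
#' @param inhib_factor Multiplier (< 1) during the stimulus for inhibited.
#' @param n_trials Number of stimuli (default 69, the reported mean).
#' @param period Stimulus period (s), default 5.
#' @param stim_duration Stimulus duration (s), default 0.5.
#' @param short_peak,long_peak Latencies (s) of the two excitatory peaks.
#' @param kernel_mix Relative weight of the short and long components.
#' @param pre Recording time before the first onset (s).
#' @param seed Optional integer seed.
#' @return List with `neurons` (one-row spike-train tibble) and `trials`
#'   (one-row trial tibble).
#' @export
simulate_shock_session <- function(rate, kind = c("excited", "inhibited", "none"),
                                   gain = 3, inhib_factor = 0.2, n_trials = 69,
                                   period = 5, stim_duration = 0.5,
                                   short_peak = 0.04, long_peak = 0.21,
                                   kernel_mix = c(1, 1), pre = 5, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "excited" && gain < 0) abort("gain must be nonnegative")
  if (kind == "inhibited" && (inhib_factor < 0 || inhib_factor >= 1))
    abort("inhib_factor must be in [0, 1)")
  duration <- pre + n_trials * period
  onsets <- pre + (seq_len(n_trials) - 1) * period
  intensity <- function(t) {
    lam <- rep(rate, length(t))
    if (kind == "none") return(lam)
    # time since the most recent onset (kernel tails are negligible after one period)
    rel <- t - onsets[pmax(1L, findInterval(t, onsets))]
    active <- rel >= 0 & t >= onsets[1]
    if (kind == "excited") {
      lam[active] <- rate * (1 + (gain - 1) *
        shock_kernel(rel[active], short_peak, long_peak, kernel_mix, stim_duration))
    } else {
      inwin <- active & rel < stim_duration
      lam[inwin] <- rate * inhib_factor
    }
    pmax(lam, 0)
  }
  run <- function() {
    lam_max <- if (kind == "excited")
      rate * (1 + (gain - 1) * max(shock_kernel(seq(0, stim_duration, 1e-3),
                                                short_peak, long_peak, kernel_mix,
                                                stim_duration))) else rate
    lam_max <- max(lam_max, rate) * 1.0001
    n_cand <- rpois(1, lam_max * duration)
    cand <- sort(runif(n_cand, 0, duration))
    keep <- runif(n_cand) < intensity(cand) / lam_max
    s <- cand[keep]
    s[diff(c(-1, s)) > 0]  # drop exact duplicates (measure-zero guard)
  }
  s <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(
    neurons = spike_trains("fs1", list(s), duration),
    trials = trial_sets("fs1", list(onsets), stim_duration)
  )
}

#' Simulate a behavioral-state session
#'
#' Generates a motion-energy-like trace (rectified, smoothed
#' Ornstein-Uhlenbeck noise) and a spike train whose intensity is
#' `rate * active_gain` whenever the smoothed motion exceeds its session
#' 80th percentile and `rate` otherwise, i.e. the planted coupling uses the
#' same percentile rule the analysis applies. The behavioral-state
#' modulation index therefore converges to `(g - 1) / (g + 1)`.
#'
#' @param rate Quiet-state firing rate (Hz).
#' @param active_gain Rate multiplier during high-motion samples (> 0).
#' @param session_length Session duration (s); >= 300 s recommended.
#' @param sample_rate Motion sampling rate (Hz).
#' @param tau Motion autocorrelation time (s).
#' @param smooth Moving-average width (s) applied before thresholding.
#' @param active_percentile Percentile defining the active state.
#' @param seed Optional integer seed.
#' @return List with `neurons` (one-row spike-train tibble) and `motion`
#'   (motion-trace tibble).
#' @export
simulate_state_session <- function(rate, active_gain = 2, session_length = 300,
                                   sample_rate = 20, tau = 2, smooth = 0.5,
                                   active_percentile = 0.8, seed = NULL) {
  if (active_gain <= 0) abort("active_gain must be positive")
  run <- function() {
    n <- ceiling(session_length * sample_rate)
    dt <- 1 / sample_rate
    a <- exp(-dt / tau)
    x <- numeric(n)
    x[1] <- rnorm(1)
    innov <- rnorm(n, sd = sqrt(1 - a^2))
    for (i in 2:n) x[i] <- a * x[i - 1] + innov[i]
    m <- abs(x)
    ms <- smooth_ma(m, max(1L, round(smooth * sample_rate)))
    thr <- quantile(ms, active_percentile, names = FALSE)
    lam <- ifelse(ms > thr, rate * active_gain, rate)
    # piecewise-constant intensity: Poisson counts per sample bin
    counts <- rpois(n, lam * dt)
    s <- sort(unlist(lapply(which(counts > 0), function(i)
      runif(counts[i], (i - 1) * dt, i * dt))))
    s <- s[diff(c(-1, s)) > 0]
    list(spikes = s, motion = m)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(
    neurons = spike_trains("bs1", list(out$spikes), session_length,
                           condition = "awake"),
    motion = motion_trace("bs1", out$motion, sample_rate)
  )
}

# centered moving average with shrinking edges
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
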