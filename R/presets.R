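#' Published LHb firing-phenotype presets
#'
#' Per-type targets for the four spontaneous firing phenotypes of lateral
#' habenula neurons, as reported for the anesthetized and awake datasets:
#' mean firing rate (Hz), coefficient of variation of the interspike
#' intervals, and burst index (fraction of ISIs < 25 ms), each with the
#' published between-neuron SD. Type-2 CVs are reconstructed from the
#' published Tukey mean differences against Type-1.
#'
#' Each preset also carries the temporal burst signature used by the
#' generator: the mean number of extra spikes per burst and the intra-burst
#' ISI range. These express the qualitative per-type descriptions (Type-1:
#' early, sharp ISI/ACG peak from short fast bursts; Type-2: regular firing,
#' late peaks; Type-4: sustained high-rate bursting with longer intra-burst
#' intervals, most pronounced awake).
#'
#' @param condition `"anesthetized"` (default) or `"awake"`.
#' @return A tibble with one row per type: `type`, `rate`, `rate_sd`, `cv`,
#'   `cv_sd`, `burst`, `burst_sd`, `burst_len`, `intra_min`, `intra_max`.
#' @export
#' @examples
#' lhb_type_presets("awake")
lhb_type_presets <- function(condition = c("anesthetized", "awake")) {
  condition <- match.arg(condition)
  if (condition == "anesthetized") {
    tibble::tibble(
      type = 1:4,
      rate = c(2.07, 3.45, 10.67, 19.57),
      rate_sd = c(2.29, 2.47, 4.61, 9.25),
      cv = c(1.53, 0.71, 0.74, 0.95),
      cv_sd = c(0.58, 0.30, 0.54, 0.62),
      burst = c(0.22, 0.0038, 0.03, 0.24),
      burst_sd = c(0.20, 0.0078, 0.03, 0.16),
      burst_len = c(3, 2, 2, 2.5),
      intra_min = c(0.003, 0.003, 0.003, 0.008),
      intra_max = c(0.010, 0.015, 0.015, 0.020)
    )
  } else {
    tibble::tibble(
      type = 1:4,
      rate = c(7.15, 7.37, 20.18, 46.42),
      rate_sd = c(6.78, 4.23, 5.80, 13.32),
      cv = c(1.57, 1.13, 0.93, 0.69),
      cv_sd = c(0.57, 0.40, 0.54, 0.24),
      burst = c(0.24, 0.06, 0.26, 0.69),
      burst_sd = c(0.17, 0.07, 0.10, 0.15),
      burst_len = c(3, 2, 2, 3),
      intra_min = c(0.003, 0.003, 0.003, 0.009),
      intra_max = c(0.010, 0.015, 0.015, 0.015)
    )
  }
}
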