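# habclust

Unsupervised classification of lateral habenula (LHb) neurons from in vivo
spike trains, and quantification of how the resulting firing phenotypes are
modulated by aversive stimuli and behavioral state.

The LHb relays aversive information to midbrain monoamine systems, and its
neurons fire in vivo in several distinct spontaneous patterns — from slow
irregular bursting to sustained high-rate firing. This package is for
electrophysiologists who have well-isolated single-unit spike times (e.g.
from juxtacellular recordings) and want to (i) classify neurons into firing
phenotypes without supervision, (ii) check that the phenotypes found in one
condition (anesthetized) correspond to those found in another (awake), and
(iii) relate phenotype membership to stimulus- and state-driven rate
modulation. Everything is validated against a calibrated synthetic
generator with planted ground truth, so the package is also a self-contained
test bed for this class of pipeline.

## The methods in brief

Per neuron, five spontaneous-activity descriptors: mean rate, ISI
coefficient of variation CV = σ(ISI)/mean(ISI), burst index (fraction of
ISIs < 25 ms), the ISI distribution (0–0.5 s), and the autocorrelogram
(±0.1 s). Sparse PCA reduces each histogram to 8 temporal components,
giving 19 features per neuron. Gaussian mixtures are fitted for k = 1…6
with 100 k-means-initialized EM restarts each; the number of clusters is
selected by the mean BIC, `BIC = -2 log L + M log N`, together with the
saturation of its gradient. Clusters from two datasets are matched by the
cosine similarity of their centroids, `S_C = A·B/(||A|| ||B||)`, under a
Hungarian assignment minimizing `Σ(1 − S_C)`, keeping pairs with
`S_C ≥ 0.6`. Modulation is quantified by two bounded indices,

    FSMI = (FR_stim − FR_base) / (FR_stim + FR_base)
    BSMI = (FR_active − FR_quiet) / (FR_active + FR_quiet)

where the foot-shock baseline is the 1 s before stimulus onset (neurons
below 1 Hz excluded), and active/quiet states are epochs where facial
motion energy is above its session 80th / below its 20th percentile.
Per-neuron state significance uses the unpaired rank-sum test on per-epoch
rates at α = 0.05. See the methods vignette
(`vignettes/habclust-methods.Rmd`) for every modeling choice and its
rationale.

## Worked example

Simulate a population with the four published anesthetized phenotypes,
cluster it, and inspect the result:

```r
library(habclust)

pop <- simulate_population(n_per_type = 70, duration = 120, seed = 1)
ft  <- build_feature_table(compute_features(pop$neurons))
mod <- order_clusters(select_k(ft, seed = 2))
mod
#> Gaussian mixture: k = 4 (full covariance), n = 280 neurons
#> log-likelihood -1109.6, BIC 6946.8
#> cluster
#>  1  2  3  4
#> 70 70 70 70
```

The mixture selects four clusters and recovers the planted 70/70/70/70
split. Per-type statistics land on the published phenotype values
(Type-1: 2.07 Hz, CV 1.53, burst index 0.22; … Type-4: 19.57 Hz, 0.95,
0.24):

```r
summarize_types(compute_features(pop$neurons), tidy(mod))$scalars
#>    type     n rate_mean rate_sd cv_mean  cv_sd burst_index_mean burst_index_sd
#> 1     1    70      2.16   0.703   1.53  0.243           0.210          0.0655
#> 2     2    70      3.40   0.784   0.720 0.0838          0.00472        0.00650
#> 3     3    70     10.7    1.46    0.719 0.164           0.0289         0.0130
#> 4     4    70     19.8    3.02    0.953 0.173           0.246          0.0476
```

A foot-shock session with a planted stimulus gain of 3 yields an index near
its analytic value (3−1)/(3+1) = 0.5, and a state session with active-state
gain 2 converges to (2−1)/(2+1) = 1/3:

```r
fs <- simulate_shock_session(5, "excited", gain = 3, n_trials = 100, seed = 3)
shock_modulation(fs$neurons, fs$trials)
#>   neuron_id fr_baseline fr_stimulus  fsmi excluded n_trials auc_300
#> 1 fs1              5.39        14.8 0.465 FALSE         100    1.31

st <- simulate_state_session(10, active_gain = 2, session_length = 400, seed = 4)
state_modulation(st$neurons, st$motion)[, c("fr_active", "fr_quiet", "bsmi",
                                            "category", "p_value")]
#>   fr_active fr_quiet  bsmi category  p_value
#> 1      19.6     9.97 0.326 increase 7.21e-17
```

`fsmi = 0.465` is the planted 0.5 up to trial-sampling error, the positive
`auc_300` reflects the sustained short+long-latency excitatory response,
and the state neuron is correctly classified as a significant increase with
`bsmi ≈ 1/3`. For real data, `read_spike_dataset()` ingests a plain-CSV
layout (one row per spike plus a metadata table, optional trial and
motion-energy tables), and the same functions apply unchanged;
`match_clusters()` compares the cluster models of two conditions fitted in
a pooled feature space (see `subset_features()`).

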