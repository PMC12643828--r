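---
title: "Classifying lateral habenula firing patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lateral habenula firing patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habclust)
```

## The problem

Neurons of the lateral habenula (LHb), an epithalamic hub for aversive
signals, fire in vivo in markedly different spontaneous patterns: slow
irregular bursting, slow regular tonic firing, faster tonic firing, and
sustained high-rate bursting. `habclust` implements an unsupervised pipeline
that classifies single-neuron spike trains into such firing phenotypes and
then asks whether phenotype membership predicts functional modulation — by an
aversive stimulus (electrical foot shock) and by spontaneous behavioral
state (indexed by facial motion energy).

The pipeline has four stages:

1. **Feature extraction** — per neuron: mean firing rate, the coefficient of
   variation (CV) of the interspike intervals (ISIs), the burst index, the
   ISI distribution over 0–0.5 s, and the spike autocorrelogram (ACG) over
   ±0.1 s.
2. **Embedding** — sparse PCA compresses each histogram bank to eight
   temporal components; together with the three scalars this gives a
   19-dimensional feature vector per neuron.
3. **Clustering** — Gaussian mixture models fitted across candidate cluster
   counts; the number of clusters is chosen by the Bayesian information
   criterion (BIC) averaged over 100 random restarts, together with the
   saturation point of its gradient.
4. **Cross-condition matching** — clusters found independently in two
   datasets (e.g. anesthetized and awake recordings) are matched by the
   cosine similarity of their centroids under an optimal (Hungarian)
   assignment, with matches below a similarity of 0.6 discarded.

Because every stage is statistical, the package also ships a *calibrated
synthetic generator*: it produces spike-train populations with planted
phenotype labels, foot-shock sessions with planted response gains, and
behavioral-state sessions with planted rate coupling, so that each stage can
be validated against a known ground truth without any external data.

## Spike-train features

For a train with spikes $t_1 < \dots < t_n$ over duration $T$ and ISIs
$x_i = t_{i+1} - t_i$:

* rate $= n / T$;
* CV $= \sigma(x) / \bar x$, using the population (n-denominator) standard
  deviation — the difference from the sample SD is negligible at the
  hundreds of ISIs typical of these recordings, and the population form
  makes small hand-checked examples exact;
* burst index $=$ fraction of ISIs strictly shorter than 25 ms;
* ISI histogram over $[0, 0.5]$ s, normalized by the **total** ISI count, so
  that slow neurons keep visibly less in-range mass (the histogram then
  retains rate information rather than being a pure shape);
* ACG: the histogram of all ordered spike-pair lags within ±0.1 s, zero-lag
  self-pairs excluded, divided by the spike count. Any per-neuron uniform
  scaling convention would do here, because the bins are z-scored across
  neurons before the sparse PCA; per-spike normalization is used because it
  makes the ACG comparable across recording lengths.

Bin widths are 5 ms for the ISI histogram (100 bins) and 2 ms for the ACG
(100 bins, 50 per side). These resolve the sub-25 ms burst structure while
keeping each bank at about a hundred dimensions; both are parameters of
every relevant function. Neurons with fewer than 10 spikes are reported but
excluded from clustering (rate is still defined; CV and burst index need at
least two ISIs).

## The synthetic generator

### Base process and calibration

Each neuron is a **refractory gamma renewal process with burst insertion**.
Base events follow a gamma renewal process offset by an absolute refractory
interval of 26 ms; each base event starts, with probability $p$, a burst of
extra spikes whose count is geometric (mean `burst_len`) and whose
intra-burst ISIs are uniform on a range strictly below 25 ms. After the last
spike of a burst the renewal clock restarts.

This mechanism was chosen because it gives *independent, closed-form control*
of the three calibrated targets. Writing $f$ for the expected fraction of
ISIs that are intra-burst, $\mu_s$ for the mean intra-burst ISI and $\mu_g$
for the mean base gap:

* rate $= (1 + f/(1-f)) / (\mu_g + \frac{f}{1-f}\mu_s)$, solved for $\mu_g$;
* burst index $= f$ plus the (usually zero) fraction of base gaps below
  25 ms — the refractory offset keeps base gaps above the criterion, and a
  short fixed-point iteration absorbs the residual contribution at very
  high rates;
* CV: the ISI population is a two-component mixture (uniform intra-burst
  ISIs, shifted-gamma gaps), so matching the target second moment yields the
  gamma shape directly.

The calibration is open-loop; across all eight published (condition × type)
presets the measured population means of rate, CV and burst index land
within roughly ±10% of their targets at 120 s per neuron, comfortably inside
the ±30% tolerance the validation suite enforces.

### Phenotype presets

`lhb_type_presets()` carries the published per-type means (rate, CV, burst
index) for the anesthetized and awake datasets. Two derived values deserve
note: the Type-2 CVs are not printed directly for both conditions and are
reconstructed from the published Tukey mean differences against Type-1
(anesthetized $1.53 - 0.82 = 0.71$; awake $1.57 - 0.44 = 1.13$).

Each preset also fixes a *temporal burst signature*: Type-1 uses longer
bursts of very short (3–10 ms) intra-burst ISIs, producing the early, sharp
ISI/ACG peak described for that phenotype; Type-4 uses longer intra-burst
intervals (8–20 ms anesthetized, 9–15 ms awake), which is also what makes
the awake Type-4 corner (burst index 0.69 *and* CV 0.69 at 46 Hz) reachable
— with the default 3–15 ms range the ISI mixture cannot be made that
regular at that burst fraction.

### Between-neuron dispersion

The published per-type SDs describe the spread of neurons *within clusters
that a mixture model had already carved out of feature space*: they are
statistics of disjoint decision regions, inflated further by
feature-estimation noise. Treating them as SDs of independent per-parameter
generative clouds produces far more overlap than the real clusters had: with
full published SDs the *Bayes-optimal* classifier on the true generating
parameters — an oracle no unsupervised method can beat — recovers the
planted labels only at an adjusted Rand index (ARI) of about 0.85, so a
ground truth defined that way cannot validate a clustering pipeline.

The generator therefore draws per-neuron targets from truncated normals
centred on the published means with SDs scaled by `dispersion_scale`
(default 0.3), and accepts a draw only if its own type is the
maximum-likelihood generator among all presets ("classification-consistent
sampling" — the synthetic analogue of the hard assignment that produced the
published per-cluster statistics). At the default the planted partition is
essentially identifiable (oracle ARI ≈ 1), so recovery failures indicate
pipeline defects rather than intrinsic ambiguity; population means remain on
the published targets. Users who want overlap at the published scale can set
`dispersion_scale = 1`, with the understanding that no method can then reach
high ARI. Consequently, passing recovery tests on the default preset shows
that the pipeline works on well-separated phenotypes; it does not show that
the real data's clusters are that crisp — whether real LHb phenotypes are
discrete or a continuum is not a question synthetic data can answer.

### Stimulus and state sessions

Foot-shock sessions draw spikes from an inhomogeneous Poisson process with
intensity $r_0 (1 + (g-1)\,s(t - t_{\text{onset}}))$, where the response
kernel $s$ is a mixture of two alpha functions peaking at 40 ms and 210 ms
(the short- and long-latency excitatory components) normalized to unit mean
over the 0.5 s stimulus window. The expected stimulus-window rate is then
exactly $g r_0$, so the foot-shock modulation index (below) converges to
$(g-1)/(g+1)$; inhibited neurons instead multiply the intensity by a factor
below one during the stimulus. The trial protocol follows the published
one: 0.5 s stimuli every 5 s, 69 trials by default.

State sessions generate a motion-energy-like trace as rectified (absolute
value), smoothed Ornstein–Uhlenbeck noise with a 2 s correlation time,
sampled at 20 Hz. Spike intensity is $r_0 g$ at samples where the smoothed
trace exceeds its session 80th percentile and $r_0$ elsewhere — deliberately
the *same* rule the analysis applies, so the behavioral-state index
converges to $(g-1)/(g+1)$ by construction.

## Embedding and clustering

### Variance stabilization

Histogram mass for a neuron with $N$ ISIs has multinomial sampling noise of
order $\sqrt{p/N}$: at a fixed recording length, slow neurons are noisier
per bin than fast ones by an order of magnitude. Left uncorrected, this
heteroscedasticity gives every cluster a "clean core plus diffuse halo"
structure in the component scores, which a full-covariance mixture is happy
to split — restarts then converge to high-likelihood solutions that cut
types apart. The banks are therefore square-root transformed before per-bin
z-scoring (the standard variance-stabilizing transform for count data),
which makes bin noise approximately uniform across neurons. This is a
deliberate numerical choice of this implementation (`stabilize = FALSE`
restores raw banks).

### Sparse PCA

Each z-scored bank is reduced to 8 components with sparse loadings (25
non-zero bins out of ~100 per component, i.e. ~75% zeros). The sparsity
level is deliberately stronger than "half zero": the leading structure of
both banks lives in contiguous early-lag bins, and concentrating the
loadings there both aids interpretation and suppresses the diffuse
far-lag noise bins. With the sparsity disabled (`keep = Inf`) the routine
reproduces ordinary PCA to machine precision, which is how it is
cross-checked in the tests. The component subspace of the published analysis
is not expected to be reproduced exactly, since the exact sparse-PCA penalty
used there is not documented.

For cross-condition matching the sparse PCA and the feature standardization
are fitted on the **pooled** data and the table is then subset per
condition (`subset_features()`), so both datasets live in one feature space
and centroid cosines are meaningful.

### Mixture fitting

The 19 features are z-scored and fitted with full-covariance Gaussian
mixtures by EM. Each of the 100 restarts starts from a fresh k-means
partition (the standard initialization of widely used GMM implementations);
a ridge of $10^{-6}$ on the covariance diagonal keeps components invertible.
Diagonal covariance is available as a variant; on the synthetic presets it
changes little, consistent with the modest feature correlations reported
for the real data.

The number of parameters entering the BIC, $M = (k-1) + kd + k\,d(d+1)/2$
for full covariance in $d = 19$ dimensions, is substantial: about 210 per
additional component against a penalty factor $\ln N \approx 5.6$ at
$N = 280$. One consequence, verified in the test suite, is that BIC with
full covariance correctly *refuses* to split two blobs separated along a
single direction at this sample size — the likelihood gain of such a split
(about $\tfrac{N}{2}\ln(1 + \Delta^2/4)$) cannot pay for 210 parameters.
Phenotype structure is selected because the types differ jointly in means
and covariance scales across many coordinates. The demonstration of
two-blob recovery in the tests therefore uses the diagonal variant.

### Choosing the number of clusters

For every candidate $k$ the per-restart BIC values are averaged. The
selected $k$ is the smallest candidate whose mean BIC is the grid minimum
*or* whose forward gradient has saturated:
$|\overline{\mathrm{BIC}}(k) - \overline{\mathrm{BIC}}(k+1)| <
0.1\,|\overline{\mathrm{BIC}}(1) - \overline{\mathrm{BIC}}(2)|$.
The 10% threshold operationalizes "smallest mean BIC and the saturation
point of its gradient" deterministically and is a configuration parameter.
The default grid is $k = 1,\dots,6$: on both synthetic and published
curves the mean BIC reaches its minimum and flattens by $k = 4$–5, and the
grid must in any case stay below $n/10$. Final labels come from the
best-BIC restart at the selected $k$; clusters are then relabeled by
ascending mean firing rate (ties by ascending burst index), matching the
Type-1…4 convention.

t-SNE is provided for visualization only (fixed seed, never used in any
statistic).

## Cross-condition matching

Centroids are compared in the shared standardized feature space by cosine
similarity; the Hungarian algorithm minimizes $\sum (1 - S_C)$ over
one-to-one assignments. Costs are clamped at zero (cosines can exceed 1 by
machine epsilon), and unequal cluster counts are handled by padding with
dummy clusters at cost 1, whose pairs are dropped. The acceptance threshold
of 0.6 is **inclusive** — a match at exactly 0.60 is kept, as in the
published analysis. An exhaustive permutation oracle (`brute_force_match`)
verifies the assignment cost on thousands of random instances in the tests.

## Modulation analyses

### Foot shock

The PSTH spans −0.2 to +1.3 s around onset in 20 ms bins (75 bins), rate =
pooled counts / (trials × bin width). The foot-shock modulation index is

$$\mathrm{FSMI} = \frac{FR_{\text{stim}} - FR_{\text{base}}}
                        {FR_{\text{stim}} + FR_{\text{base}}}$$

with $FR_{\text{base}}$ from the 1 s before onset and $FR_{\text{stim}}$
from the 0.5 s stimulus window, both pooled across trials (pooling and
averaging coincide for equal-length windows). Neurons with spontaneous rate
below 1 Hz are excluded — they may fire less than one spike per stimulus.
Two baselines coexist deliberately: the FSMI baseline is 1 s, while the
z-scored PSTH uses the 10 pre-stimulus bins of its own window ([−0.2, 0) s)
as baseline, switchable to the 1 s window. The sustained-response measure is
the area under the z-scored PSTH over the first 300 ms (15 bins × bin
width). Trials truncated by the recording edges are dropped, not padded.

### Behavioral state

Motion energy is smoothed with a 0.5 s moving average and thresholded at
its session-wise 80th/20th percentiles; runs of same-state samples become
epochs, and epochs shorter than 0.5 s are dropped (avoiding single-sample
flicker). Percentiles are rank-based, hence invariant to monotone rescaling
of the trace — but only before smoothing, which is why the invariance
property is stated for the thresholding step. The behavioral-state
modulation index is the same ratio form with active/quiet rates from total
spikes over total time per state; per-epoch rates are kept as the sampling
unit for inference.

The per-neuron significance test is the **two-sample (unpaired) rank-sum
test** on per-epoch rates at $\alpha = 0.05$ — the source description
("unpaired Wilcoxon signed-rank") is self-contradictory, since the
signed-rank test is paired; "unpaired" and the active-versus-quiet design
point to the rank-sum form, and epochs of the two states are not naturally
paired. The *population-level* test across neurons, by contrast, is the
paired signed-rank test on (active, quiet) rate pairs per neuron, which is
what the corresponding published figure states. Neurons need at least 10 s
of data and 3 epochs per state; otherwise they are flagged and classified
"no change". With epochs as the unit, the test's empirical type-I error on
null synthetic sessions sits near 0.03–0.07; a fixed-width binning variant
of the unit of testing was considered and left out, as the epoch unit is
both simpler and calibrated.

## Validation problem sizes

The shipped validation suite exercises the pipeline at the study scale it
is meant for: populations of 280 neurons (70 per type) recorded for 120 s,
20 independent populations for the recovery checks; 100-trial foot-shock
sessions; 300–400 s state sessions, 1000 of them for the type-I calibration.
At these sizes the whole suite runs in minutes on a single core. Selection
of $k$ uses the full 100 restarts; the fixed-$k$ fits used in the matching
check use 50.

## Known limitations

* The generator reproduces the *marginal statistics and temporal signatures*
  of the published phenotypes, not their mechanisms: no anesthetic
  pharmacology, no non-stationarity or drift within a recording, no
  correlation between a neuron's spontaneous phenotype and its planted
  stimulus/state response (those are set independently by the caller).
* Real ISI/ACG sparse components need not match the synthetic ones bin for
  bin; only their role in the pipeline is validated.
* The state analysis is correlational by design; nothing here supports
  directional claims about motion driving LHb firing or vice versa.
* Exact reproduction of published per-neuron counts from the deposited
  recordings would additionally require matching undocumented choices
  (sparse-PCA penalty, feature scaling, epoching unit); the reader for such
  data is a thin CSV layer (`read_spike_dataset`) that a mapping script can
  target.
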