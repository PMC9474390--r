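---
title: "Methods: spike-train and electrical-footprint analysis for HD-MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train and electrical-footprint analysis for HD-MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`orgephys` implements the analysis chain used to characterize spontaneous
activity of developing neuronal tissue — human cerebral organoid slices in
particular — recorded on planar high-density microelectrode arrays
(HD-MEAs, 26,400 electrodes at 17.5 µm pitch, 10–20 kHz sampling). The
input is spike-sorted: a spike table (unit, time), per-unit electrical
footprints (EFs; the spike-triggered average extracellular waveform across
electrodes), and optionally raw traces and low-frequency local field
potentials (LFPs). This vignette documents the models behind each stage,
the tunable parameters and their defaults, the synthetic ground-truth
generator the test suite runs against, and known limitations.

## Synthetic ground truth

Every estimator in the package is exercised end-to-end against a generator
whose parameters are the cohort-level statistics such recordings exhibit:

| parameter        | default | meaning                                     |
|------------------|---------|---------------------------------------------|
| `unit_rate`      | 0.38 Hz | background firing rate per unit             |
| `burst_rate`     | 0.01 Hz | Poisson rate of network-burst initiation    |
| `burst_duration` | 4.05 s  | burst length                                |
| `burst_osc_freq` | 14.33 Hz| oscillatory modulation inside bursts        |
| `burst_gain`     | 20      | peak rate multiplier inside a burst         |
| `burst_ramp`     | 0.5 s   | raised-cosine onset/offset ramp             |
| `osc_depth`      | 0.5     | relative depth of the sinusoidal modulation |
| `true_velocity`  | 0.41 m/s| axonal conduction velocity                  |

Background spiking is homogeneous Poisson per unit; bursts multiply each
unit's rate by `burst_gain` under a raised-cosine envelope with sinusoidal
modulation, realized by Poisson thinning. Synaptic edges copy source
spikes to targets at a fixed delay (≥ 1 ms, so injected connections are
never removed by the sub-millisecond cross-correlogram exclusion) with a
transmission probability. All draws descend from one root seed through
named substreams (one per unit, per edge, plus one for burst initiation),
so enlarging a simulated population never perturbs existing units.

The generator is deliberately phenomenological. No claim is made about
burst initiation mechanisms (pacemaker neurons versus recurrent
excitation); bursts simply arrive as a Poisson process, because the data
these methods target constrain only the emergent rate, duration and
oscillation frequency. The generator also omits several features of real
recordings — electrode noise correlations, unit amplitude drift within a
session, non-Poisson interval statistics (e.g. burstiness of single
units), overlapping-spike sorting errors — so green tests demonstrate
correct recovery of the generative statistics under the stated model, not
robustness to every artifact of real data.

EF generation places a stereotyped biphasic spike template (negative
trough, then a positive rebound, ~1.5 ms; a smaller tri-phasic variant
models axonal signals) on each electrode of an axonal path. The trough on
electrode *k* lags the path origin by cumdist(*k*)/velocity, optionally
with Gaussian latency jitter, and the amplitude decays as
exp(−cumdist/`decay_const`). Burst-period LFP segments are 1/f^x noise
(default exponent 2, typical for extracellular field potentials) plus a
sinusoid at the burst oscillation frequency.

## Unit quality control and footprints

Two post-sorting filters are implemented. The refractory filter removes
units whose fraction of inter-spike intervals in the 0–1 ms bin exceeds
5% of spikes — contamination above chance for any biophysically plausible
refractory period. Duplicate removal handles the case of one neuron split
across two sorted units: for unit pairs whose EF peak channels lie within
100 µm, spikes of the lower-amplitude unit within 0.5 ms of a
higher-amplitude unit's spike are dropped (ties by lower unit id). The
kept unit's original train defines coincidences, making the operation
idempotent. Both filters only remove rows; spike times are never altered.

Electrical footprints are plain spike-triggered averages over a window of
2 ms before to 3 ms after each spike (the window is a package choice wide
enough to contain the 3 ms clustering snippet with margin), requiring at
least 30 fully contained spikes per unit. The peak channel is the
electrode with the largest absolute trough amplitude.

## Network bursts

Multi-unit activity (MUA) is binned at 0.1 s, smoothed with a Gaussian
kernel, and normalized to its maximum (any affine normalization gives the
same detections, since the threshold is mean + 2 SD of the normalized
vector itself). Detections are extended to the nearest crossings of the
mean level, which define onset and offset; crossing times are linearly
interpolated between bin centers.

Two numerical choices deserve explanation:

* **Smoothing SD = 0.1 s (one bin).** The offset threshold (the mean of
  the normalized MUA) sits far below the burst plateau, so a smoothed
  burst edge crosses it roughly σ·Φ⁻¹(1 − mean/max) *outside* the true
  edge. At σ = 0.3 s this inflates measured durations by ≈ 0.4 s per
  side (≈ 20% for 4 s bursts); at one bin the bias is within the bin
  width while bin-count noise is still suppressed.
* **Minimum 0.5 s above threshold.** Under the 2 SD rule, ≈ 2% of bins
  of a stationary recording exceed the threshold by chance, but such
  excursions retreat within a bin or two, whereas genuine bursts stay
  above threshold for seconds. Requiring 0.5 s above the *detection*
  threshold (not the onset–offset span, which is wide for any crossing)
  reduces false alarms on burst-free recordings to essentially zero.

Bursts separated by less than one bin are merged. The burst rate is
events per second over the recording.

## Burst-LFP spectral parametrization

Power spectral densities are estimated during burst periods only, with
Welch's method (1 s Hann segments, 50% overlap) on the 1 kHz LFP,
averaged per group of spatially adjacent electrodes; windows shorter than
one segment are skipped. The spectrum is then decomposed, in log10 power
over log10 frequency on 2–100 Hz, into an aperiodic component
(offset − exponent·log10 f) plus up to 6 Gaussian peaks, extracted
tallest-first from the aperiodic-flattened residual and jointly refit;
peaks are retained when their fitted height is at least 0.3 log10-power
units (the conventional unit for the "minimum peak power" of spectral
parametrization) and their Gaussian width lies in 1–12 Hz. If the joint
fit fails the aperiodic-only model is returned with a warning. Per-burst,
per-group peak frequencies are pooled and the recording's "most likely
peak" is the mode of their kernel density. Individual per-burst spectra
are noisy (a 4 s window yields 7 Welch segments) and can contribute
spurious peaks; the pooled mode is robust to them, which mirrors why
pooling is done at all.

## Axonal conduction velocity

Per unit, the latency map holds each electrode's trough time relative to
the peak channel and its trough amplitude. Electrodes are excluded when
their amplitude does not exceed the noise floor (default: 5× the median
absolute deviation of the channel's pre-trough baseline) or when their
latency is negative — the signal preceded the peak channel, so it cannot
lie on the outgoing axonal path. EFs below 20 kHz are up-sampled.

Trough times use parabolic three-point interpolation by default. At
17.5 µm pitch and ~0.4 m/s the per-electrode latency step is ~43 µs,
*below* the 50 µs sampling period at 20 kHz; at sample resolution the
latency axis is quantization-dominated and the regression cannot resolve
the velocity, while the interpolated trough of a smooth extracellular
waveform is accurate to a few microseconds. Sample-resolution latencies
remain available (`interp = "none"`).

The flow graph has a directed edge i → j when latency(i) < latency(j)
and the electrodes are ≤ 60 µm apart; strict ordering makes it acyclic.
"Clusters" of this graph are its weakly connected components — the
natural segmentation of a sparse latency DAG into putative axonal
segments, left as an explicit package choice since several graph
clusterings could serve. Within each component the path runs from the
origin (the peak channel where present, otherwise the earliest-latency
electrode) to the electrode most distant from the origin, along the
shortest path by cumulative edge length; a 10⁻⁶ µm per-edge bonus breaks
exact length ties in favour of the denser route, so a straight chain is
traced electrode by electrode. Points (cumulative distance, latency) are
pooled over segments — each segment re-referenced to its own origin so a
single intercept is meaningful — and ordinary least squares of distance
(m) on latency (s) gives the velocity as the slope. Estimates with
r² ≤ 0.8 (or non-positive slope) are flagged and excluded from cohort
statistics. On 100 simulated EFs at 0.41 m/s with 20 µs latency jitter
the estimator's mean recovered velocity is within a few percent of truth
(the residual downward bias is classical regression attenuation from
jitter in the latency regressor) and ≥ 95 units pass the r² filter.

## Waveform clustering

Peak-channel waveforms at 20 kHz are high-pass filtered (2nd-order
Butterworth, 150 Hz, zero-phase), aligned on the filtered trough, cut to
61 points (1 ms before to 2 ms after the trough) and normalized so the
trough equals −1. The 61-point length is taken as authoritative (it is
3.05 ms at 20 kHz, not exactly 3 ms). "AP peak" is interpreted as the
trough — the dominant negative deflection — consistent with trough
normalization.

Clustering operates on a fuzzy k-nearest-neighbour graph (k = 15):
neighbour distances are converted to membership strengths
exp(−(d − ρ)/σ) with ρ the nearest-neighbour distance and σ calibrated
per point so total membership equals log₂k, then symmetrized by the
fuzzy union a + b − ab. This is the high-dimensional graph a nonlinear
embedding would construct; the 2-D embedding itself is deliberately not
produced, since the communities are found on the graph, not on embedded
coordinates. Louvain community detection with a resolution parameter
(headline setting 1.5) labels the units; the reported Q is the standard
modularity of that partition on the same weighted graph, recomputable
from the usual formula. The resolution sweep repeats clustering (default
20 iterations per resolution, seeds = root + iteration) and reports mean
Q and mean cluster count.

## Functional connectivity

**Cross-correlograms.** Counts of target spikes around source spikes in
1 ms bins over ±50 ms. The slow baseline is the CCG convolved with a
Gaussian kernel (SD 10 ms, truncated at 3 SD, renormalized at the
edges); the kernel includes the peak bin — a plain convolution, since
partially hollow variants are a refinement this implementation does not
claim. The tallest bin within ±5 ms is tested against the baseline rate
at that bin by the exact Poisson upper tail P(X ≥ peak | λ), compared to
α = 0.001 with no correction across the window's bins (a single α, as is
conventional for this test). CCGs whose in-window maximum falls in a
sub-millisecond bin are excluded outright: such latencies are faster
than synaptic transmission and typically betray duplicate or split
units. Connection direction follows the sign of the peak lag.

**Transfer entropy.** Spike trains are binned and binarized; the plug-in
estimator uses a target history of 1 bin and a source history of 4 bins
at a delay of 1 bin, so the source window at bin size b spans b to 4b ms
(35–140 ms at b = 35). The time-scale ladder {1, 1.6, 3.5, 7.4, 16, 35,
74, 160} ms is log-spaced to satisfy the anchors of range 1–160 ms with
scale 2 at 1.6 ms and scale 6 at 35 ms. Significance uses 50 surrogates
in which each source spike is jittered by an integer offset uniform on a
7-bin window; offsets that would collide in one occupied bin (or leave
the recording) are redrawn so surrogates keep the empirical train's bin
occupancy — without this, every surrogate TE is biased slightly low and
false positives inflate. The empirical TE is z-scored against the
surrogate mean and SD and called significant when z exceeds the Gaussian
quantile at α = 0.001. Per scale, the package reports connection density
(significant fraction of ordered pairs) and the modularity Q of a
Louvain partition of the symmetrized significant-edge graph.

For efficiency, the surrogate loop uses a sparse kernel: the target-side
pattern code is computed once per pair, and only bins within the source
window of a spike are touched per surrogate. The kernel is exactly equal
to the dense estimator (asserted in the tests).

## Multi-day tracking

With a fixed electrode configuration, units are tracked across sessions
by template matching: cosine similarity between flattened EFs on shared
channels, optimal one-to-one assignment per consecutive day pair
(Hungarian algorithm, written in-package and verified against exhaustive
enumeration), and acceptance above a similarity threshold (default
0.85). Chains of consecutive matches define units tracked across spans,
so tracked counts are non-increasing with span. Cosine similarity is
gain-invariant, so uniform amplitude drift between days does not impair
matching. This is a template-matching surrogate for tracking by
concatenated re-sorting, which requires the raw data and a sorter; with
no accepted threshold for when a concatenated-sort unit counts as
"tracked", comparisons to published multi-day counts are qualitative.

## Problem sizes used by the test suite

The suite validates recovery at desk scale: velocity on 100 simulated
EFs on a 60×60 grid; bursts on a 50-unit, 2 h simulated recording;
spectra on ~40 burst windows of LFP at 1 kHz; firing rates on 50 units
for 1 h; false-positive control on all ordered pairs of 50 independent
Poisson units over 1 h (CCG at 1 ms, TE at the 35 ms scale). These sizes
give Monte-Carlo error comfortably below the tolerances being asserted
while keeping the full suite in a few minutes.

## Known limitations

* The surrogate z-test for TE is not exactly calibrated: under
  independence, 2N·ln2·TE is approximately χ² with
  (2^l_source − 1)·2^k_target ≈ 30 degrees of freedom, and the right
  skew of that null makes P(z > 3.09) ≈ 4–5·10⁻³ rather than 10⁻³ even
  with exact surrogate moments; estimating the moments from 50
  surrogates adds further t-type tail inflation. The measured
  false-positive rate on independent networks is accordingly a few
  times nominal α (the suite quantifies it), while the CCG test, built
  on an exact Poisson tail, stays within 2α. Users comparing edge
  counts across conditions should rely on within-study contrasts rather
  than the nominal α.
* Velocity estimates inherit classical attenuation bias when latency
  jitter is comparable to the latency span; short paths (few electrodes)
  are affected most. The r² filter removes the worst cases but does not
  de-bias the rest.
* The waveform-clustering stage consumes the neighbour graph directly;
  no low-dimensional embedding is produced for visualization.
* Spike sorting itself, drift correction, stimulation-triggered
  velocity estimation, multivariate/conditional TE, and synaptic sign
  classification are out of scope.
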