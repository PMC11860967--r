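---
title: "Methods: MEA spike-train features, burst detection and synchrony"
author: "meapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA spike-train features, burst detection and synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meapipe)
```

# Scope and model

`meapipe` analyzes multi-well MEA recordings of cultured neural networks:
each well holds a grid of extracellular electrodes, each electrode yields a
spike train (action-potential timestamps) over a 30-minute window, and the
scientific questions are asked at the *well* level — how do spiking,
bursting and synchrony change after a treatment, relative to each well's
own baseline and to untreated control wells of the same age?

The pipeline is deterministic end to end given its seeds; every stage is a
pure function of spike times and parameters.

# Spike detection

Raw traces are sampled at 10 kHz and bandpass filtered 4–4,000 Hz with a
second-order Butterworth filter applied forward and backward
(`signal::filtfilt`), so filtering adds no systematic latency to spike
times. A spike is a negative-going crossing of
$-k\hat\sigma$ with $k = 6.5$ by default, where $\hat\sigma$ is the
baseline noise SD. Choices worth noting:

- **Noise SD** is estimated once per recording per electrode as the
  median absolute deviation scaled to the Gaussian SD (constant 1.4826).
  The MAD is nearly unbiased under pure noise and moves by only a few
  percent under sparse large spikes, which a plain SD does not survive.
- **Polarity** is negative-only (extracellular somatic spikes are
  dominated by a negative trough); the threshold comparison is inclusive,
  so an event whose peak sits exactly at $-k\hat\sigma$ counts.
- **Timestamp** is the most negative sample within the crossing epoch —
  stable under noise jitter, unlike the first-crossing sample.
- **Refractory merge window** of 1 ms: crossings closer than this are one
  event. This is the typical width of an extracellular spike; the value
  is a parameter (`detectorParams(refractory = )`).

# Max-interval burst detection

The detector is the classic max-interval method with five parameters
(defaults in parentheses): a burst *starts* at the first spike of a pair
with ISI ≤ `maxBeginIsi` (0.1 s) and *extends* while ISIs stay ≤
`maxEndIsi` (0.2 s); bursts separated by a gap < `minIbi` (0.5 s) are
*merged*, interior spikes included; merged bursts are kept only if they
last ≥ `minDuration` (0.05 s) and contain ≥ `minSpikes` (6).

Conventions that the parameter names alone do not pin down, fixed here and
enforced by tests:

- "maximum"/"minimum" thresholds are inclusive; merging is strict
  (`gap < minIbi`), so two clusters exactly 0.5 s apart remain two bursts.
- Merging runs *before* the duration/spike-count filter, so two
  sub-threshold fragments separated by a short gap survive as one burst
  rather than both being discarded.
- Burst duration is last spike time minus first spike time, unpadded.
- All interval comparisons carry an absolute tolerance of $10^{-9}$ s.
  Spike times are float64 values typically assembled by ms-grid
  arithmetic; the tolerance (far below any physical timing resolution,
  far above accumulated rounding) makes boundary inputs classify by their
  intended value. The same tolerance backs the electrode filters.

The implementation is verified against an exhaustive oracle that
enumerates all index windows satisfying the rules (O(n²)) on 1,000 random
trains, and its constants are recovered black-box by boundary sweeps.

# Features and electrode filters

Six features per electrode: spike count, firing rate (count/duration),
mean ISI, mean burst duration, bursts per minute, and total spikes in
bursts. Interval features without support (fewer than two spikes; no
bursts) are `NA`, never silent zeros.

Electrodes partition into **inactive** (< 10 spikes per recording),
**noisy** (mean burst duration strictly > 5 s; a degenerate detector
output on such electrodes usually reflects recording artifacts), and
**included**. Well values are means over included electrodes. Count-type
features include zeros from silent-but-included electrodes; interval
features average only where defined — the convention that reconciles
"inactive electrodes count as zero" with intervals that have no defined
value. An `includeInactive` switch additionally pools inactive electrodes
as zeros into the count features, for the alternative reading; the
default applies the inclusion rule. Whether the "ISI" feature is a mean
or a median is another genuinely open choice; the mean is used, and it
moves inversely with firing rate as expected.

# Synchrony

For two trains on a shared window the time-resolved SPIKE-distance is

$$S_n(t) = \frac{\Delta t_P^{(n)}\,x_F^{(n)}(t) + \Delta t_F^{(n)}\,x_P^{(n)}(t)}{x_{ISI}^{(n)}},
\qquad
S(t) = \frac{S_1(t)\,x_{ISI}^{(2)} + S_2(t)\,x_{ISI}^{(1)}}{2\,\langle x_{ISI}\rangle^2},
\qquad
D = \frac{1}{T}\int_0^T S(t)\,dt,$$

where for train $n$, $t_P/t_F$ are the preceding/following spikes of $t$,
$x_P = t - t_P$, $x_F = t_F - t$, $x_{ISI} = t_F - t_P$, and
$\Delta t_P/\Delta t_F$ are the distances from $t_P/t_F$ to the nearest
spike of the *other* train. $D$ is symmetric, bounded in $[0,1]$, zero
exactly for identical trains, and invariant to common time shifts and
rescalings.

Numerical choices:

- **Edge correction**: auxiliary spikes at the window edges (0 and $T$)
  are added to each train, which defines the profile for arbitrarily
  sparse trains, including empty ones.
- **Exact integration**: between corner points (the union of both
  augmented trains) every constituent of $S(t)$ is constant except
  $x_P, x_F$, which are linear — so $S$ is piecewise linear and the
  integral is a sum of trapezoids evaluated at segment-interior limits.
  There is no grid-resolution knob; the test suite instead uses a dense
  sampling grid ($\Delta t = 10^{-4}$ s) as the independent oracle and
  agrees to better than $10^{-3}$.

The reported synchrony is $1 - D$, so 1 is perfect synchrony. Because the
distance assigns higher chance similarity to denser trains, each pair's
similarity is divided by the mean similarity of $n = 20$ independent
Poisson surrogate pairs matched to the two trains' empirical rates, and
capped at 1. The normalization form (ratio to surrogate mean, cap at 1),
the surrogate count and the rate-matching scheme are this package's
choices — only *that* random-train normalization happens is given — so
all three live behind `SurrogateSpec`, and the uncapped ratio plus the
raw similarity are kept as attributes for audit. Pairs with an empty
train have no defined chance level and are excluded (`NA`). Well-level
summaries score all unordered pairs of included electrodes (the noisy
exclusion applies to synchrony as well as features) and report the mean
plus a fixed-bin histogram (width 0.05, matching the granularity at
which such score distributions are usually displayed).

# Fold-change analysis and statistics

For each well and feature, post-exposure values are divided by that
well's pre-exposure baseline (removing well-to-well offsets and
pipetting disturbances), then by the mean of the control wells'
baseline-normalized values at the same timepoint (the age-matched
comparison). When a plate has two first-hour recordings after dosing,
they are the 30- and 60-min timepoints and the single pre-dose recording
is the baseline. Control fold changes average to exactly 1 per
timepoint by construction (a tested invariant, tolerance $10^{-12}$);
wells with zero/undefined baselines and timepoints with undefined
control means are flagged and excluded, not imputed.

The statistics stage is deliberately a thin wrapper over standard
engines: `lmerTest::lmer(foldChange ~ label * timepoint + (1 | well))`
per feature, with `emmeans` treatment-vs-control contrasts per timepoint
under Dunnett-style adjustment, significance at 0.05. Singular designs
(one condition, one timepoint, fewer than two wells per arm) are
rejected explicitly.

# The synthetic plate generator

The generator stands in for recordings the package was built to analyze:
it emulates wells of 16–40 electrodes, 30-minute windows, background
Poisson firing overlaid with bursting episodes (Poisson onsets; spike
counts $1 + \mathrm{Poisson}(\mu - 1)$ so no burst is empty; fixed
within-burst ISI), and well-level multiplicative treatment effects that
switch on at a configurable timepoint. Default activity levels
(background 0.5 Hz, 10 bursts/min, 8 spikes/burst at 20 ms ISI) were
chosen once as plausible for mature cortical cultures on MEAs — real
baseline activity statistics for this preparation are not published in a
form that could be matched, so fidelity claims stop at "same structure,
realistic magnitudes".

Design decisions:

- The burst-duration effect scales the within-burst ISI while the
  spikes-per-burst effect scales the count mean, so the two effects act
  on distinct observables and are separately recoverable.
- The firing-rate effect scales the background rate only.
- Overlapping burst episodes are merged in the ground-truth annotations,
  since no ISI-based detector could ever report them separately; bursts
  truncated by the recording end are flagged.
- Per-electrode seeds are a deterministic 31-bit hash of
  (master seed, well, timepoint, electrode), so any subset of a plate
  regenerates identically with no seed bookkeeping, and identical specs
  give byte-identical HDF5 files.
- Raw traces are Gaussian noise plus a fixed 1-ms biphasic template
  (dominant negative trough about 0.5 ms wide, normalized so the deepest
  sample is exactly −1) at each timestamp; overlapping templates sum.

What passing the synthetic-data tests does *not* show: real recordings
have non-Poisson ISI structure, electrode-to-electrode heterogeneity,
slow drifts, correlated network-wide bursts and non-Gaussian noise. The
generator validates the *pipeline's* correctness and statistical
behavior, not biological realism.

# Validation experiments and problem sizes

The test suite runs, at sizes chosen to exercise the defaults while
keeping a full run in minutes:

- Boundary recovery of all decision constants (threshold multiple on a
  0.1 grid; burst limits on 1–10 ms grids; electrode filters by count
  sweeps) — each recovered exactly.
- Oracle equivalence: burst detector vs. exhaustive search (1,000 random
  trains ≤ 50 spikes); spike distance vs. dense-grid integration
  (50 random pairs, rates 0.5–8 Hz, 100-s windows).
- Parameter recovery: 0.5× effects on burst duration, firing rate and
  spikes-per-burst, each on five full plates (6 wells/arm, 16
  electrodes), recovered within ±0.15. Each effect is probed in a regime
  where its observable dominates: low background for burst features, a
  background-dominated rate for the firing-rate effect, and a
  spikes-per-burst mean of 20 so the 6-spike rule censors both arms
  negligibly — with 8 spikes/burst, censoring by the minimum-spike rule
  distorts a 0.5× count effect to ≈0.17, an identifiability limit of the
  detector, not a pipeline defect.
- Chance-level behavior of the normalization: across 0.5/2/8 Hz
  independent Poisson pairs (50 seeds per rate, 200-s windows), the
  uncapped score ratio sits at 1.000–1.003 at every rate — the surrogate
  normalization equalizes expected scores across firing rates. A
  companion test asserts the stronger property that the *capped* score's
  across-rate spread is smaller than the raw similarity's; see the
  limitations below for why that stronger form does not hold here.
- Statistics: 50 null plates keep significant control-referenced
  comparisons ≤ 10%; 20 effect plates detect a 50% burst-duration
  reduction at ≥ 2 post-onset timepoints in ≥ 90% of replicates
  (6 wells/arm, 8 electrodes, 4 timepoints).

# Known limitations

- The exact spike distance is invariant under common time rescaling, so
  for *equal-rate* independent Poisson pairs its expected value is
  rate-independent except at low spike counts, where edge effects raise
  the similarity of sparse pairs (about +0.03 at eight spikes per
  window). Consequently the density bias the surrogate normalization
  corrects is a sparse-train phenomenon; at moderate counts the raw
  across-rate spread is sampling noise, while the capped score carries a
  small systematic rate dependence of its own (the cap truncates the
  ratio's upside, and the truncation bias grows with the score's
  variance, hence with sparseness: mean capped scores 0.992/0.995/0.998
  at 0.5/2/8 Hz). The spread-comparison test above therefore fails as
  stated, and is retained unweakened as a record of this limitation; the
  uncapped ratio, emitted alongside every score, is free of the cap
  artifact.
- Spike sorting is out of scope: an electrode's train is treated as one
  unit stream.
- Network-wide (array-level) burst detection and directed connectivity
  are not implemented; synchrony is pairwise only.
- The noise SD is estimated once per recording, not tracked over time.
- Fold changes require positive baselines and control means; silent
  wells propagate as flagged missing values by design.
- Statistical results depend on the standard mixed-model machinery
  (Satterthwaite degrees of freedom, Dunnett-style adjustment);
  equivalence with any particular commercial implementation is not
  claimed.
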