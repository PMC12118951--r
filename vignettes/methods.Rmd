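---
title: "Models and methods behind sleeposc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sleeposc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sleeposc analyzes chronic multi-regional sleep electrophysiology: spike
trains of sorted single units from ventral hippocampus (vCA1), prelimbic
cortex layer 5 (PL5) and basolateral amygdala (BLA), multi-channel LFP, and
a hypnogram of NREM/REM/wake bouts. This vignette explains the models the
package implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices that matter when reproducing results.

## Sleep architecture

A raw hypnogram is normalized before any analysis
(`normalize_hypnogram()`):

* **Microarousals.** Wake bouts shorter than 40 s that sit inside NREM
  sleep, or at a REM-to-NREM transition, are relabeled NREM and merged with
  their neighbors. Wake at sleep onset or offset is never merged.
* **Short epochs.** Epochs lasting 50 s or less stay in the timeline but
  are flagged unusable and excluded from rate analyses.
* **Extended sleep** (`find_extended_sleep()`) is any maximal sleep period
  longer than 30 min with no wake bout over 60 s.
* **NREM--REM--NREM triplets** (`find_triplets()`) are consecutive epochs,
  each longer than 50 s. Whether "consecutive" tolerates an intervening
  excluded short epoch is genuinely ambiguous; the package tolerates them
  by default (`tolerate_excluded = FALSE` switches to strict adjacency),
  on the reasoning that an epoch excluded from analysis should not break a
  sequence it would not contribute to either way.

## REM-preference classification

Firing rates are computed in whole 1-s bins within usable epochs (bins
straddling an epoch boundary are truncated and dropped when shorter than
1 s, which keeps every bin exactly 1 s). With mean rates $FR_R$ (REM bins)
and $FR_N$ (NREM bins), the REM-preference index is

$$\mathrm{index} = \frac{FR_R - FR_N}{FR_R + FR_N} \in [-1, 1].$$

Significance comes from a permutation null: the REM/NREM labels are
shuffled across bins (preserving the number of each), the index is
recomputed for each of 1,000 surrogates, and the neuron is called
REM-preferring above the 97.5th percentile, NREM-preferring below the
2.5th, otherwise non-significant (NS). Stricter criteria (99.5/0.5,
99.9/0.1) are available through `alpha`. Percentiles use linear
interpolation and an index exactly at a threshold stays NS (conservative).
Labels are shuffled over all pooled bins; a per-session block shuffle could
be added, but pooled shuffling matches the pooled-epoch rate definition.
The permutation inner loop runs in compiled code (a partial Fisher--Yates
per surrogate), so a 2-h session with 1,000 surrogates classifies in about
15 ms per unit.

Two calibration properties are enforced by the test suite: on
state-independent Poisson units the combined REM+NREM false-positive rate
is close to the nominal 5%, and units with a true two-fold rate ratio at
0.5 Hz or more, observed for at least 30 min per state, are recovered with
over 95% sensitivity.

## Oscillation detectors

All four detectors operate on z-scored power, with the mean and SD taken
over NREM samples, which makes detection invariant to overall amplitude
scaling. The band-pass is a 4th-order Butterworth applied
forward-backward (zero phase); moving RMS is evaluated at every sample
with a centered window (a sliding window; block-wise evaluation is the
other reading of the stated window lengths, and sliding is the finer of
the two).

| kind | signal | band (Hz) | RMS window | enter | peak | min dur | merge |
|------|--------|-----------|------------|-------|------|---------|-------|
| ripple | per vCA1 channel | 100--250 | 13.3 ms | 1.5 z | 4 z | 30 ms | < 10 ms |
| HFO | per-shank median, BLA | 90--180 | 20 ms | 2 z | 4 z | 30 ms | < 20 ms |
| cRipple | per PL5 channel | 90--180 | 20 ms | 3 z | 5 z | 50 ms | < 30 ms |
| spindle | PL5 channel average | 9--18 (wavelet) | -- | 1.4 z | 2 z | > 350 ms | -- |

Candidates are filtered (peak and minimum duration) before nearby events
are merged, and the 750-ms maximum for ripple-class events is applied last,
after any cross-channel concatenation. Sharp-waves are detected on the
2--40 Hz filtered deep-minus-superficial vCA1 channel difference as runs
below $-2.5$ z lasting 20--400 ms; a ripple candidate becomes an SWR only
if it contains a sharp-wave trough from the same shank. SWRs are detected
in NREM and wake (never REM); HFOs, cRipples and spindles in NREM only.
A stringent variant raises the peak thresholds to 5/5/6/3 z; its output is
a subset of the default output by construction, which the tests verify.

Spindle power is the pointwise maximum over 11 log-spaced Morlet
($\omega_0 = 6$) wavelet scales whose center frequencies span 9--18 Hz,
each scale z-scored over NREM. The sustained-threshold rule (> 1.4 z for
more than 350 ms) is applied as a strict run with no sub-threshold dips.
Because the wavelet has finite temporal support, power runs extend some
tens of milliseconds beyond a burst's envelope; duration criteria therefore
apply to the power trace, not to the underlying burst.

Comparisons of sample-grid durations against millisecond thresholds use a
microsecond tolerance so that a run of exactly $n$ samples compares as its
exact duration rather than a float neighbor.

## Firing-rate modulation

`fr_gain()` is the rate inside events divided by the rate outside events,
both restricted to the reference state (NREM for sleep oscillations, wake
for awake SWRs); "outside" excludes only the kind under analysis, not
other kinds. Peri-event rates use 10-ms bins smoothed with a Gaussian of
$\sigma$ = 50 ms for ripple-class events and 50-ms bins with
$\sigma$ = 250 ms for spindles, on lag windows of ±0.5 s and ±2 s
respectively (wide enough to hold the smoothing kernels). Shock gain is
the peak of the 0.1-s-bin PSTH within the 2-s shock window divided by the
mean rate in the 20 s before the first conditioned stimulus; spikes from
0.1 ms before to 5 ms after each 2-ms shock pulse are censored first.

Z-scored epoch rates (sleep-long trends, within-event changes) are
normalized per unit using the mean and SD of its epoch means across all
NREM epochs of all extended-sleep periods in the dataset; the normalization
population is not uniquely determined by the definitions in common use, and
this choice uses the most data per unit.

## Coactivity

For a pair of neurons and $N$ events, with $n_A$ and $n_B$ events in which
each neuron fires at least once and $R$ events in which both do, the null
of independent activity makes $R$ hypergeometric, so

$$E = \frac{n_A n_B}{N}, \qquad
\sigma^2 = \frac{n_A n_B (N - n_A)(N - n_B)}{N^2 (N - 1)}, \qquad
Z = \frac{R - E}{\sigma}.$$

Pairs with $\sigma = 0$ ($n_A \in \{0, N\}$ or $n_B \in \{0, N\}$, or
$N = 1$) are excluded with a recorded reason. Activity is counted within
the event's own $[start, end)$ interval. Pair types are NN/RR for two
NREM-/REM-preferring members; cross-regional mixed pairs are ordered NR/RN
by the fixed region order vCA1, PL5, BLA; within-region mixed pairs have no
natural order and are reported as NR; pairs with an NS member are "other"
(they still enter the index-product correlations). The moment formulas are
tested against exhaustive enumeration of the hypergeometric pmf for
$N \le 12$ and against a large Monte-Carlo label shuffle.

## Cell typing

Cross-correlograms use 0.1-ms bins smoothed with a Gaussian of
$\sigma$ = 0.5 ms; positive lags mean the target fires after the reference,
and exact zero-lag self-pairs are excluded. The null band comes from 1,000
surrogates in which every spike of both trains is jittered independently
and uniformly in ±5 ms; the 99.5th percentile of surrogate maxima and 0.5th
percentile of minima over ±5 ms form 99% global bands. A candidate needs a
strict band exceedance inside +1 to +4 ms. Manual curation of suspicious
connections is approximated by an automatic, configurable rule: a candidate
is rejected when its exceedance run touches ±0.4 ms (zero-lag) or spans
more than 3 ms (broad). Units with only excitatory (only inhibitory)
significant outputs are typed by that evidence; everything else falls back
to spike width (> 0.6 ms excitatory, < 0.5 ms inhibitory, between:
unclassified and excluded downstream).

## Quality metrics

The ISI index is the count of inter-spike intervals in [0.5, 2) ms over the
count in [2, 10) ms, multiplied by 8/1.5 to normalize the window lengths.
The contamination rate is the minimum over refractory windows
$[0.5, n)$ ms, $n = 1.5, 2.5, \ldots, 9.5$, of the window-length-normalized
ratio of autocorrelogram counts against two baselines ([0.5, 49.5) and
[250, 500) ms). All count windows are half-open, so no lag is counted
twice. Isolation distance is the squared Mahalanobis distance (cluster
covariance) from the cluster center to the $n_c$-th nearest same-shank
noise spike; the feature space is caller-supplied. Waveforms are
spline-upsampled to 200 kHz; amplitude is trough depth below baseline
(baseline = mean of the first 20% of samples, which the source definition
leaves open) and width is trough-to-peak time; a waveform whose rebound
never rises more than 5% of the amplitude above baseline is flagged
monophasic and its width uses the global post-trough maximum. A unit is
included when isolation distance > 15, (ISI index < 0.2 OR contamination
< 0.05), mean rate > 0.01 Hz and amplitude > 50 µV.

## Statistics

Mann--Whitney, Wilcoxon signed-rank and Spearman tests delegate to the
base-R routines, with exact enumeration on small tie-free samples and
tie-corrected approximations otherwise; the suite checks them against
explicit exhaustive enumeration. The Steel--Dwass all-pairs post hoc is
implemented in the package (it is not in the standard libraries): each
group pair is jointly ranked, the rank-sum statistic is studentized with
the tie-corrected variance
$V = \frac{n_i n_j}{N(N-1)} \left(\sum r^2 - \frac{N(N+1)^2}{4}\right)$,
and $\sqrt{2}\,|z|$ is referred to the Studentized range distribution with
$k$ groups and infinite degrees of freedom. With two groups this reduces
exactly to the two-sided tie-corrected rank-sum z test. The post hoc runs
only when the Kruskal--Wallis omnibus p is below 0.05 (the gate is
configurable). All tests are two-sided.

## The synthetic-data generator

Real sessions of this kind are not publicly deposited, so the package
ships a generator (`synth_config()`, `generate_session()`) whose defaults
define the study conditions under which everything is tested:

* **Hypnogram**: a semi-Markov chain over wake/NREM/REM with log-normal
  dwell times (medians 25 s wake, 250 s NREM, 90 s REM; a longer initial
  wake). These were chosen once so that a 2-h session usually contains an
  extended-sleep period and several triplets, with frequent microarousals
  to exercise the merging rules.
* **Spike trains**: piecewise-constant-rate Poisson processes per state
  bout — log-normal NREM base rates (median 1.5 Hz), log-uniform REM/NREM
  ratios in [0.25, 4] — followed by a 2-ms absolute refractory period, as
  in well-isolated units; without it every simulated unit would fail the
  refractory-based quality criteria, and at these rates it removes well
  under 1% of spikes.
* **LFP**: Gaussian $1/f$ background (spectral exponent 1, synthesized in
  the frequency domain) per channel; vCA1 has exactly a
  superficial/deep pair so sharp-wave detection on the channel difference
  is exercised; PL5 and BLA one channel each. Events are Gaussian-windowed
  sinusoids: ripples 150 Hz, 50--100 ms, on both vCA1 channels, with a
  negative sharp-wave deflection on the deep channel; HFOs 120 Hz,
  40--80 ms; cRipples 120 Hz, 80--140 ms (long enough that their
  supra-threshold power runs satisfy the 50-ms criterion — the
  supra-threshold run of a Gaussian burst is about 0.64 of its nominal
  duration plus the RMS window); spindles 12 Hz, 0.5--1 s. Default
  amplitudes (4--5 background SD) put peak z-scores far above the
  confirmation thresholds. HFO/cRipple/spindle are injected only in NREM;
  ripples also in wake.
* **Modulation**: each unit carries a log-uniform gain in [0.5, 5] applied
  to its rate inside events of its home region's kinds (by exact Poisson
  superposition or thinning), a shock gain in [1, 6], and the shock
  schedule writes the 8-Hz pulse trains needed for censoring. The default
  LFP rate of 1250 Hz is an assumption (the source recordings' rate is not
  reported) and is configurable.

The generator is deliberately minimal in ways that matter for
interpretation: the background LFP carries no theta/delta structure, no
EMG is synthesized, spike waveforms are parametric templates, feature
clouds are isotropic Gaussians, no true monosynaptic connections are
injected (CCG typing on a generated session therefore mostly falls back to
spike width, while the CCG pathway itself is validated on dedicated
simulated-synapse fixtures), and event amplitudes are homogeneous within a
kind. Passing tests on this material demonstrates the correctness of the
computations and their calibration under the stated conditions — not
detector performance at the low signal-to-noise ratios real recordings can
present.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `run_pipeline()` seeds once
and produces bit-identical outputs across reruns, which the test suite
verifies by hashing every written table. Tables are TSV with nine
significant digits and `NA` for missing; LFP is float32 binary with a JSON
sidecar; reloading reproduces stored values exactly.

The validation harness uses 2-h hypnograms with 1,000 units for the
type-I calibration, 200 units per direction for sensitivity, a 30-min
session with roughly 100 injected events per kind for the detectors, 500
events per gain level for gain recovery, and 25 simulated synapse pairs
plus 200 independent pairs (1,000 surrogates each) for CCG typing; these
sizes put Monte-Carlo error comfortably below the tolerances being
checked while the whole suite stays quick to run.
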