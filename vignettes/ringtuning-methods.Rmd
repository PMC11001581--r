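---
title: "Models and methods behind ringtuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ringtuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ringtuning)
```

`ringtuning` analyzes head-direction (HD) coding in thalamocortical
circuits, with a focus on the relationship between sharply tuned excitatory
HD cells and broadly, often radially symmetrically tuned fast-spiking (FS)
interneurons. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data tests do
and do not establish about real recordings.

## Tuning curves and HD information

A tuning curve is the ratio of a spike-count histogram to an occupancy
histogram over angular bins (1° by default), both smoothed with a circular
Gaussian kernel (3° s.d. by default, truncated at ±4 s.d.) *before* the
division. Smoothing numerator and denominator separately stabilizes bins
with little occupancy without inventing rate mass: the kernel sums to one,
so total time and total spike count are conserved exactly, and the rate in
an empty bin is inherited from its neighbours. Bins are half-open and
anchored at 0°; angles are yaw in a fixed world frame. Samples slower than
2 cm/s are excluded from both histograms except in cue-rotation and
optogenetic epochs, which are too short to refine.

HD information is
$I = \sum_i \lambda(\theta_i)\,\log_2\!\frac{\lambda(\theta_i)}{\bar\lambda}\,p(\theta_i)$
in bits/s, with $\bar\lambda = \sum_i \lambda(\theta_i) p(\theta_i)$ and
$p$ the normalized occupancy; division by $\bar\lambda$ gives bits/spike,
which is invariant to rate scaling and rotation. Zero-rate bins contribute
zero; a silent cell has undefined bits/spike (`NaN`). The null distribution
comes from a time-reversed control: reversing the HD sample order against
the timestamps preserves both the spike train and the occupancy histogram
while destroying their pairing. Cells are classified as HD cells above the
99th percentile (linear interpolation) of the pooled control distribution,
or above a fixed 0.2 bits/spike cut — the value the percentile rule
resolves to in large cortical datasets. FS cells are defined by waveform
and rate alone (trough-to-peak < 0.4 ms and mean rate > 10 Hz), never by an
information threshold.

## Fourier signatures

The mean-removed curve is projected on $\cos k\theta$ and $\sin k\theta$
for $k = 1$ (period 360°) up to half the bin count (period twice the bin
width, 2° for 1° bins). The power at $k$ is the RMS of the two projections,
scaled so that $\sum_k \text{power}_k^2$ equals the curve's variance —
the Parseval identity fixes the scaling uniquely, and
`parseval_check()` verifies it to below $10^{-9}$ on every non-flat curve.
Phases are four-quadrant arctangents in $(-180°, 180°]$; rotating a curve
by $\delta$ shifts the phase of component $k$ by $k\delta$ and leaves all
powers unchanged. The per-cell *signature* is the power of the first ten
harmonics normalized to their sum (power, not squared power). Signatures
are compared with the KL divergence in natural log units
(the log base is a convention; all comparisons are internal), always
directed as $D(\text{cell} \,\|\, \text{population mean})$, with zero
entries of the cell contributing nothing and zero entries of the reference
floored at $10^{-12}$. The dominant component (argmax over the ten
normalized powers, ties to the lowest harmonic) classifies a cell's radial
symmetry: onefold, twofold, threefold, …

Two population-level summaries are distinct on purpose:
`population_signature()` averages per-cell normalized signatures (a mean of
ratios), while `population_power_spectrum()` normalizes the mean raw power.
Random linear mixing preserves the latter in expectation — the mean of
ratios is biased toward flatness for narrowly tuned cells — so the spectral
preservation analyses use the power spectrum.

## The feed-forward model

Output units integrate HD-tuned input curves linearly through non-negative
random weights: `outputs = W %*% inputs`, with no rectification needed
because weights and rates are non-negative. Weight families
(log-normal, gamma, uniform, truncated Gaussian) are parameterized by their
natural-scale mean and CV; the CV is the lever. At CV 0 all outputs equal
the scaled population mean; as the weight s.d. passes the mean (CV > 1) the
proportions of outputs dominated by the first three harmonics plateau and
become independent of the family and of the mean — `symmetry_proportions()`
estimates them with mean ± s.d. over 30 independent draws per condition.
Output HD information is governed by the *number* of inputs per output, not
the CV: mixing more inputs converges on the population-mean curve. Every
output lies exactly in the span of the input curves (subspace residual
below $10^{-9}$), and the phases of different output components are
mutually independent when preferred directions are uniform.

The two-pathway fit (`fit_two_pathway()`) models a broadly tuned thalamic
(ADN-like) pathway and a sharply tuned cortical (PoSub-like) pathway with
log-normal weights, four free parameters (mean and s.d. per pathway, kept
positive by a softplus reparameterization). The loss is the equally
weighted sum, each term scaled by its target magnitude, of squared
mismatches in (1) mean firing rate, (2) variance of firing rates, and
(3) variances of the first ten Fourier coefficient magnitudes across
outputs. Statistics are computed from common random numbers — fixed
standard-normal draws scaled by the current parameters — averaged over four
weight batches to tame the heavy-tailed sampling noise, and evaluated via
the linearity of the DFT (output Fourier coefficients are the weighted
mixture of input coefficients), which avoids materializing output curves.
The optimizer runs a multi-start finite-difference gradient descent with
backtracking and then a Nelder-Mead simplex refinement: the loss surface
has long curved valleys in which fixed-step descent reliably stalls around
$10^{-4}$ with pathway CVs off by tens of percent, while the simplex polish
reaches the exact self-consistent zero. On targets generated by the same
machinery the fit recovers the generating CVs; on independently drawn
targets the residual error reflects the sampling noise of 500-cell
statistics. Decomposing fitted outputs into per-pathway contributions uses
the modulation depth $(\max-\min)/(\max+\min)$; broad-ADN/narrow-PoSub
inputs yield a flatter ADN than PoSub contribution.

## Ring manifold and virtual HD

Population vectors are 200 ms spike-count bins per HD cell, smoothed with a
400 ms s.d. Gaussian and square-root transformed. The embedding is
Isomap-style: a k-nearest-neighbour graph (k = 12, Euclidean distances,
ties broken by item index, exact duplicates separated by a fixed-seed
$10^{-9}$ jitter), all-pairs shortest-path geodesic distances, classical
MDS into 3 dimensions (2 for tuning-shape space). A disconnected graph is
reduced to its largest component and the dropped items flagged. Dense
eigendecomposition keeps this practical up to a few thousand items; the
pipeline caps the embedded set at 2,500 vectors. When population vectors
come from temporally smoothed, contiguous bins, adjacent bins are strongly
correlated and can monopolize the neighbour lists, turning the graph into a
temporal thread; embedding every second bin (0.4 s spacing) removes this
artifact without touching k.

The virtual HD $\alpha$ is the four-quadrant arctangent of the first two
embedding dimensions. Its direction is arbitrary, so the sign is chosen by
whichever of $\text{real} - \alpha$ or $\text{real} + \alpha$ has the
smaller circular variance; its origin is arbitrary, so internal tuning
curves of the HD cells (1° bins, 3° smoothing in wake; 6° bins and
smoothing for REM, where virtual-HD occupancy is uneven) are
cross-correlated with their real-HD curves and $\alpha$ is rotated by the
circular mean peak offset. The procedure depends only on HD cells, so FS
cells remain fully held out: their internal tuning from $\alpha$ is an
independent prediction. For wake/REM comparisons the wake vectors are
randomly downsampled to the REM count and both epochs are embedded
jointly; sessions with under 100 s of REM are skipped.

## Decoding and cue rotation

The Bayesian decoder assumes independent Poisson spiking with rates given
by baseline tuning curves: per 50 ms bin the log posterior under a uniform
prior is $\sum_i n_i \log \lambda_i(\theta) - \tau \sum_i
\lambda_i(\theta)$, with counts smoothed by a 100 ms Gaussian (non-integer
counts enter the same expression) and rates floored at $10^{-3}$ Hz.
Decoder error is the signed smallest angle between decoded and real HD —
signed, because a cue rotation has a direction.

In the cue-rotation analysis the cue alternates between two positions 90°
apart every 200 s. Rotation epochs are excluded when the following epoch's
mean absolute decoder error stays under 45° (no realignment happened — by
construction this also excludes every return-to-origin epoch, whose error
returns to zero) or when the animal was slower than 2 cm/s in the
preceding epoch. A four-parameter logistic
$y = A + (B-A)/(1+e^{-(t-t_0)/s})$ is fitted to the error time course by
Levenberg-Marquardt from five midpoint starts (the best deviance wins;
single-start fits occasionally lock onto a boundary), and the realignment
window is where the normalized sigmoid crosses 0.01 and 0.99. Per-epoch
tuning is computed from the realignment end to the next rotation, bounded
so that at least the last 40% of the epoch contributes even when a shallow
sigmoid stretches the nominal window.
Per-cell rotations are cross-correlation peak offsets between
consecutive-epoch curves; in addition, tuning is pooled across all stable
windows at each of the two cue positions and cross-correlated once per
cell — the pooled estimate is far less alias-prone for multipeaked FS
curves, and the FS-vs-HD comparison uses it.

## Monosynaptic detection and spike-rate coupling

Cross-correlograms span ±50 ms in 0.2 ms bins (501 bins). The baseline
predictor is the correlogram convolved with a full (non-hollow) 4 ms s.d.
Gaussian; each bin is tested against the Poisson 99th percentile at the
predicted rate, and a connection requires at least two consecutive
suprathreshold bins inside the short-latency search window (0.5-5 ms after
the presynaptic spike; configurable — a standard monosynaptic latency
band). The weight is the excess count over the predictor summed across the
contiguous positive-excess run containing the window peak, per presynaptic
spike: a single-bin peak amplitude systematically under-recovers efficacy
once latency jitter spreads the peak over several 0.2 ms bins, while the
summed excess is insensitive to the jitter scale. The discreteness of the
Poisson threshold plus the two-bin rule suppress the nominal 1%-per-bin
false-positive rate to well under 2% of independent pairs.

Pairwise spike-rate coupling fits, per time offset on a ±10 s / 0.1 s
grid, a Poisson GLM with log link of cell A's binned-and-smoothed rate on
cell B's offset rate and the aggregate population rate. Smoothed counts
are non-integer; they are fitted by the same IRLS Poisson deviance anyway —
a statistical irregularity reproduced deliberately, as standard GLM
fitters accept it. The asymmetric procedure is repeated with the roles
swapped and averaged at equivalent offsets, making the reported curve
exactly symmetric under pair exchange; non-convergent or boundary fits are
flagged and excluded. Wake/REM conservation is the Pearson correlation of
coupling values across pairs, per pair class, either at zero offset or
over full curves (both modes exist because either reading of the
conservation statistic is defensible).

## Gain decomposition

Baseline (light-OFF) and high-gain (light-ON) tuning curves are computed
in 6° bins with no smoothing — smoothing would correlate adjacent bins and
bias the regression — and no speed filter. Both are divided by the
baseline maximum and the high-gain curve is regressed on the baseline
curve by ordinary least squares (matching the conventional polynomial-fit
usage; occupancy weighting is deliberately not applied). Slope =
multiplicative factor, intercept = additive factor in units of the
baseline maximum. Cells enter the analysis only when both the Wilcoxon
signed-rank test on per-period ON vs OFF rates and the Pearson correlation
between the two curves are significant at 0.05. `noise_detectability()`
maps how estimation noise attenuates the recovered slope: in `forward`
mode noise corrupts only the high-gain curve; in `eiv` mode both curves,
the classic errors-in-variables regime where the slope attenuates by
$\mathrm{var}(x)/(\mathrm{var}(x)+\sigma^2)$. Both modes exist because
noise placement changes the bias direction; `forward` is the default for
simulating a noisy manipulated estimate.

## The synthetic-session generator

The generator emulates the statistical structure the analyses assume, with
ground truth retained:

- **Trajectory**: head direction is wrapped Brownian motion
  (`angular_diffusion`, deg²/s, default 200 — angular increments over lag
  $\tau$ have circular variance $1 - e^{-D\tau(\pi/180)^2/2}$), sampled at
  10 ms. Speed has a log-normal marginal with an Ornstein-Uhlenbeck
  correlated latent (defaults: median 8 cm/s, log-s.d. 0.7, correlation
  time 1 s), so the 2 cm/s filter removes a realistic ~10-15% of samples.
- **HD cells**: von Mises bumps plus a constant baseline, preferred
  directions uniform, FWHM uniform on 60-120° (regional width differences
  are modeled by this range), peak modulation 5-40 Hz, baseline 0.1-1 Hz.
  The functional form is an assumption: only "HD-like" unimodality and a
  width scale are required downstream.
- **FS cells**: exact linear mixtures of the HD curves through draws from
  the configured weight family (default log-normal, CV 2, all inputs, mean
  3/n so FS rates land in the fast-spiking range).
- **Spiking**: per-10 ms Poisson counts at $\lambda(\text{hd}(t))\,dt$
  with uniform within-step jitter — 10 ms is far below every smoothing
  kernel used downstream. Opto epochs replace $\lambda$ with
  $m\lambda + a\max\lambda$; negative rates are clipped at zero and
  counted.
- **REM**: the head freezes, speed drops to zero, and spiking follows a
  latent wrapped Brownian angle with its own diffusion constant
  (default 400 deg²/s — internally generated drift is faster than
  behaviour).
- **Cue rotations**: the whole ground-truth population rotates coherently
  with a sigmoidal time course between two cue positions 90° apart every
  200 s (16 switches by default after a stable baseline).
- **Synapses**: per presynaptic spike, with probability `efficacy`, a
  postsynaptic spike is inserted at the latency plus Gaussian jitter.

Everything is seed-deterministic; each stage consumes a named substream of
the master seed, so adding a unit never changes another unit's spikes.

What passing tests show — and do not. The generator produces
inhomogeneous-Poisson spikes from stationary tuning on a diffusive
trajectory. Real recordings have non-Poisson spiking statistics
(refractoriness, bursting), slow drifts in excitability, theta rhythmicity
and behavioural correlations that the generator omits. Recovery tests
therefore validate the *estimators* (that each analysis recovers the
structure it targets when that structure is present, at realistic rates and
durations), not the biological conclusions themselves.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale versions of each analysis, chosen
as the smallest sizes at which the estimators are comfortably in their
asymptotic regime: 30-minute sessions and 200 cells for spectral
concentration; 500 outputs for mixing-preservation and the two-pathway
fit; 30 repeats for symmetry proportions; ~2,500 embedded population
vectors for ring recovery (the >0.99 circular-correlation check uses a
densely sampled ring — 160 inputs, 0.2 s bins, independently drawn latent
angles — because the statistic behaves like the squared cosine of the
angular error and demands ~3° RMS accuracy); 500 independent pairs for the
false-positive audit. Circular correlation between angle series uses the
pairwise Fisher-Lee form (computed in O(n) by product-sum identities),
which is well defined for uniform marginals where mean-direction-based
forms are not. Percentiles use linear interpolation. All degenerate inputs
(flat curves, empty trains, zero-variance regressors, silent cells,
disconnected graphs) return flagged values or errors rather than silent
numbers.

## Known limitations

- The linear feed-forward model ignores recurrence, conductance effects
  and spiking nonlinearity; it is a model of tuning-curve mixing only.
- Isomap-based virtual HD degrades when the ring is unevenly covered
  (short sessions, slow exploration); the radial coordinate's CV is the
  practical diagnostic.
- The two-pathway fit's pathway means are only weakly identified by the
  three constraint groups (one linear constraint ties the two means);
  recovery of the CVs relies on the weak coherent terms and is accurate at
  500-output scale only with the simplex refinement.
- The monosynaptic detector targets excitatory (peak) connections only;
  troughs (inhibition) are out of scope.
- Session directories store spike times as text; precision below about a
  nanosecond is not preserved through CSV round-trips.
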