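# ringtuning

Analysis toolkit for head-direction (HD) coding in thalamocortical circuits,
built around one scientific question: where does the tuning of fast-spiking
(FS) cortical interneurons come from? In the postsubiculum, most excitatory
neurons are classical HD cells with a single sharp peak, while FS
interneurons show broad, irregular, often radially symmetrical tuning
(two or three equally spaced peaks). `ringtuning` implements the analyses
that link the two populations:

- **Tuning curves and metrics** — occupancy-normalized circular tuning
  `λ(θ)` in 1° bins with circular Gaussian smoothing, HD information
  `I = Σᵢ λ(θᵢ) log₂(λ(θᵢ)/λ̄) p(θᵢ)` (bits/s, normalized to bits/spike),
  time-reversed controls, FWHM, multipeak and cluster-contamination scores,
  cross-validated circular auto-/cross-correlograms.
- **Fourier signatures** — each tuning curve decomposed onto the harmonics
  of the circle (period 360° down to 2°); power is the RMS of the sine and
  cosine projections so that `Σₖ powerₖ² = var(curve)` (Parseval); the
  normalized power of the first ten harmonics is the cell's *Fourier
  signature*, compared across cells with the KL divergence
  `D(σᵢ‖S) = Σₖ σᵢ(k) log(σᵢ(k)/S(k))`.
- **Ring manifold** — Isomap-style geodesic embedding (kNN graph +
  shortest paths + classical MDS) of HD population vectors; the angular
  coordinate α of each population vector on the embedded ring is a
  *virtual HD* that can be read out during wake and REM sleep, and used to
  build internal tuning curves for held-out cells.
- **Decoding and cue rotation** — Poisson Bayesian HD decoding
  (`log P(θ) ∝ Σᵢ nᵢ log λᵢ(θ) − τ Σᵢ λᵢ(θ)`), sigmoid-fitted realignment
  after visual-cue rotations, per-cell tuning rotations.
- **Connectivity** — monosynaptic connection detection from ±50 ms / 0.2 ms
  spike cross-correlograms against a 4 ms-Gaussian baseline predictor with
  a Poisson 99th-percentile threshold and a two-consecutive-bin rule;
  synaptic weight distribution statistics (mean, s.d., CV, skewness).
- **Spike-rate coupling** — pairwise Poisson GLM of one cell's binned rate
  on another's plus the population rate, across ±10 s offsets, and its
  conservation between wake and REM.
- **Feed-forward model** — the core circuit model: output units linearly
  integrate HD-tuned inputs through random non-negative weights. The weight
  coefficient of variation (CV = s.d./mean) governs the emergence of radial
  symmetries in the outputs (plateauing once s.d. exceeds mean), the number
  of inputs governs the output HD information, and a two-pathway
  (thalamic + cortical) version is fitted to output statistics by gradient
  descent.
- **Gain decomposition** — optogenetic gain changes split into additive
  (intercept) and multiplicative (slope) factors by regressing the
  max-normalized high-gain tuning curve on the baseline curve, with
  inclusion filters and noise-detectability simulations.
- **Synthetic sessions** — a seed-deterministic generator
  (`simulate_session()`, `generate_cue_session()`) producing spike trains,
  trajectories, epochs and unit metadata with full ground truth retained,
  so every analysis above is testable end to end.

## Worked example

```r
library(ringtuning)

ses <- simulate_session(session_config(
  duration_s = 600,
  hd = list(n = 25, peak_rate_range = c(10, 40)),
  fs = list(n = 5, n_inputs = 8),
  seed = 515))

res <- run_pipeline(ses, stages = c("tuning", "fourier"), seed = 2)

# a canonical HD cell
print(res$tuning$curves[["hd001"]])
#> tuning_curve: 360 bins of 1 deg, peak 42.03 Hz at 284 deg, mean 9.49 Hz, occupancy 587.5 s
round(res$tuning$info[1], 2)     # HD information, bits/spike
#> 0.72
res$tuning$is_hd[1]
#> TRUE

# an FS-like mixture cell: broad tuning, low information
round(res$tuning$info[26], 3)
#> 0.077

# Fourier signature of the FS cell: power concentrated in few low harmonics
print(res$fourier$signatures[[26]])
#> fourier_signature: dominant k = 1, first 10 harmonics hold 97.8% of power
round(res$fourier$population, 3)  # population mean signature
#> 0.501 0.255 0.108 0.045 0.021 0.015 0.013 0.013 0.013 0.015
```

The printed numbers are what the code produces for this seed: the HD cell
carries 0.72 bits per spike of directional information, the FS mixture an
order of magnitude less (0.077), while the FS cell's tuning-curve power
still lives almost entirely in the first ten harmonics and the population
mean signature decays smoothly with harmonic number — the spectral
equivalence the package is built to quantify.

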