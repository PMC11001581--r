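Package: ringtuning
Title: Head-Direction Tuning Curves, Fourier Signatures and Ring-Manifold
    Analysis of Excitatory-Inhibitory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing head-direction (HD) coding in cortical
    circuits: occupancy-normalized circular tuning curves and HD information,
    Fourier decomposition of circular tuning into harmonic power/phase
    signatures, Isomap-style geodesic embeddings of tuning-curve shape space
    and of the HD population ring manifold (with virtual-HD extraction during
    wake and REM sleep), Poisson Bayesian HD decoding and cue-rotation
    realignment, detection of putative monosynaptic connections from
    fine-timescale spike cross-correlograms, population-rate-conditioned
    pairwise spike-rate coupling (Poisson GLM), additive/multiplicative gain
    decomposition of optogenetic manipulations, and a random feed-forward
    linear-integration model linking heavy-tailed synaptic weight
    distributions to the radial symmetries of fast-spiking interneuron
    tuning. Includes a seed-deterministic synthetic-session generator with
    retained ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
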