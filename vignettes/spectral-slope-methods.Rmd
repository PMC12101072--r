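---
title: "Measuring and comparing spectral slopes of colour patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing spectral slopes of colour patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specslope)
```

# The measurement

The quantity this package measures is the **spectral slope** of an image:
fit a line, by ordinary least squares, to the rotationally averaged Fourier
amplitude against spatial frequency on log–log axes. Natural scenes cluster
near a slope of −1 (the familiar 1/f statistic); white noise is flat
(slope 0); images dominated by large smooth structures are steeper. Because
the slope is a pure exponent it is invariant to overall image brightness
and to the base of the logarithm — both invariances are asserted in the
test suite rather than assumed.

The full chain, in order, is:

1. convert the multispectral stack to the receptor's view
   (`fit_computational_filter()` + `apply_filter_weights()`),
2. preprocess (`preprocess_stack()`: dark subtraction, pixel repair,
   normalisation, Naka–Rushton),
3. crop (`largest_inscribed_square()` for specimens,
   `center_square_crop()` for scenes),
4. taper, transform, average, restrict, bin, fit
   (`measure_spectral_slope()`),
5. compare groups (`fit_hierarchical_model()`, `contrast()`).

The order matters and is fixed: pixel repair happens *after* the receptor
conversion; normalisation *before* the Naka–Rushton transform; the taper
*after* cropping. `run_specimen_batch()` enforces it.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `taper_frequency` | 4 | cycles/image | upper edge of the taper window's own spectral content; keeps it below the 5 cpi analysis floor |
| analysis band | 5 … side/10 | cycles/image | floor excludes taper content; ceiling guards against aliasing and pixel-level artefacts |
| `n_bins` | 9 | – | equalises the leverage of sparsely sampled low frequencies on the log axis |
| `fov_mm` | 5.7 | mm | horizontal field of view of the reference macro configuration (1392 px across) |
| `inter_receptor_deg` | 0.04 | degrees | salticid principal-eye inter-receptor angle used for the resolution bound |
| `chains`, `iterations`, `warmup` | 4, 5000, 2500 | – | reference MCMC settings; halved freely in tests since the Gibbs/slice sampler mixes fast |

Frequencies exist in two unit systems: **cycles/image** (integer ring
indices of the crop) and **cycles/mm** (physical, `cpi / crop_mm` where
`crop_mm = side_px × FOV / width_px`). Within a species, analysis bounds
are harmonised in cycles/mm so males and females are compared over the same
physical scales.

# Numerical conventions

**Taper geometry.** The "cosine taper with spatial frequency four" is
implemented as a separable Tukey window: flat interior, raised-cosine
roll-off of width `side / taper_frequency` at each edge, blending to the
image mean so corners sit exactly at the mean. The roll-off width was the
one genuinely open numerical choice. A narrower reading (roll-off
`side / (2·taper_frequency)`) looks equally plausible on paper but fails in
practice: its window spectrum extends to ~8 cycles/image, leaking the very
large low-frequency energy of steep images into the 5–8 cpi rings, which
biases a β = −2 image's measured slope by −0.08. With the quarter-side
roll-off the window's content stays below ~4 cpi — the only reading under
which "analyse from 5 cpi upward *to exclude the taper*" is coherent — and
recovery is unbiased to < 0.01 across β ∈ [−2, 0]. The package treats this
as a correctness constraint, not a tuning knob.

**Ring membership.** A Fourier coefficient at Euclidean distance *r* from
DC belongs to integer ring `floor(r + 0.5)` (half-up rounding). DC is
excluded; rings beyond `floor(side/2)` (Nyquist) are dropped. The
implementation is vectorised; the tests compare it against a literal
double-loop enumeration on every grid size up to 64² and on 128² spot
checks.

**Binning.** Bin edges are evenly spaced in log10 frequency. Per bin, y is
`log10(mean amplitude)` — mean first, then log — and x is the mean log10
frequency of the members. Mean-then-log follows the source convention but
is not exactly bin-invariant on a pure power law: it leaves a curvature
residue of order 2·10⁻⁵ in the fitted slope (the log-then-mean alternative
would be exact). Tests assert the pure-power-law fit at 10⁻⁴ and R² ≥
0.999. Empty bins are dropped with a warning and the used count is
reported.

**Harmonisation direction.** To give all members of a species a common
frequency range in cycles/mm, the common lower bound is the **maximum** of
the per-member minima (`mode = "intent"`). A literal "take the lowest
minimum" (`mode = "literal"`) is available but excludes nothing by
construction, which defeats the purpose of a common range; the default
implements the evident intent.

**R².** Reported for the binned regression actually fitted — nine points —
not for the unbinned ring amplitudes.

**Exposure-stability statistic.** "Variation" across three consecutive
frames is `(max − min) / mean` of the three frame means: scale-free,
conservative, and computed on every sliding window of three. The 0.5%
threshold is a strict inequality. Other readings (SD-based, per-pixel) are
defensible; this one is documented rather than claimed canonical.

**Degenerate inputs.** Empty masks, non-square FFT inputs, non-positive
normalisation references, negative excitation inputs, sub-60-px crops,
single-chain diagnostics and single-species random-slope fits all error
with explicit messages. Saturated regions with no valid donor anywhere on
their boundary error rather than invent data. SD parameters in the sampler
have a numerical floor of 10⁻⁶ so zero-variance cohorts remain computable.

# The hierarchical model

Spider slopes follow

$$y_{ij} = \alpha + \beta\,male_{ij} + a_j + b_j\,male_{ij} +
\varepsilon_{ij}, \qquad (a_j, b_j) \sim \mathcal N_2(0, \Sigma),\quad
\varepsilon_{ij} \sim \mathcal N(0, \sigma^2),$$

with species *j* contributing a random intercept and a random sex effect;
scene slopes get one mean per region, `y_k ~ N(μ_region, σ_scene²)`, fitted
jointly. Priors are weakly informative: improper flat on α, β and the
region means, half-Normal(0, 5) on every SD, uniform on the random-effect
correlation. "Flat defaults" in the reference analysis under-specify the SD
priors; half-Normal(0, 5) is a standard weak choice on the slope scale
(values are order 1) and is the package's documented decision.

The sampler is Gibbs for every conditionally conjugate block with
univariate slice updates for SDs and the correlation — correct for this
conjugate normal hierarchy with no step-size tuning. The fixed-effects
update integrates the random effects out (per-species Woodbury identities),
which removes the α–a ridge that otherwise freezes mixing when σ is tiny;
the zero-noise recovery test exercises exactly that regime. Convergence is
summarised by rank-normalised split-Rhat and bulk ESS (Geyer initial
monotone sequence); a fit with any Rhat > 1.01 warns and is flagged, with
summaries still emitted.

Group means for contrasts are the fixed-effect quantities: female mean α,
male mean α + β, scene mean the unweighted average of the region means. A
95% equal-tailed credible interval excluding zero is read as credible
evidence of a difference.

# What the synthetic generators emulate — and what they don't

`gen_powerlaw_image()` draws Hermitian-symmetric uniform phases against a
deterministic `f^β` amplitude profile, sets DC for an exact target mean,
scales fluctuations to a target RMS contrast, clips to [0, 1] and reports
the clipped fraction (clipping distorts spectra, so it must be visible; the
mean is re-centred to a fixed point after clipping). `gen_abdomen_mask()`
produces a single 4-connected elliptical or fan-like region covering
20–80% of the frame. `gen_multispectral_stack()` applies a linear camera
forward model — reflectance × filter inner products, gain, dark offset,
Gaussian read noise, forced saturation, dark columns, an optional grey
patch. `gen_cohort()` draws slopes from exactly the Gaussian hierarchy the
model assumes. Generator defaults (18 species, 5 per sex, female mean
−1.15, sex difference −0.31, scene mean −1.09 ± 0.14 over 41 scenes) echo
published summary statistics for the motivating system so demonstration
runs look like real cohorts.

That choice is about interpretability, **not** validation: a green test
establishes that the pipeline recovers the parameters of its own stated
world. Real data differ in ways the generators deliberately omit —
anisotropic and non-Gaussian scene statistics, spatially structured
iridescence, segmentation error in masks, chromatic aberration, model
misspecification in the cohort (non-Gaussian residuals, unequal group
sizes). In the image fixtures the power-law texture is pasted into the
exact region the pipeline will crop, because a sub-window of a larger
power-law field carries extra windowing bias (measured ≈ −0.05 at a
280-px window of a 512-px β = −1.5 field) that is not part of the declared
ground truth.

MCMC-heavy tests (two 50-replicate calibrations at the 18-species design)
run with 2 chains × 1200 iterations instead of the 4 × 5000 reference
settings — a runtime concession only; replicate counts, design size and
coverage thresholds are unchanged.

# Known limitations

- Orientation information is discarded by rotational averaging; anisotropy
  is out of scope.
- The receptor conversion is linear; fluorescence or polarisation effects
  are not modelled.
- Masks are taken as given; segmentation is upstream.
- Raster I/O is plain-text PGM; binary TIFF/PNG support would need an
  external imaging dependency.
- The inscribed-square tie-break (centre nearest the mask centroid, then
  smallest row, then column) is a deterministic convention, not a claim
  about any particular historical implementation.
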