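---
title: "Methods: motion-gated LFP analysis, coupling, complexity, pathology loads and factorial inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion-gated LFP analysis, coupling, complexity, pathology loads and factorial inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpath)
```

`lfpath` implements the complete desk-scale computational chain of a
longitudinal amyloid/tau mouse electrophysiology and pathology study:
motion-gated epoching of multi-channel local field potentials (LFP),
Welch band-power estimation, theta-gamma phase-amplitude coupling (PAC)
by the Tort modulation index, Higuchi fractal dimension (HFD)
complexity, voxel-based regional pathology loads with
plaque-colocalization splitting, and factorial linear mixed-model
inference with likelihood-ratio interaction testing, predicted marginal
means and Benjamini-Hochberg (BH) false-discovery-rate control. A
synthetic-data generator produces every input with known ground truth,
so the whole pipeline is testable without any recording hardware or
imaging data.

## Preprocessing: activity gating and artifact rejection

Sessions are split into contiguous, non-overlapping 4-s epochs
(trailing remainder discarded). An epoch enters the analysis only if
the animal was behaviorally active during it: the activity threshold is
30% of the peak video-tracked displacement over the entire session, and
an epoch counts as active when at least a quarter of its 25 Hz video
frames exceed that threshold (`min_active_fraction = 0.25`). The
"sufficient duration" rule is a package convention exposed as a knob: a
relative-duration rule is scale-free, and the threshold's relativity to
the session peak makes the gate exactly invariant to uniform rescaling
of the displacement trace. At the canonical rates (1000 Hz LFP, 25 Hz
video) each 4-s epoch aligns exactly with 100 video frames, so the
alignment is an integer frame-index map with no interpolation.

Artifact screening is deliberately permissive and catches only gross
faults: absolute amplitude above 1000 µV, robust z-score (against the
session-wide per-channel median/MAD) above 8, or a flatline run of 100
identical samples. These defaults are package conventions, not values
taken from any particular acquisition setup; they are monotone knobs
(loosening any limit can only unflag epochs). A session is excluded
when fewer than `min_retained = 30` clean active epochs survive. No
band-pass pre-filtering is applied before epoching.

## Spectral stage

The pipeline order is fixed: Welch periodogram, median filter across
frequency bins, natural log, epoch averaging, band extraction.

* **Welch PSD** uses 1-s Hamming-windowed segments with 50% overlap
  (seven segments per 4-s epoch), giving a 1 Hz grid from 0 Hz to
  Nyquist. One second was chosen because the frequency bands have
  integer edges and the spectra of interest span 1-100 Hz; the window
  power correction makes the integrated density consistent with signal
  variance (Parseval) to within ten percent on white noise.
* **Median filter**: kernel of 5 bins with reflected edges — the
  smallest kernel that removes single-bin line noise while leaving a
  constant spectrum untouched.
* **Log transform**: natural log with the density floored at the
  smallest positive normalized double, keeping the transform total.
* **Bands**: delta 1-4, theta-1 4-6, theta-2 6-8, low gamma 30-50,
  high gamma 51-80 Hz. Abutting edges force a disjointness convention:
  bands are half-open on the right, with high gamma closed at 80 Hz,
  and the 50-51 Hz gap between the gamma bands is kept as defined.
* **Band power** is the mean of log-density bins (not the log of
  integrated power): band summaries on the log scale match per-band
  "log power" bar-plot semantics and inherit the exact `2 ln k` shift
  under amplitude scaling `k`. The integrated alternative is available
  via `band_power(..., method = "integrated")`.

## Phase-amplitude coupling

Phase and amplitude are both extracted from complex Morlet convolutions
of width 7 cycles — no separate filter-Hilbert path. The comodulogram
grids are 2-12 Hz in 0.5 Hz steps (phase) by 10-200 Hz in 5 Hz steps
(amplitude). The wavelet support is truncated at ±3 standard deviations
of its Gaussian envelope so that even the 2 Hz wavelet (σ_t ≈ 0.56 s)
fits inside a single 4-s epoch; no within-epoch edge trimming is
applied (an option exists to drop the convolution tails).

The Tort modulation index bins phase into 18 equal bins over (-π, π]
(the canonical choice for this estimator), computes the normalized mean
amplitude per bin, and returns the Kullback-Leibler divergence from
uniform divided by `ln 18`, so MI ∈ [0, 1] with 0 exactly at uniformity.
MI is computed per epoch and then averaged — a 4-s epoch holds eight
cycles of a 2 Hz phase signal, which is short; concatenation across
epochs is therefore exposed as an alternative for very low phase
frequencies, but per-epoch averaging is the default because every other
readout is an epoch average. An empty phase bin (impossible for
multi-second nondegenerate signals) contributes zero mean amplitude and
raises a warning rather than an error, keeping batch runs total.

Band-pair summaries average comodulogram cells with the spectral
band-edge convention: theta-1 phase columns {4, 4.5, 5, 5.5}, theta-2
{6, 6.5, 7, 7.5}, low-gamma amplitude rows {30, 35, 40, 45}, high-gamma
{55, 60, 65, 70, 75, 80}.

## Higuchi fractal dimension

For delays `k = 1..13` and offsets `m = 1..k`, the normalized curve
length is

$$L_m(k) = \left[\sum_{i=1}^{\lfloor (N-m)/k\rfloor} |x(m+ik) - x(m+(i-1)k)|\right]
\frac{N-1}{\lfloor (N-m)/k\rfloor\,k}\cdot\frac1k,$$

`L(k)` the mean over offsets, and the dimension the OLS slope of
`ln L(k)` on `ln(1/k)` over the full delay range (no subset selection;
only `kmax = 13` is fixed). The exact normalization factor matters — its
omission changes values, and the unit tests pin it against an
independent double-loop implementation. Smooth signals score near 1,
uncorrelated noise near 2, Brownian motion near 1.5. A constant epoch
has zero curve length at every delay and returns 1.0 with a degenerate
flag rather than an error. The estimator is exactly scale-invariant and
offset-invariant (up to floating-point roundoff of the sums).

## Pathology quantification

Quantification starts from binary segmentation masks and an integer
region-label volume (axis order z, y, x; label 0 background) —
segmentation of raw light-sheet images is out of scope. The regional
load ("label ratio") is positive voxels divided by the region's voxel
count. Plaque-associated tau is defined by a 5-voxel Euclidean-ball
dilation of the plaque mask: tau voxels inside the dilated boundary are
plaque-associated, the rest non-associated. The dilation is fully 3D
and isotropic in voxel units — the boundary is defined in pixels, not
micrometres, so physical voxel anisotropy is deliberately ignored; a
per-slice 2D variant can be emulated by passing single-slice volumes.
All splits use integer voxel arithmetic before division, so
colocalized + non-associated equals the total load exactly, to the last
bit. Loads are fractions; multiply by 100 for percent. Pearson
correlation between pooled load vectors uses the t transform on n - 2
degrees of freedom.

## Factorial mixed-model inference

Readouts are modeled with a Gaussian linear mixed model: sex, age at
injection, genotype, treatment, timepoint and region (or electrode) as
main effects, the full factorial interaction product of all factors
except sex, and a random intercept per animal. Sex is main-effect-only
and is averaged over (equal weights) when predicted marginal means are
formed. Estimation is maximum likelihood, not REML, because REML
log-likelihoods are not comparable across fixed-effect structures; fits
are deterministic given the data. Two degenerate designs drop to
ordinary least squares on the same fixed structure: one observation per
animal (random intercept unidentifiable) and noiseless outcomes
(singular covariance).

The interaction df is analytic: the product over the term's factors of
(observed levels - 1), which equals the number of columns the term adds
to a full-factorial design matrix (verified against `model.matrix`
column counts). The likelihood-ratio statistic is
`2(logLik_full - logLik_null)` against the chi-square upper tail on that
df. `drop_and_refit()` tests the highest-order term first; while an
entire order tests non-significant at α = 0.05 it is removed, the model
refit, and each next-lower-order term tested against its own null,
emitting the full decision trail.

Contrast tables use predicted marginal means (via `emmeans`) with SEs
from the coefficient covariance and a constant residual df
(observations minus fixed-effect parameters) per table — the constant
per-table df mirrors standard practice for balanced designs; a
normal-theory alternative (`df_method = "asymptotic"`) is exposed.
Raw two-sided p-values are BH-adjusted within each table with the
step-up rule, significance at q = 0.05.

The ML likelihood-ratio test is asymptotic: with ~50 fixed-effect
parameters its type-I error is calibrated only when observations
comfortably exceed parameters (the statistic inflates by roughly
`n/(n - p)`). The calibration check therefore uses 10 animals per
between-animal cell (960 observations against 49 parameters) of the
reduced design (2×2×2 factors, 3 timepoints, 2 regions); at desk scale
with 1-3 animals per cell the same test rejects a true null in about
9-20% of runs — a known small-sample property worth keeping in mind
when interpreting borderline interactions.

## The synthetic-data generator

The generator emulates the study's inputs, not its biology:

* **LFP**: 1/f^α background (spectral shaping of white noise; default
  α = 1, 30 µV RMS at 1000 Hz), band-limited Gaussian oscillations, and
  optional PAC by multiplicative envelope modulation — a narrowband slow
  oscillation supplies the phase θ(t), and a narrowband carrier is
  multiplied by `(1 + m cos(θ - φ0))/2`, so the modulation depth
  `m ∈ [0, 1]` orders the measured MI monotonically and `m = 0` is
  exactly uncoupled. Optional artifacts: large transients and flatline
  drop-outs at per-minute rates.
* **Motion**: alternating exponential active/inactive bouts; the
  inactive-bout mean is scaled so the long-run active fraction matches
  the request. Active frames draw displacements on [0.4, 1] × amplitude
  (all clear the 30%-of-peak gate); inactive frames are exactly zero, so
  a fraction of 0 yields a still animal and zero active epochs.
* **Study tables**: outcomes from a declared linear predictor over the
  full factorial design plus animal random intercepts and residual
  noise; the true coefficient vector is returned, and with all SDs zero
  the outcomes reproduce it exactly.
* **Pathology volumes**: desk-scale (default 32×64×64; all operators
  are resolution-agnostic) slab-labeled regions, spherical plaques,
  cubic tau clusters; `affinity` is the probability a tau cluster is
  seeded within the dilated neighborhood of a plaque. Geometry clipped
  at the bounds is counted in the returned truth record. No attempt is
  made to simulate tau spreading dynamics or plaque growth.

The end-to-end driver (`simulate_ephys_study()`) builds a genotype ×
treatment study (balanced sexes, two electrodes, 48-s sessions of
twelve 4-s epochs, 70% active bouts) with two injected effects chosen
once to echo the magnitudes such studies report: a TG-vs-WT theta-2
log-power shift of 0.65 ln units on the RSC electrode only (injected as
a theta amplitude multiplier `exp(0.65/2)`), and an HFD reduction in
seeded TG animals injected by raising their 1/f exponent by 0.5
(characterized once on this generator: fractal dimension falls from
≈1.80 at α = 1.0 to ≈1.55 at α = 1.5, with between-animal spread well
below that drop at the chosen jitter SDs of 0.25 ln units power and
0.05 exponent units). Because a steeper exponent also reallocates
background power across bands, the seeded-TG group shows incidental
band-power shifts too — as pathology does in real recordings; the
detection checks target only the built-in contrasts. Short sessions
can draw an all-inactive bout sequence; such sessions would be excluded
in practice, so the driver re-records them with a fresh motion seed
(still deterministic given the study seed).

What passing tests show — and what they do not: the synthetic LFP is
stationary within a session, noise is Gaussian, electrodes are
independent, and pathology geometry is convex and uniformly placed.
Real recordings violate all of these (nonstationarity, movement
artifacts, volume conduction, correlated electrodes, irregular
pathology morphology), so green tests certify the computational chain,
not robustness to every property of real data.

## Numerical conventions

* Determinism: every generator takes an explicit seed and restores the
  caller's RNG state; identical spec + seed is bit-identical.
* Phase bins are half-open (-π, π] with phase exactly -π folded into
  the first bin; MI of an all-zero signal is 0 by the uniform
  convention.
* TSV writers emit 6 significant digits with unit-suffixed numeric
  headers and stable row order; EDF output quantizes to 16 bits over a
  per-channel symmetric physical range (round-trip error below
  range/2^16), and the CSV path is lossless.
* Desk-scale problem sizes used in the checks: 4000-sample epochs,
  60-s coupling runs, 8^3-24×32×32 voxel volumes, 500-run LRT
  calibration, 20-seed detection runs — all chosen so the full suite
  reruns in minutes on one core.

## Known limitations

The EDF writer supports continuous recordings at integer sampling rates
only. TIFF volumes are 8-bit (labels ≤ 255); use NIfTI beyond that.
PAC has no surrogate-based significance testing (none is part of the
procedure), and no alternative estimators (PLV, GLM-PAC). The mixed
model is Gaussian-identity only; pathology fractions are modeled
untransformed by default with a logit option for near-boundary loads
left to the user's discretion.
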