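---
title: "Pair-correlation analysis of line-scan carpets: models, simulator, and design choices"
author: "carpetFCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-correlation analysis of line-scan carpets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carpetFCS)
```

## The measurement

A confocal spot is swept rapidly and repeatedly along one line (here 32
pixels at 100 nm spacing, 6.3 µs per pixel, one line every 0.473 ms).
Stacking the lines in time gives a *carpet*: a photon-count matrix whose
columns are positions along the line and whose rows are successive scan
lines. Each column is a fluorescence-fluctuation record sampled once per
line period; each pair of columns is a two-point experiment.

Two estimators extract transport information:

* the **autocorrelation function** (ACF) of one column,
  `G(τ) = ⟨δF(t) δF(t+τ)⟩ / (⟨F⟩_head ⟨F⟩_tail)`, whose amplitude is
  inversely proportional to the mean number of molecules in the focal
  volume and whose decay time reflects the local diffusion coefficient;
* the **pair correlation function** (pCF) of two columns a distance δr
  apart, the same estimator applied across the pair. Because the same
  molecule cannot be in two places at once, the pCF at separations beyond
  the PSF waist starts at or below zero (spatial anti-bunching) and rises
  to a maximum at the average time a molecule needs to travel δr. A
  diffusion barrier between the two pixels postpones that maximum; an
  impenetrable boundary removes it entirely.

The estimator is computed on a multi-tau grid: 32 unit-spaced lags at full
line resolution, then 16 lags per octave with factor-2 co-binning of both
channels. `scheme = "direct"` evaluates the identical estimator by
exhaustive summation and pins the fast path to < 1e-12. Head/tail
(symmetric) normalization is used because it halves the bias caused by
slow drifts of the mean intensity over a segment. Reported lag values are
`k·linePeriod + δr·pixelDwell`: the constant intra-line sampling offset
(≤ a few tenths of a microsecond per pixel of separation) is folded into
the lag axis rather than resolved as extra grid points. Negative
correlation values are preserved throughout — the anti-correlation dip is
the method's single-molecule signature, not an artifact to clip.

### Normalization conventions

The amplitude convention is γ = 1, i.e. fits report an *apparent* focal
occupancy `N = 1/G(0)` equal to concentration × Veff with
`Veff = π^{3/2} w0² wz`. Neither the diffusion coefficient nor any peak
position depends on this convention. The closed-form models are

```
ACF:  G(τ) = (1/N) (1 + 4Dτ/w0²)^-1 (1 + 4Dτ/wz²)^-1/2
pCF:  G(τ; δ) = ACF(τ) · exp(−δ² / (w0² + 4Dτ))
```

for a 3D Gaussian illumination profile `W(r)` with radial waist `w0` and
axial waist `wz` (`κ = wz/w0` defaults to 5, a typical confocal
elongation; only `w0` is usually calibrated, against a dye of known
`D = 300 µm²/s`). In the 2D limit the pCF maximum has the closed form
`τ_peak = (δ² − w0²)/(4D)` and its amplitude falls off exactly as `1/δ²`;
the 3D maximizer sits slightly earlier and is found numerically
(`peakTimeTheory()`). The mean-field pCF model is non-negative; the
negative short-lag dip of the *measured* estimator comes from
single-molecule occupancy exclusion, which a mean-concentration model
cannot carry. Fits (`fitACF()`, Levenberg–Marquardt on log-parameters,
convergence flagged explicitly, never silent) default to the lag range
`[linePeriod, maxLag/4]`: the longest quarter of the grid is dominated by
drift and estimator noise. Across-column scatter is used as
inverse-variance weights only when at least 8 columns contribute; a 2- or
3-sample variance estimate is too unstable to weight with.

## Reading out transit times

`detectPeak()` implements the transit readout: Gaussian smoothing over the
(log-spaced) lag bins (σ = 2 bins by default), argmax over a search window
`[tauMin, tauMax]` (default `tauMin = 2` line periods, which excludes the
shot-noise/anti-correlation region), and a significance gate. The
amplitude is the maximum's *topographic prominence* — its height above the
level the hump rises from, taken as the lower of the pre-peak minimum and
the early-segment median; that level is the anti-correlation dip for a
transit hump. Significance is prominence over a MAD noise scale from the
earliest segment, with `found = FALSE` below 3 (this rejects ≥ 95 % of
pure-noise curves, validated by Monte-Carlo in the test suite). Two
positions are reported: `tauPeak`, the smoothed argmax (the position of
the maximum), and `tauMean`, the log-lag centroid of the hump's above-baseline region
(the average position in time of the hump). For sharp intracompartment
humps the two coincide within a bin or two; for the decade-wide humps of
envelope-crossing curves the centroid is far more stable under noise and
is the recommended cross-compartment readout.

For compartment-wide cross-envelope readouts the protocol used by the
package's own validation is: average every spanning pair at 12, 16 and 20
pixel separations (`averageCurves(..., requireSameDelta = FALSE)`; the lag
grids differ only by microseconds), smooth with σ = 6 bins (the humps span
a decade), and search `[10 ms, 1.5 s]`. The lower bound is the
free-diffusion transit bound for ≥ 1.2 µm at cellular mobilities; the
upper bound brackets the slowest physiologically reported envelope delays
and keeps the argmax away from the very-long-lag region where the
estimator averages too few fluctuations to be trustworthy.

`transitMap()` classifies each origin column: `intra` (delay consistent
with the intracompartment reference), `barrier_delayed` (delay more than
10× the median intra delay — safely between intra scatter and the
40–100-fold slowdowns of envelope transport), `no_communication` (no
significant maximum — the impenetrable-gap signature), `unstable` (failed
stationarity QC). All thresholds are recorded on the object.

## The simulator

`simulateCarpet()` produces synthetic carpets from Brownian dynamics so
the whole pipeline can be validated against ground truth:

* molecules take Gaussian steps of std `√(2 D Δt)` per axis, one step per
  pixel dwell during the active scan and one lumped step over the retrace
  dead time — this resolves intra-line correlations at the microsecond
  scale without per-microsecond cost everywhere;
* the outer walls reflect (periodic wrap would teleport molecules across
  the barrier);
* photon counts are `Poisson(background + brightness · Σᵢ W(rᵢ − beam))`,
  with the PSF truncated beyond `3 w0` radially and `3 wz` axially
  (< 1e-7 relative error);
* one integer seed expands into independent streams for trajectories,
  translocation dwells and photon noise, so re-sampling photons cannot
  perturb trajectories; runs are bit-reproducible.

### The envelope model

The barrier is an infinitesimally thin plane. A step whose x-path crosses
it is transmitted with probability
`p = pCross · √(Δt/Δt_ref) · √(D_ref/D_side)` (reference: a pixel-dwell
step from the left compartment). The two scalings make the underlying
membrane permeability independent of the step size and preserve detailed
balance when the compartments have different diffusion coefficients —
without them, a passive barrier between D = 12.5 and 5.5 µm²/s
compartments would spuriously pump molecules toward the slow side, while
physically a passive envelope must relax to a homogeneous concentration
(as it does here: realized Keq → 1 in the tests). Because any per-attempt
probability is a numerical device, the barrier is characterized by an
observable instead: `calibratePermeability()` bisects `pCross` until the
mean first-crossing time from a stated start offset (brute-force
first-passage oracle, `meanCrossingTime()`, censored passages reported
separately and never averaged in) hits the requested value.

The carrier channel is a minimal capture-and-release mechanism: on a
rejected barrier contact from the source side, the molecule is captured
with probability `pActive`, held at the pore mouth, and released on the
far side after an exponential dwell (default mean 5 ms). This is not a
mechanistic pore model; it is the smallest mechanism that produces a fast,
directional transport component and an asymmetric steady state. With the
channel on (capture probability 0.5) the simulations settle at a
nuclear/cytoplasmic occupancy ratio of ~7, emergently close to the ~6.5
partition ratio typical of NLS-cargo in live cells.

`barrierThickness > 0` replaces the semi-permeable plane by an
impenetrable, fluorophore-free slab — the geometry of the two-adjacent-
cells control, where the scan line crosses the gap between cells.

### What the generator emulates, and what it does not

Default geometry and conditions: the standard 32 px × 100 nm scan; for
uniform (single-compartment) runs a box with 2 µm x-margins beyond the
scan and generous y/z extent; for barrier runs shallow compartments
(0.5 µm beyond the scan ends, box 4.1 × 3 × 12 µm) representing only the
envelope-proximal region of each compartment. Shallow compartments keep
the calibrated barrier *transmission-limited* — as a pore-limited envelope
is — rather than diffusion-limited; with deep compartments most of a
250 ms mean crossing time would be spent diffusing toward the envelope and
the pCF would read free-diffusion transit instead of barrier transit. The
large (mostly invisible) z-extent enlarges the total molecule pool, which
suppresses a finite-size artifact of closed boxes: with N molecules in
total, compartment occupancies are anti-correlated and every cross-
compartment curve rides on a baseline of order −1/N. The prominence-based
peak readout measures the hump from the level it rises from, which removes
the residual sensitivity to this baseline. Molecule numbers default to
about one per effective focal volume (single-molecule fluctuation
conditions); brightness defaults to 0.5 counts per molecule per dwell
(~80 kHz at the PSF center, a bright but attainable molecular brightness),
and the barrier experiments use 1.0 to keep the weak cross-envelope
correlation above shot noise within a few minutes of simulated
acquisition.

Known divergences from real recordings: no discrete pores (the envelope is
uniformly permeable, so the geometric dispersion caused by an unknown
line-to-pore distance is absent); no photobleaching, blinking or triplet
photophysics (drift appears only via the QC path); closed-box finite-size
correlations (see above) instead of an open cytoplasmic reservoir; and an
instantaneous passive transmission event rather than a pore dwell. Passing
tests therefore demonstrate the method's behavior under controlled
transport physics, not the full variability of live-cell data — in
particular, real cross-envelope peak *positions* vary with pore geometry
in ways the simulator deliberately does not model.

### Numerical choices

Simulation problem sizes used in the package's own validation: 6×10⁴ lines
for compartment-D recovery (a ~30 s segment), 2.2×10⁵ samples for PSF
calibration, 6×10⁵ lines for passive envelope crossing and 3×10⁵ for the
carrier-channel experiments — cross-envelope correlations are an order of
magnitude weaker than intracompartment ones and need the longer records;
well beyond the minimum record such weak correlations require.
Fits run to ftol 1e-12/ptol 1e-10 with a 500-iteration cap and an explicit
convergence flag. Bisection in `calibratePermeability()` works on log
pCross with a fixed per-evaluation RNG stream so the objective is a
deterministic monotone function; tolerance 10 % of the target. Degenerate
inputs are errors, not guesses: missing sidecar metadata, zero-mean
columns, counts above the 16-bit TIFF range, targets faster than free
diffusion. An all-zero column gets drift metric 0 and an `empty` flag,
never NaN.

### Open design points, resolved

* Column indices are 1-based and inclusive throughout (idiomatic R);
  column *i* sits at `(i−1)·pixelSize` µm. Acquisitions that were recorded
  with 1-based column numbering therefore map directly.
* The envelope position within a drifting segment is not re-tracked; the
  stationarity QC flags the affected columns and re-segmentation is left
  to the user.
* A second slow diffusive species (the slow cytoplasmic component seen in
  some records) is available in analysis as the explicit two-component
  model (`modelId = "3d_2comp"`), never auto-selected; the generator does
  not claim a mechanism for it.
* The stationarity threshold (0.2 relative windowed drift) is calibrated
  to pass Poisson-stationary records at ensemble intensities while
  rejecting bleaching-scale drifts; at single-molecule intensities with
  few windows the metric also reflects occupancy fluctuations, so QC
  windows should cover many correlation times.

## Worked example

```{r example}
library(carpetFCS)

# a nuclear-like compartment: free diffusion at 12.5 um^2/s
cfg <- simConfig(nLines = 60000, dLeft = 12.5, seed = 11)
res <- simulateCarpet(cfg)
cpt <- carpet(res)

# per-column ACF carpet, averaged, fitted
fit <- fitACF(averageCurves(pcfCarpet(cpt, 0)), psf = cfg@psf)
fit

# transit delay over 0.4 um
pk <- detectPeak(averageCurves(pcfCarpet(cpt, 4L)))
c(measured_ms = pk$tauPeak * 1e3,
  theory_ms = peakTimeTheory(12.5, 0.4, cfg@psf)$tauPeak * 1e3)
```

A two-compartment experiment with a calibrated envelope and the
direction-resolved transit analysis is shown in the README; the
`scripts/acceptance.R` entry point reruns those experiments end to end.
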