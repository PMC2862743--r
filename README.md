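# carpetFCS

Pair-correlation-function (pCF) analysis of confocal line-scan
fluorescence *carpets*, with a Brownian-dynamics simulator of
nucleocytoplasmic transport for end-to-end validation.

## The problem

A laser spot swept rapidly along a single line through a cell samples
every position on that line thousands of times per second. Stacking the
scan lines in time gives a carpet: columns are positions, rows are time.
The autocorrelation of one column is a classic FCS experiment — its
amplitude gives the number of molecules in the focal volume (G(0) = 1/N)
and its decay the local diffusion coefficient. The *pair* correlation of
two columns a distance δr apart follows single molecules: because one
molecule cannot be in two places at once, G(τ) starts at or below zero and
rises to a maximum at the average time a molecule needs to travel δr,

> ACF: G(τ) = (1/N)·(1 + 4Dτ/w0²)⁻¹·(1 + 4Dτ/wz²)^(−1/2)
> pCF: G(τ; δr) = ACF(τ)·exp(−δr²/(w0² + 4Dτ))

for a Gaussian focal volume with waists w0 (radial) and wz (axial). A
diffusion barrier between the two pixels — the nuclear envelope — delays
that maximum by one to two orders of magnitude; an impenetrable boundary
(the gap between adjacent cells) removes it entirely. Choosing the
orientation of the correlation (column A → B vs B → A) selects the
transport direction, which separates passive nucleus→cytoplasm shuttling
from fast carrier-mediated cytoplasm→nucleus import.

The package is for experimentalists and methods developers who want to
run, test or extend this analysis without microscope data: it provides
the carpet data model and I/O (TIFF/CSV/raw + JSON sidecar), a multi-tau
correlator with an exhaustive-summation oracle, diffusion-model fitting
and PSF calibration, transit-delay maps with barrier/no-communication
classification, and a two-compartment Brownian-dynamics simulator
(semi-permeable envelope, optional directional carrier channel, Gaussian
PSF scanning, Poisson photon detection) with first-passage oracles and
permeability calibration.

## Worked example

Simulate a nuclear-like compartment (free diffusion at 12.5 µm²/s, the
standard 32-pixel / 6.3 µs / 0.473 ms scan, ~1 molecule per focal volume),
fit the averaged ACF carpet, and read a 0.4 µm transit delay:

```r
library(carpetFCS)

cfg <- simConfig(nLines = 60000, dLeft = 12.5, seed = 21)
res <- simulateCarpet(cfg)
cpt <- carpet(res)

fitACF(averageCurves(pcfCarpet(cpt, 0)), psf = cfg@psf)
#> DiffusionFit (3d_1comp)
#>   D = 12.92 +/- 0.52 um^2/s, N = 1.213, G0 = 0.8243
#>   fit over [0.000473, 0.969] s, 128 lags, RSS = 10.1

pk <- detectPeak(averageCurves(pcfCarpet(cpt, 4L)))
pk$tauPeak * 1e3                                   # measured delay, ms
#> [1] 2.3902
peakTimeTheory(12.5, 0.4, cfg@psf)$tauPeak * 1e3   # model prediction, ms
#> [1] 1.808516
```

The fitted D recovers the 12.5 µm²/s ground truth (seed-to-seed scatter
at this record length is roughly ±10 %), N sits near the one-molecule
occupancy the configuration targets, and the pCF(4) transit delay lands
within a lag bin of the closed-form prediction.

A two-compartment transport experiment calibrates the envelope to a
chosen mean crossing time, then reads the cross-envelope delay:

```r
cfg <- simConfig(nLines = 600000, dLeft = 12.5, dRight = 5.5,
                 barrierX = "center", brightness = 1, box = c(4.1, 3, 12),
                 nParticles = 170, seed = 42)
cal <- calibratePermeability(0.25, cfg, startOffset = 0.5, seed = 43)
cfg@pCross <- cal$pCross          # mean first-crossing time now ~250 ms
cpt <- carpet(simulateCarpet(cfg))

# whole nuclear compartment cross-correlated into the cytoplasm
crossing <- averageCurves(pcfCarpet(cpt, 16L, columns = 1:16))
detectPeak(crossing, tauMin = 0.01, tauMax = 1.5, smoothingBins = 6)$tauMean
```

which returns a delay of one to several hundred milliseconds — an order
of magnitude above the intracompartment delay over the same distance —
while the same analysis on a simulated cell-gap control finds no
significant maximum at all.
`transitMap()` and `directionalAnalysis()` turn these readouts into
per-column classifications (intra / barrier_delayed / no_communication /
unstable) and forward-vs-backward delay asymmetries.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/pcftool.R",
                          package = "carpetFCS"))')" \
    simulate --config sim.yaml --out-prefix run/sim
```

with `correlate` and `analyze` subcommands operating on saved carpets;
every command writes a manifest recording inputs, parameters and seed.

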