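---
title: "Models and methods behind fretquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

fretquant quantifies experiments made with a genetically encoded cAMP
biosensor read out by FRET between a cerulean donor and a citrine acceptor.
This vignette is the package's own account of the models it fits, the
parameters that matter, the numerical choices made where the design was
open, and what the synthetic-data generators do and do not emulate.

## Equilibrium binding with ligand depletion

In cuvette titrations the sensor is present at micromolar concentration
while its dissociation constant is tens of nanomolar. Free and total ligand
therefore differ substantially and the familiar hyperbolic isotherm
$\theta = L/(L + K_D)$ is wrong in this regime. `bound_fraction()` works
with *total* concentrations: the bound complex $B$ is the physical root of

$$B^2 - (E_T + L_T + K_D)\,B + E_T L_T = 0,$$

evaluated in the cancellation-free form
$B = 2E_T L_T/(S + \sqrt{S^2 - 4E_T L_T})$, $S = E_T + L_T + K_D$. The
measured FRET change is modeled as
$\Delta F(L_T) = \Delta F_0 + \Delta F_{max}\,\theta$, and `fit_binding()`
estimates $K_D$, $\Delta F_{max}$ and optionally $\Delta F_0$ by unweighted
least squares with the protein concentration fixed at its known value.
$K_D$ is optimized on a log scale, which keeps it positive and makes the
standard error (delta method) meaningful across the decade-spanning
designs. Both floated and zero-fixed baselines are supported
(`float_df0`); the default floats it, since baseline correction upstream is
never perfect.

One practical caveat surfaced by simulation: at 1 µM sensor and
$K_D \approx 66$ nM the titration is depletion-dominated and a 12-point
curve leaves $K_D$ weakly identified under even 2% noise (the estimate is
visibly skewed). The recovery tests therefore use a 24-point titration for
the noise study; noiseless recovery is exact for either design.

Cellular agonist curves act upstream of the sensed second messenger, so
they are fitted with the four-parameter Hill model
$y = bottom + (top-bottom)/(1 + (EC_{50}/x)^{n_H})$ (`fit_hill()`), with
the slope optionally fixed (the EC50 recovery study fixes $n_H = 1$, as no
slope is reported for the agonist used).

## Stopped-flow kinetics

Rapid-mixing traces follow the one-step scheme
$E + L \rightleftharpoons EL$ with rates $k_{on}$, $k_{off}$:

$$\frac{d[EL]}{dt} = k_{on}(E_T - [EL])(L_T - [EL]) - k_{off}[EL],
\qquad [EL](0) = 0.$$

`simulate_complex()` integrates this with `deSolve::lsoda` at absolute
tolerance $10^{-12}$ µM and relative $10^{-9}$ — the complex concentration
is nanomolar at the lowest doses, so the absolute tolerance matters. The
same ODE has a closed-form Riccati solution with constant coefficients;
that form is implemented separately and used only as an independent test
oracle against the integrator. `global_fit_kinetics()` fits one
$(k_{on}, k_{off}, \alpha, \text{offset})$ set jointly across all traces
through the signal map $s(t) = \text{offset} + \alpha\,[EL](t)$, rates on
the log scale, Levenberg–Marquardt underneath. Trace sets whose signals
carry no relaxation (already equilibrated) are rejected as unidentifiable
rather than fitted.

The listed mixing concentrations are treated as final in-cuvette values;
simulator and fitter share the convention, so parameter recovery is
convention-independent. No dead-time correction is applied (none is
described for the instrument); the diagnostic pseudo-first-order rate
$k_{obs} = k_{on}L + k_{off}$ is exposed via `observed_rate()`.

A detail worth recording: the time to 90% of equilibrium is *not*
monotone in ligand across doses that straddle the sensor concentration —
the slow relaxation eigenvalue $k_{on}\sqrt{S^2 - 4E_TL_T}$ has a minimum
near $L_T \approx E_T$ when $K_D$ is small. The property suite asserts the
speed-up with ligand only for $L_T \ge E_T$, where it genuinely holds.

## Ratiometric processing

The dual-emission readout is
$R = (\text{donor} - \beta\,\text{acceptor})/\text{acceptor}$ with the
bleed-through coefficient $\beta = 0.69$ for the dual-view imaging
channels. The formula is implemented exactly as used with the instrument
calibration, even though a citrine-into-cerulean bleed-through of that
size is spectrally unusual; $\beta$ is configurable per dataset, and
spectrofluorometer ratios default to $\beta = 0$ (no explicit
bleed-through is calibrated for cuvette data). Traces are normalized to a
pre-stimulus baseline window so changes read directly as fractional
increases; drift is corrected by regressing a buffer-only control on time
and subtracting the fitted slope. Spectra are read at fixed wavelengths
(471 nm donor, 529 nm acceptor) by nearest-grid lookup — 1-nm grids are
expected, so interpolation would add nothing. Acceptor-photobleaching
dequenching is quantified as the percent increase of background-corrected
donor emission.

## Null-point calibration

The basal free concentration (cAMP, or pH with a buffer titration) is the
added external concentration at which permeabilization produces no ratio
change. `nullpoint_calibrate()` regresses the permeabilized-cell titration
ratios on concentration by ordinary least squares and solves
$\text{regression}(c) = R_{basal}$. Because the underlying
ratio–concentration relation is an occupancy isotherm, the regression is
only *locally* linear: over a 0–100 nM titration with $K_D = 73$ nM a
global line crosses the baseline ~30% away from the true null point purely
from curvature. The `range` argument therefore selects the titration
points entering the regression, and the recommended practice (used by the
package's own acceptance computation) is to regress over the points
bracketing the basal ratio — with the 25–75 nM bracket the recovered basal
concentration is within 6% of truth. The titration span itself should stay
within roughly $3 K_D$. Extrapolated crossings are flagged, zero slopes
are an error, and `free_from_occupancy()` converts a calibrated occupancy
into a free concentration by inverting the dilute isotherm
$c = K_D\theta/(1-\theta)$ (inside a cell the sensor does not deplete the
ligand pool it reports on).

## TCSPC lifetime fitting and FLIM maps

Photon-arrival histograms are modeled as the measured IRF convolved with a
bi-exponential, $a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}$, plus a floated
constant background, fitted by iterative reconvolution with Poisson
(Neyman) weights, $\mathrm{var} = \max(y, 1)$ — the chi-square weighting
convention is not documented for the original analysis software, so Neyman
was chosen and is stated here. Label switching is resolved by enforcing
$\tau_1 \ge \tau_2$. The reported summary is the amplitude-weighted mean
lifetime $\tau_{wm} = (a_1\tau_1 + a_2\tau_2)/(a_1 + a_2)$, which stays
well determined even when the two components are barely separable (the
mono-exponential limit). The default grid is 12.5 ns over 256 bins (80 MHz
excitation); synthetic IRFs are Gaussian with $\sigma$ = 0.1 ns by default
(the measured-IRF shape is not published), and any measured IRF histogram
can be supplied instead.

FLIM maps follow the standard recipe: pixels whose own total count is
below 20 are masked; each retained pixel's decay is the *sum* of its
15×15 neighborhood (photon pooling, edge-truncated) before fitting —
pooling photons, not averaging fitted lifetimes, is what "binning to
increase photon count" means. The map stays aligned to the input grid.
Tests use smaller frames and bin sizes (down to 3×3 on 5×5–15×15 images)
purely as a problem-size choice; the rules under test are identical.

## Dual-view flagellar analysis

The two emission channels are registered per frame by FFT
cross-correlation with parabolic sub-pixel peak interpolation (integer
shifts are recovered exactly, sub-pixel shifts to better than 0.1 px on
smooth images); frames whose normalized correlation peak falls below a
quality floor are flagged rather than silently kept. The flagellum is
tracked per frame: Otsu threshold, largest connected component, Zhang–Suen
skeletonization, longest geodesic path through the skeleton (double BFS),
orientation from the brighter head/droplet end, then a smoothing spline
resampled at 0.5 µm arc-length steps. A reference-centerline mode (track
once, reuse) exists as a config option for slowly moving cells, since the
original processing does not state which variant was used; per-frame
tracking is the default. Channel intensities are sampled along the
centerline by bilinear interpolation, with out-of-bounds points masked as
`NA`, never zero.

Region kinetics use the cytoplasmic droplet as the landmark separating
midpiece (head side) from principal piece (tip side): 20 µm windows are
placed 5 µm from the droplet on each side (configurable within the 5–10 µm
convention), the bleed-corrected ratio is averaged within each window per
frame, each trace is normalized to its pre-stimulus baseline, and the rise
is fitted with the four-parameter logistic
$y(t) = A_2 + (A_1 - A_2)/(1 + (t/x_0)^p)$ — the standard "logistic"
family of the curve-fitting tool named by the original analysis, which
does not print the formula. With the droplet at 22 µm arc length the
midpiece window necessarily truncates at the head end; the package warns
(`fq_shortened_window`) instead of failing. Flat traces return a
degenerate plateau-only fit, never a spurious half-rise time.
`average_kinetics()` evaluates each cell's fitted curve on a common grid
and returns pointwise mean ± SD per region.

## Synthetic data: what it emulates, and what it does not

Every generator draws from the forward model of the stage that consumes
it, is deterministic under a fixed seed, and returns its ground truth as
an attribute. Defaults encode the study conditions: dose-response grids
spanning 0.1–30 × $K_D$; the six-dose stopped-flow series (0.5, 1, 1.6,
2.5, 5, 10 µM against 2.5 µM sensor, 200 Hz); occupancy-derived null-point
titrations; bi-exponential decays at 80 MHz timing with Poisson counting
noise; and a dual-view movie (nominally 200×600 px at 0.25 µm/px, 600
frames at 1 Hz) of a ~60 µm flagellum with the droplet at 22 µm, a 26%
midpiece and 22% principal-piece plateau, half-rise times of 120 s and
60 s, $\beta = 0.69$ mixed into the donor channel, and Poisson + Gaussian
camera noise. The movie flagellum is built in arc-length parameterization
(tangent-angle traveling wave), so its ground-truth length is exact by
construction; intensities are splatted bilinearly and blurred with a
Gaussian of 1.2 px.

The generators deliberately do not model: optical PSF beyond that single
Gaussian blur, photobleaching over the movie, beat-frequency waveform
realism, sensor diffusion, or any mechanism linking stimulus to cAMP —
the logistic time courses are imposed, not produced by a signaling model.
Passing recovery tests therefore demonstrates that the *analysis* is
correct and unbiased under the assumed noise structure, not that real
recordings satisfy those assumptions.

## Problem sizes and tolerances used by the test suite

Simulations are sized for a single CPU: 200-replicate Monte-Carlo checks
for the regression-based estimators, 20 replicates for the global kinetic
fit (each fit integrates six ODE traces per iteration), FLIM maps up to
16×12 pixels at 128 time bins, and a 20-movie cohort at 80×140 px / 360
frames for the end-to-end dual-view pipeline, where plateau recovery is
assessed at cohort level (the single-movie spread is about 1.5 percentage
points at the chosen photon budget). Integrator and optimizer tolerances
are stated at their call sites; recovery tolerances in the tests are 0.5%
on noiseless refits, 2% for lifetime summaries under Poisson noise at
$10^6$ counts, and 10% for null-point and half-rise recoveries where
local-linearity or photon noise dominates.
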