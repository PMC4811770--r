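# fretquant

Quantification toolkit for genetically encoded FRET biosensor experiments,
built around a cAMP sensor read out by cerulean/citrine emission ratios and
donor lifetimes. It targets the full measurement stack such a sensor goes
through — cuvette, cell population, single cell, and the beating sperm
flagellum — for researchers who need the numbers behind each readout:

- **Equilibrium binding with ligand depletion.** Sensor concentrations are
  micromolar while K_D is tens of nanomolar, so `fit_binding()` fits the
  mass-action quadratic in *total* concentrations,
  B² − (E_T + L_T + K_D)B + E_T·L_T = 0, rather than the dilute hyperbola.
  `fit_hill()` covers cellular agonist curves
  (y = bottom + (top−bottom)/(1+(EC₅₀/x)^n_H)).
- **Stopped-flow kinetics.** `simulate_complex()` integrates
  d[EL]/dt = k_on(E_T−[EL])(L_T−[EL]) − k_off[EL]; `global_fit_kinetics()`
  fits one (k_on, k_off) pair jointly across all ligand concentrations.
- **Null-point calibration.** `nullpoint_calibrate()` finds the added
  external concentration at which permeabilization changes nothing —
  the basal free cAMP or intracellular pH — by local linear regression.
- **TCSPC / FLIM.** `fit_decay_reconvolution()` fits IRF-convolved
  bi-exponential decays with Poisson weights; `flim_map()` applies the
  20-count pixel mask and 15×15 photon pooling to produce
  weighted-mean-lifetime (τ_wm) maps.
- **Ratiometric processing.** Bleed-through-corrected ratio
  R = (donor − β·acceptor)/acceptor (β = 0.69 for the dual-view channels),
  baseline normalization, drift correction, acceptor-photobleaching
  dequenching.
- **Dual-view flagellar analysis.** Channel registration (sub-pixel FFT
  cross-correlation), centerline tracking (Otsu → skeleton → longest path →
  spline), arc-length sampling, 20-µm midpiece / principal-piece windows
  around the cytoplasmic droplet, and logistic response kinetics
  y(t) = A₂ + (A₁−A₂)/(1+(t/x₀)^p).
- **Synthetic data.** Seeded generators (`gen_dose_response`,
  `gen_stopped_flow`, `gen_nullpoint`, `simulate_tcspc`,
  `gen_flagellum_movie`) emulate every input with ground truth attached, so
  each stage has an exact recovery target.

## Worked example

Fit a noisy synthetic titration (true K_D 66 nM, 1 µM sensor, 0.5% noise),
a six-dose stopped-flow set, and a null-point experiment:

```r
library(fretquant)

grid <- exp(seq(log(6.6), log(1980), length.out = 24))
curve <- gen_dose_response(binding_params(kd_nM = 66, et_uM = 1,
                                          df_max = 0.45, df0 = 0.05),
                           grid = grid, noise_sd = 0.005, seed = 42)
fit_binding(curve, et_uM = 1)
#> <binding_fit>
#>   kd_nM      76.5715  (SE 9)
#>   df_max     0.454073  (SE 0.00586)
#>   df0        0.0509134  (SE 0.000754)
#>   RSS: 0.000164918
#>   converged

ts <- gen_stopped_flow(kinetic_params(2.6e7, 12.8, alpha = 0.4, offset = 1),
                       noise_sd = 0.01, seed = 42)
global_fit_kinetics(ts)
#> <kinetic_fit>
#>   k_on       2.55874e+07  (SE 2.77e+05)
#>   k_off      12.6481  (SE 0.174)
#>   alpha      0.399937  (SE 0.000608)
#>   offset     1.00039  (SE 0.000984)
#>   RSS: 0.0517673
#>   converged

cal <- nullpoint_calibrate(gen_nullpoint(35, 73,
                                         titration_nM = seq(0, 100, 25)),
                           range = c(25, 75))
cal
#> <nullpoint_cal>
#>   basal free concentration (nM): 37.01
#>   regression slope 0.00302, intercept 0.8827, R^2 0.9864
```

The binding fit reads the dissociation constant off a depletion-dominated
titration (truth 66 nM recovered as 77 ± 9 nM at this noise level — K_D is
the hard parameter in this regime; amplitude and baseline are tight). The
kinetic fit recovers the association/dissociation rates within ~2% at 1%
trace noise. The null-point crossing lands at 37 nM for a 35 nM truth; the
~6% offset is the local-linearity error of regressing a curved occupancy
readout, which is why the regression runs over the bracketing titration
points only.

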