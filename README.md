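# dualslope

Self-calibrating (dual-slope) broadband diffuse reflectance spectroscopy:
simulation, extinction extraction, chromophore inversion, and perturbation
robustness analysis.

## The problem

Diffuse reflectance spectroscopy (DRS) delivers broadband light into tissue
through a fiber and measures the back-scattered spectrum at a known
source–detector distance (SDD). The decay of the detected intensity with
distance is governed by the effective extinction coefficient of diffuse
light,

    mu_eff(lambda) = sqrt( 3 * mu_a * (mu_a + mu_s') ),

from which skin chromophore concentrations (oxy-/deoxyhemoglobin, water,
melanin, "dry matter") and reduced-scattering parameters can be
reconstructed. The catch is instrumental: every source and detection
channel carries its own wavelength-dependent transfer characteristic
(fiber losses, bending, connector variation, probe–tissue coupling), and a
broadband 460–1030 nm system is especially exposed because those transfer
functions are spectrally structured.

With a symmetric probe carrying two source fibers (S1, S2) and two
detection fibers (D1, D2) — short SDD `r_S` = 2 mm, long SDD `r_L` = 4 mm,
so that `r11 = r22 = r_S`, `r12 = r21 = r_L` — three estimators of
`mu_eff` are available from the four measured spectra `I_kj` (source k,
detector j, exposure `E_kj`):

- **single-slope**, one source and both detectors:

      mu_eff = 1/(r_L - r_S) * ln( I11/I12 * E12/E11 * r_S/r_L )     (S1D1D2)
      mu_eff = 1/(r_L - r_S) * ln( I22/I21 * E21/E22 * r_S/r_L )     (S2D1D2)

  These cancel the source chain and spectrometer sensitivity but silently
  assume the two detector transients are equal.

- **dual-slope / self-calibrating**, all four measurements:

      mu_eff = 1/(2 (r_L - r_S)) *
               ln( (I11 I22)/(I12 I21) * (E12 E21)/(E11 E22) * r_S^2/r_L^2 )

  Every per-channel multiplicative transfer function — source *and*
  detector — cancels exactly; algebraically this estimator is the mean of
  the two single slopes.

This package implements that whole computational pipeline as reusable,
tested code: a synthetic four-channel instrument (diffusion-theory forward
model, per-channel transfer chains, exposure times, dark signal, shot
noise, heartbeat-period averaging, and a catalog of ten instrumental
perturbations), the three extraction formulas, a bounded least-squares
inversion of `mu_eff` into the tissue parameter vector
`K = [C_blood, StO2, C_water, mua_dry, a, b, f]` with
`mu_a = C_water*mua_water + C_mel*mua_mel +
C_blood*(StO2*mua_oxy + (1-StO2)*mua_deoxy) + mua_dry` and the
Rayleigh–Mie power law
`mu_s'(lambda) = a*(f*(lambda/500)^-4 + (1-f)*(lambda/500)^-b)`, and the
robustness statistics (RMSE deviation of perturbed extinction spectra from
the unperturbed baseline; relative deviations of reconstructed
parameters).

## Worked example

Simulate a palm measurement with a strong detection-channel loss (a 105 um
fiber inserted into channel D1, transmittance 0.2756), then extract and
invert:

```r
library(dualslope)

basis      <- load_chromophore_basis()
geometry   <- probe_geometry()                 # r_S = 2 mm, r_L = 4 mm
instrument <- default_instrument(default_grid(), basis, geometry)

ms <- simulate_measurement(palm_preset(), basis, instrument, geometry,
                           perturbations = list(make_perturbation("D1L")),
                           noise = TRUE, seed = 7)
ms
#> <measurement_set> D1L, 571 wavelengths 460-1030 nm, E = 15/80/80/15 ms,
#>   n_avg = 67/12/12/67

truth <- model_extinction(palm_preset(), basis)
for (ext in list(dual_slope(ms), single_slope(ms, 1)))
  cat(ext$method, "RMS error:",
      sqrt(mean((ext$mu_eff$values - truth$values)^2, na.rm = TRUE)),
      "mm^-1\n")
#> S1S2D1D2 RMS error: 0.0012 mm^-1
#> S1D1D2   RMS error: 0.6368 mm^-1
```

The dual-slope spectrum is essentially untouched by the perturbation
(residual 0.0012 mm^-1 is the shot-noise floor), while the single-slope
spectrum is shifted by `ln(0.2756)/2 mm = -0.64 mm^-1`. Fitting the
dual-slope spectrum recovers the generating palm parameters:

```r
fit_extinction(dual_slope(ms), basis, fit_config(seed = 7))
#> <fit_result> S1S2D1D2: objective 0.0008287 mm^-2, converged, start 1,
#>   939 evaluations
#>  C_blood     StO2  C_water  mua_dry        a        b        f    C_mel
#> 0.002008 0.798317 0.404656 0.015244 1.994184 0.517142 0.146517 0.005000
```

(generating values: 0.002, 0.8, 0.4, 0.015, 2, 0.5, 0.15, with C_mel held
at 0.005). The full study — six unperturbed baselines plus three repeats
for each of the ten cataloged perturbations, with extraction by all three
methods and inversion of every dual-slope spectrum — runs via
`run_study(study_config(seed = 7))` in a few seconds and prints the
per-perturbation deviation table and the class-averaged parameter
deviations.

## Scope notes

The embedded chromophore tables are synthetic parametric reconstructions
of the standard compiled spectra (see `data-raw/make_chromophore_tables.R`
and the methods vignette); they are validated at load against the
published peak wavelengths (oxyhemoglobin 576 nm, deoxyhemoglobin 756 nm,
water 975 nm). The forward model is the infinite-medium diffusion Green's
function: boundaries, layered skin, and Monte-Carlo transport are out of
scope, as are hardware control and frequency-domain methods.
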