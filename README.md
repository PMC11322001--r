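# cytodroplet

Quantitative image and trajectory analysis for synthetic cytoskeletons —
peptide and peptide–DNA filament networks assembled in bulk or confined in
cell-sized water-in-oil droplets — as imaged by multi-channel confocal
time-lapse microscopy. The package is aimed at experimentalists who need
reproducible, scriptable versions of the measurements this system calls for:

- **Filament mechanics.** Bending stiffness κ from thermal shape
  fluctuations. A filament backbone is decomposed into free-end bending
  eigenmodes y_q(s) (wavenumber q = α_k/L); equipartition fixes each
  amplitude variance, var(a_q) = k_B·T/(κ·q⁴), so a fixed-slope fit of
  var(a_q) against q yields κ and the persistence length L_p = κ/(k_B·T).
  Amplitudes are projected from tangent angles, a_q = −∫ θ(s) ỹ_q(s) ds.
- **Bundle/tactoid morphometry.** Segmentation of condensed bundles;
  length, width (2 × mean skeleton distance transform), aspect ratio,
  thin/large classification (width < 1 μm), intensity line scans, the
  power-law fit of aspect ratio versus crosslinker mole fraction, and a
  structure-tensor alignment fraction.
- **Droplet shape.** Sphericity D_in/D_out from the maximum inscribed and
  minimum circumscribed circles (spherical: D_in/D_out > 0.8), solidity
  (area ÷ convex hull), local-curvature profiles κ(s)/κ₀ by sliding-window
  circle fits, and the sphericity-versus-size threshold fit.
- **Spatial statistics.** Radial probability profiles P(r/R) (circular
  averages of binarized equatorial slices), temporal cross-correlation of
  binarized projections, and the cortex contour correlation C(s) with its
  correlation length ξ_c (1/e crossing).
- **Particle dynamics.** Detection linking, time-averaged MSD, diffusive vs
  trapped classification, diffusion coefficients from MSD = 4Dτ + offset,
  and the Stokes–Einstein reference D = k_B·T/(3πηd).
- **Intensity kinetics.** Acridine-orange two-channel unmixing
  (I_green − β·I_red with the peptide bleed-through ratio β), flat-field and
  photobleach correction, cortex release curves and single-exponential decay
  fits I(t) = I∞ + (I0 − I∞)·e^(−kt).
- **Synthetic data.** Generators for every input — equipartition-sampled
  filaments, rendered scenes with ground-truth tables, Brownian/caged
  trajectories, release series, illumination fields — so each stage is
  testable by parameter recovery.

Units are μm, s, pN throughout (k_B·T = 4.045 × 10⁻³ pN·μm at 293 K).

## Worked example

Recover a bending stiffness from simulated thermal fluctuations, then
measure a droplet:

```r
library(cytodroplet)

truth <- filament_truth(L = 6, kappa = 0.04, temperature = 293, frames = 500)
fil    <- gen_fluctuating_filament(truth, seed = 7)
modes  <- backbone_spectra(fil$backbones, k_max = 4)
estimate_kappa(modes, temperature = 293)
#> <stiffness_estimate> kappa = 0.04005 pN um^2, L_p = 9.901 um (500 frames, modes 1,2,3,4)
#>   freely fitted exponent: -3.941 (fixed at -4 in the fit)
```

The generator drew mode amplitudes at κ = 0.04 pN·μm²; the tangent-angle
pipeline re-estimates κ = 0.0400 pN·μm² (persistence length ≈ 9.9 μm), and
the freely fitted exponent ≈ −4 confirms the thermal q⁻⁴ spectrum.

```r
tracks <- gen_trajectories(kinetics_truth(D_free = 0.31, cage_radius = 0.3),
                           n_particles = 500, n_steps = 100, dt = 1,
                           trapped_fraction = 0.4, seed = 11)
res <- analyze_tracks(tracks, dt = 1)
res$trapped_fraction          #> 0.4
res$mean_D_diffusive          #> 0.3019  (um^2/s; generated at 0.31)
stokes_einstein(1, 293.15, 1) #> 0.4294  (1-um sphere in water at 20 C)
```

A thin command-line wrapper for the most tool-like entry points lives in
`inst/cli/cytodroplet.R` (`stiffness`, `tracks`, `simulate`).

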