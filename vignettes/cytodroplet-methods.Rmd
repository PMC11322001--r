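---
title: "Models and methods behind cytodroplet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytodroplet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodroplet)
```

cytodroplet quantifies fluorescence-microscopy data of synthetic
cytoskeletons: semiflexible peptide filaments, DNA-crosslinked bundles and
tactoids, and their organization inside cell-sized water-in-oil droplets.
This vignette is the package's account of the underlying models, the
defaults that matter, and the numerical choices — including which features
of real data the synthetic generators do and do not emulate.

All lengths are in μm, times in s, forces in pN, so bending stiffness comes
out in pN·μm², diffusion coefficients in μm²/s, and the thermal energy is
`kBT(293)` = 4.045 × 10⁻³ pN·μm.

## Bending stiffness from shape fluctuations

A freely fluctuating, inextensible, semiflexible filament of contour length
$L$ is described by its transverse deflection $u(s,t)$ about a straight
baseline, expanded in the bending eigenmodes of a free–free elastic rod:

$$u(s,t) = \sum_q a_q(t)\, y_q(s), \qquad q = \alpha_k / L .$$

The eigenfunctions are the classic cosh/cos (odd $k$, symmetric) and
sinh/sin (even $k$, antisymmetric) free-end beam shapes, normalized by
$1/\sqrt{L}$ so that $\int_0^L y_q^2\,ds = 1$. Equipartition assigns each
mode the variance

$$\mathrm{var}(a_q) = \frac{k_B T}{\kappa\, q^4},$$

which is what `estimate_kappa()` inverts: per-mode sample variances are fit
in log–log with the exponent *fixed* at −4 (intercept-only least squares),
because with a handful of modes a freely fitted exponent is mostly noise;
the freely fitted exponent is still reported as a diagnostic of whether the
spectrum is thermal.

**Eigenvalue convention.** The free-end eigenvalue condition is
$\tan(\alpha/2) + \tanh(\alpha/2) = 0$ for odd modes and
$\tan(\alpha/2) - \tanh(\alpha/2) = 0$ for even modes, with roots
$\alpha_k \approx (k + \tfrac12)\pi$ (4.7300, 7.8532, 10.9956, …). Only the
exact roots make the printed eigenfunctions orthonormal — with
$(k+\tfrac12)\pi$ the $k=1$ normalization is off by 6 × 10⁻³ and odd–odd
cross-terms reach 5 × 10⁻⁴, which the test suite's quadrature oracle
rejects. `mode_alpha()` therefore defaults to the exact roots
(`"exact"`); `"half_integer_pi"` and the literal `"printed"` $k+\tfrac12$
are available for comparison with sources that quote those forms.

**Tangent-angle projection.** Amplitudes are measured from the local
tangent angle $\theta(s_i) = \mathrm{atan2}(y_{i+1}-y_i,\,x_{i+1}-x_i)$ via
integration by parts, $a_q = -\int \theta(s)\,\tilde y_q(s)\,ds$
(trapezoid rule), where $\tilde y_q$ is the antiderivative of $y_q$. Two
details make this projection exact rather than approximate:

1. The even-mode antiderivative must carry a **minus** sign on its cos
   term, $\tilde y_q \propto \cosh/\sinh(\alpha/2) - \cos/\sin(\alpha/2)$
   (the derivative of cos is −sin). At the exact eigenvalues, $\tilde y_q$
   then vanishes at both filament ends for every mode, so the boundary term
   of the integration by parts vanishes identically. With the sign flipped,
   even-mode amplitudes come back at −1.76× their true value.
2. The per-frame mean tangent angle is subtracted before projecting. Since
   $\int \tilde y_q\,ds = 0$ for every mode, this changes nothing for an
   ideal frame but removes rigid-body rotation exactly, making the κ
   estimate invariant under rotation and translation of the backbones.

The small-slope assumption $\partial u/\partial s \approx \theta$ is
monitored: `mode_amplitudes()` warns when the tangent excursion exceeds
0.35 rad. Frames are treated as statistically independent; no
correlation-time correction is applied.

**What the generator emulates.** `gen_fluctuating_filament()` draws each
$a_q$ from its equipartition law and builds the backbone by integrating the
tangent field $\theta(s) = \sum_q a_q y_q'(s)$, i.e.
$x(s) = \int \cos\theta$, $y(s) = \int \sin\theta$. This makes the filament
exactly inextensible (contour length $L$ by construction) and agrees with
"baseline plus deflection" to leading order. The alternative — adding
$u(s)$ to a straight baseline and rescaling the arclength — shrinks mode
amplitudes by 10–15 % at the default conditions (κ = 0.04 pN·μm², L = 6 μm,
hence $L/L_p \approx 0.6$) and would make recovery systematically biased;
with the tangent construction the κ estimate is unbiased to < 1 % over
seeds. The generator does not emulate localization noise, frame-to-frame
correlation, out-of-plane bending, or backbone-extraction artifacts; κ
recovery on synthetic data is therefore a best case, and real-data
estimates inherit whatever noise the backbone tracing adds.

Defaults: `k_max = 4` (higher modes of a ~6 μm filament fall below typical
localization noise), 100 backbone points per frame, temperature 293 K.

## Scene rendering and preprocessing

`render_scene()` rasterizes disks, shells, rectangles, spindle-shaped
tactoids (half-width profile $\tfrac{W}{2}\sin(\pi(u/L + \tfrac12))$, i.e.
pointed tips) and filament polylines with an anti-aliased coverage ramp
(linear across one pixel), convolves with an ideal Gaussian PSF, and adds
constant background plus Gaussian read noise. There is no optical-sectioning
model — the analyses operate on single planes or projections. Pixel
coordinates are 0-based pixel centers with y increasing downward; the
default 0.2 μm/pixel on a 512² field is an arbitrary but configurable
confocal-like geometry.

Preprocessing follows standard confocal practice:

- **Flat-field**: `build_flatfield()` normalizes a background-subtracted
  homogeneous-dye image to mean exactly 1; `apply_flatfield()` divides it
  out (round trip is exact to < 10⁻⁶ relative SD).
- **Background**: default estimate is the mode of the lowest intensity
  quartile, applied per image.
- **Photobleaching**: factors are mean foreground intensities relative to
  the first acquisition, over a foreground ROI *fixed from the first
  acquisition* so that bleaching cannot shrink the ROI; factors > 1 beyond
  tolerance are clamped at 1 with a warning. The generator models bleaching
  as a constant multiplicative factor per acquisition (geometric decay),
  matching a repeated-acquisition control design.
- **Binarization**: Otsu by default (parameter-free, threshold logged as an
  attribute), or a fixed threshold.

## Tactoid morphometry and the choice of threshold

`segment_bundles()` measures each connected component: width is twice the
mean distance-transform value along the longest skeleton path (robust for
curved tactoids; a bounding-box width is not), orientation from second
moments, and length from the skeleton path. Two systematic errors of
pixel-scale morphometry deserve explanation because the package corrects
them explicitly:

- Zhang–Suen thinning stops short of blunt ends and eats tapered tips, so
  the raw geodesic skeleton under-reads length; end caps (the
  distance-transform radii at the two path ends) recover blunt ends.
- A detection threshold near the noise floor — needed because the pointed
  tips of a tactoid carry little fluorescence and an Otsu/half-max
  threshold cuts them (≈ −19 % mean length at the default PSF) — dilates
  the whole object by the PSF tail, so the maximum Feret diameter
  over-reads length.

When the intensity image is supplied, the dilation is removed
per object: for a PSF-blurred step edge the half-maximum contour sits
exactly on the true boundary, so the width excess of the detection mask
over the half-maximum mask measures the (isotropic) dilation, and the
corrected length is the Feret diameter minus that excess; the reported
width is the half-maximum width. Without the image, the mean of the
end-capped skeleton length and the Feret diameter is used — the two bracket
the true tip-to-tip length from below and above. On rendered spindle fields
(50 objects, mean 5.4 μm, 15 % CV, width 1.2 μm, 0.2 μm/pixel) every
object is then recovered within 10 % and the mean within ~3 %.

`classify_bundles()` uses the strict convention thin ⇔ width < 1 μm (a
width exactly at the threshold is "large"). `fit_power_law()` is ordinary
least squares of log aspect ratio on log crosslinker fraction; aspect-ratio
fits are reported per size class. The alignment fraction is the
intensity-weighted mean structure-tensor coherence
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ over the Otsu foreground,
with the tensor smoothed at `tensor_sigma` (default 1 μm); parallel ridges
score > 0.9, isotropic noise < 0.2, and the measure is rotation-invariant
to ~2 %.

## Droplet shape

Contours come from marching squares at the 0.5 level (`contourLines`),
hole-filled, counter-clockwise, lightly smoothed (5-vertex circular moving
average, logged) and resampled uniformly in arclength at ~1 pixel spacing.
Sphericity is $D_{in}/D_{out}$ with $D_{in}$ twice the maximum interior
Euclidean distance transform and $D_{out}$ the diameter of the *exact*
minimum enclosing circle (Welzl's algorithm on the contour vertices — a
circumscribed circle, not an ellipse fit); a droplet is "spherical" when
the ratio strictly exceeds 0.8. Solidity is pixel area over the convex hull
of the pixel corners, so convex shapes score 1 up to pixelation (the
five-square plus sign scores 5/7 against the exact polygon value).

Local curvature uses a least-squares (Kåsa) circle fit in a sliding window
(default 10 % of the perimeter — curvature is meaningless without stating
this window; it is logged). Before fitting, the closed contour is low-pass
filtered by keeping Fourier harmonics with wavelength ≥ the window:
pixel-quantization waviness otherwise dominates the fitted curvature at
small windows. On digital disks of radius ≥ 30 μm the profile is flat to
±2 % and the integrated turning angle equals 2π within 1 %; on a 2:1
ellipse the tip ratio matches the analytic $a/b^2$ within 5 % when the
window is smaller than the tip curvature radius. The sign convention takes
the turning direction; the reported ratio is $|\kappa|/\kappa_0$.

`sphericity_vs_size()` fits a logistic in log droplet size (the functional
form is a package choice; residuals are returned) and reports the size at
which the fitted curve crosses 0.8, `-Inf` meaning "below every observed
size". Equatorial slice defaults to the z-slice maximizing mask area.

## Radial and cortical statistics

`radial_probability()` is the circular average of a binarized equatorial
slice: the fraction of foreground pixels per r/R bin (20 bins by default;
bins with < 10 pixels are flagged). `temporal_cross_correlation()` is the
Pearson correlation between binarized projections at $t_0$ and $t$ over the
droplet ROI — Pearson keeps values in [−1, 1] and equals overlap-based
normalizations up to affine terms. `contour_correlation()` computes the
normalized circular autocorrelation of the mean-subtracted cortex signal
(FFT-based, so C(0) = 1 exactly and C is even), and defines the correlation
length $\xi_c$ as the first 1/e crossing with linear interpolation — the
standard convention, logged, since a correlation length has no meaning
without one. The cortex signal is sampled by `shell_band_signal()` over a
radial band of default width 10 % of R (shared with the release-kinetics
module); binarized input is the default, raw intensity is supported.

## Particle dynamics

`link_detections()` performs greedy nearest-neighbour linking with
one-frame gap closing (ties broken by smallest displacement); `msd()` is
the time-averaged MSD over all pairs, by default up to a quarter of the
trajectory span. `classify_and_fit()` fits MSD = 4Dτ + offset by weighted
least squares over lags 1–10 frames — short enough to limit bias from
confinement, long enough to average localization error, which the offset
absorbs — and classifies a particle as trapped when D < 0.01 μm²/s *or*
the plateau ratio MSD(10 dt)/MSD(dt) < 3 (a free walker shows 10). Both
thresholds are configurable and logged; the dual criterion catches both
slow and caged particles, and is monotone in the D threshold. Trapped
motion is generated as a stationary Ornstein–Uhlenbeck process — the
minimal stationary confined model — with per-axis SD `cage_radius/2`, so
the long-lag MSD plateaus at `cage_radius²`. The Stokes–Einstein reference
uses T = 293.15 K and η = 1.00 mPa·s (water at 20 °C) by default, giving
0.43 μm²/s for a 1-μm sphere.

## Two-channel unmixing and release kinetics

With a dye that reports double-stranded DNA in the green channel and
single-stranded DNA in the red, but that also stains the peptide in both,
the peptide contribution cancels in $I_{green} - \beta I_{red}$ where
$\beta$ is the green/red ratio of a peptide-only sample. `estimate_beta()`
aggregates the per-pixel ratio by the **median** (not a regression through
the origin): robust to segmentation bleed and to a minority of DNA-positive
pixels, which inflate the mean but not the median. Negative unmixed values
are meaningful (local ssDNA excess) and are never clamped.

Release curves are mean cortex-band intensities divided by the
per-acquisition photobleach factor; `fit_release()` fits the
single-exponential $I(t) = I_\infty + (I_0 - I_\infty)e^{-kt}$ (a single
decay constant is the model of record; residual diagnostics are returned)
with a residual-resampling bootstrap CI (200 replicates, seeded). Skipping
the bleach correction biases the fitted rate upward — a documented
diagnostic, tested. Rates are reported per minute over the full observed
window.

## Problem sizes, determinism, degenerate inputs

Every generator is a pure function of (parameters, seed); the caller's RNG
state is restored afterwards. The test suite and the acceptance script run
at deliberately desk-scale sizes — 250–600 frames for stiffness recovery,
200–500 particles × 100 steps for diffusion, 50 rendered tactoids at 512²,
100 aspect ratios per crosslinker condition — chosen so the whole suite
completes in well under a minute while keeping Monte-Carlo errors a factor
≳ 2 below every tolerance they are tested against.

Degenerate inputs fail loudly and specifically: branched skeletons list
their branch points, constant images are rejected by Otsu with a pointer to
fixed thresholds, zero-variance amplitude tables (duplicated frames) and
zero-variance cortex signals are errors, exactly constant release curves
return k = 0 flagged as "no release" rather than a failed fit, and negative
fitted diffusion coefficients are clamped to zero with a warning.

## Known limitations

- All analyses are 2-D: no 3-D backbone tracing, surface reconstruction, or
  3-D tracking; z-stacks enter only through projections and slice choice.
- The synthetic scenes use an ideal Gaussian PSF, uniform background and
  additive Gaussian noise; real confocal data add shot noise, optical
  sectioning and drift that the generators do not emulate, so recovery
  tests bound method error, not total experimental error.
- Filament frames are assumed independent; slowly relaxing modes violate
  this and widen (but do not bias) κ confidence.
- The release model is single-exponential; diffusion-limited or
  multi-phase release would need a different model.
- Skeleton-based lengths assume roughly convex, non-branching objects;
  strongly curved or touching bundles should be inspected via the returned
  label images and line scans.
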