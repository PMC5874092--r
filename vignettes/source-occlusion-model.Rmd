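---
title: "A double-Gaussian linac source model and its small-field consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A double-Gaussian linac source model and its small-field consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gauss2src)
```

## The model

The electron beam striking the bremsstrahlung target of a linear
accelerator is modelled as a rotationally symmetric spot whose normalized
shape as a function of radial position is a mixture of Gaussian
components,

$$f(r) = \sum_{i} a_i \, e^{-r^2 / 2\sigma_i^2}, \qquad \sum_i a_i = 1,$$

with the two-component ("double-Gaussian") case as the physically
motivated default: a dominant narrow core plus a broad, faint halo.
Because $f$ is not invertible as a whole, sampling proceeds by treating
$f$ as a probabilistic mixture. The area of component $i$ under the 2-D
spot is

$$A_i = \int_0^\infty a_i e^{-r^2/2\sigma_i^2}\, r\, \mathrm{d}r
      = a_i \sigma_i^2,$$

so a component is selected with occurrence probability
$P_i = A_i / \sum_j A_j$ using a uniform deviate $R_1$ (component 1 iff
$R_1 \le P_1$; the boundary is measure-zero but fixed for
reproducibility), and the radius is then drawn in closed form by direct
inverse-transform sampling with a second uniform deviate $R_2$:

$$r^* = \sqrt{-2 \sigma_i^2 \ln R_2}.$$

A uniform azimuth completes the position. $R_2$ is drawn on $(0,1]$; a
drawn zero is redrawn, since the transform diverges there. The energy
spectrum is Gaussian, parameterized by its mean and its FWHM as a
fraction of the mean; non-positive energy draws are redrawn rather than
clipped so the positive part of the Gaussian shape is preserved (at the
default 14% fractional FWHM the redraw probability is of order
$10^{-12}$, i.e. irrelevant in practice).

### Anisotropic spots

For non-rotationally-symmetric sources each transverse axis carries its
own 1-D mixture. The 1-D case has no $r\,\mathrm{d}r$ Jacobian, so the
component-selection weights become $A_i = a_i \sigma_i$ rather than
$a_i\sigma_i^2$; each coordinate is then a component-selected Gaussian
deviate. This 1-D weight rule is a package design choice — the radial
formula cannot be carried over unchanged without mis-weighting the
components — and is the main behavioural difference between the two axis
modes.

### Default parameters

The bundled `primus_source()` presets describe a Siemens PRIMUS 6 MV
beam:

| parameter | value | role |
|---|---|---|
| single-Gaussian FWHM | 0.10 cm | conventionally commissioned spot |
| $\sigma_1$ (broad) | 0.334 mm | double-Gaussian halo width |
| $\sigma_2$ (narrow) | 0.077 mm | double-Gaussian core width |
| mixture FWHM target | 0.051 cm | fixes $a_1 \approx 0.667$ |
| spectrum | 6 MeV mean, 14% FWHM | incident energy distribution |

The component weights are not free parameters here: at the half-maximum
radius $h$ the condition $a_1 e_1 + (1-a_1) e_2 = \tfrac12$ (with
$e_i = e^{-h^2/2\sigma_i^2}$) is linear in $a_1$, so
`fit_weights_to_fwhm()` solves it in closed form, and `analytic_fwhm()`
(bisection on the monotone half-maximum equation, tolerance
$10^{-12}$ cm) verifies the round trip. The admissible target interval is
open: $2.3548\,\sigma_2 < \mathrm{FWHM} < 2.3548\,\sigma_1$.

With these parameters the broad component carries
$P_1 \approx 0.974$ of the emitted particles. The double-Gaussian model
therefore has a *narrower* effective core than the single Gaussian
(0.334 mm vs 0.425 mm $\sigma$) plus a faint halo — the geometry behind
all the small-field contrasts below.

## Phase space and source-image reconstruction

Particle records (kind, energy, position, direction cosines, statistical
weight) are scored on planes perpendicular to the beam axis; the source
plane is $z = 0$ and the nominal scoring plane $z = 100$ cm. The file
format is deliberately self-contained (a text header plus either a
57-byte-per-record little-endian binary body or a TSV body); no
compatibility with external phase-space formats is attempted, as those
vary by mode and optional fields.

Back-projection is straight-line extrapolation
$x' = x + (u/w)(z_t - z_p)$, an exact involution; records with $w = 0$
cannot be projected and are excluded with a count. The source image is
reconstructed as energy fluence versus position: particles are binned
along one axis inside a thin central strip on the orthogonal axis, and
the per-bin sum of weight × energy is divided by the bin collection area.
Defaults follow the scoring resolution the transport model emulates: bin
width 0.01 cm (a 0.1 mm voxel) and, for source images, a strip half-width
of 0.005 cm — one voxel row through the 2-D image. For broad transverse
profiles at the scoring plane a wider strip (default half-width 0.5 cm)
trades resolution for statistics. The per-bin uncertainty is the
uncorrelated-history estimate $\sqrt{\sum (wE)^2}$.

## Occlusion transport

The transport model is reduced to the single mechanism of interest:
photons travel in straight lines from the extended source through
zero-thickness, perfectly absorbing apertures (transmission at the exact
aperture boundary is inclusive, fixed for determinism), and the dose
proxy is in-air energy fluence at the scoring plane. There is no target
or flattening-filter physics, no head scatter, no aperture transmission
or scatter, no phantom transport, and no monitor-chamber correction.
What survives is the visible-source-fraction geometry: for a single
circular aperture of radius $R$ at distance $d$, a point on the axis at
distance $D$ sees the source only within the back-projected radius
$\rho_{max} = RD/(D-d)$, so the transmitted fraction is
$\sum_i P_i (1 - e^{-\rho_{max}^2/2\sigma_i^2})$ — the closed form used
as the oracle for the Monte Carlo estimator.

Naive isotropic emission would waste essentially every history, so
emission is importance-sampled: each source particle is aimed at a point
drawn uniformly over the scored region (a scan-range × strip rectangle,
or the central tally square). Over the $\sim 10^{-5}$ sr involved the
true angular density is flat to high accuracy, so all histories carry
identical weight and relative fluence is unbiased.

Default aperture planes: collimating jaws (defining $y$) at 22 cm and the
MLC (defining $x$) at 31 cm from the source — the MLC sits farther from
the source on this machine, which is why $x$ penumbras are narrower than
$y$ penumbras at matched field size; both planes are configurable, since
the machine drawings are not public. Stereotactic cones are fixed at
59 cm. Square-field side lengths are defined at the 100 cm plane and
scaled to each aperture plane by similar triangles. The Gaussian edge
spread of a single aperture follows
$\sigma_{edge} = \sigma_s (D-d)/d$, giving a 20–80% penumbra of
$1.6832\,\sigma_{edge}$ — the second closed-form oracle. The $(D-d)/d$
lever arm is the entire story of the stereotactic plane: at $d = 59$ cm
it is 0.72, versus 3.6 at the jaws, so source-model differences that are
conspicuous at jaw-defined fields nearly vanish at the cones.

`detector_blur()` convolves a profile with a discrete Gaussian kernel,
normalized per input bin so total fluence is conserved exactly before
renormalization; it emulates the partial-volume averaging of a finite
detector and is deliberately not an attempt at detector modelling.

## Profile metrics

All level-based metrics use linear interpolation between bin centers — no
spline or sigmoid fitting — and percent levels are taken relative to the
central-axis value (the bin nearest position 0), not the profile maximum,
matching isodose-line usage for near-flat small-field profiles. FWHM uses
half of the profile maximum; the profile must be unimodal at that level
or an ambiguity error lists the offending regions. Edge crossings are
located from the outside in, which makes the estimators robust to
statistical noise on the plateau. First-order uncertainty propagation
covers the bracketing bins and the level-defining bin.

### A caveat on coarse-bin FWHM estimation

Bin averaging flattens a curved peak: for the double-Gaussian source,
$f''(0) \approx -6.2 \times 10^3\ \mathrm{cm}^{-2}$, so a 0.01 cm central
bin records $\approx 0.974$ of the true peak. Half-maximum is then taken
of a too-low maximum, both crossings move outward, and the estimated
FWHM of the reconstructed source image lands near 0.054–0.055 cm instead
of the analytic 0.051 cm — a +6–8% bias that is *deterministic*, not
statistical, and that no amount of histories removes. The narrow core
(FWHM 0.018 cm, under two bins) is the culprit; the broad single-Gaussian
source (FWHM 0.10 cm, ten bins) shows the same effect only at the
$+0.5\%$ level. When the absolute width of a narrow mixture matters, use
finer bins or `analytic_fwhm()`; the 0.01 cm default is retained because
it is the scoring resolution the transport model emulates.

## What the synthetic data does and does not emulate

The generator produces exactly the study conditions the package models:
mixture-distributed starting positions, Gaussian energies, parallel or
cone emission, vacuum propagation, and absorbing-aperture transport. It
does **not** emulate bremsstrahlung production in the target (the photon
source here inherits the electron-spot shape unchanged), flattening
filter fluence horns, head scatter, electron contamination, collimator
transmission, phantom scatter, or detector response. Consequently,
passing tests demonstrate the internal consistency of the sampling,
projection, reconstruction and metric chain and the *ordering* of
source-occlusion effects (output-factor and penumbra contrasts between
source models, their decay with source-to-collimator distance); they do
not certify absolute penumbra widths or output factors of a real beam,
which require full head-scatter transport plus measurement.

## Numerical choices

- Lengths are cm internally; `mm`/`cm` suffixes are accepted in
  configuration values and converted on input. Energies are MeV.
- One seedable Mersenne-Twister stream per simulation; deviates are drawn
  in fixed blocks (all $R_1$, then all $R_2$, then all azimuths), so a
  mixture with a zero-weight second component reproduces the
  single-Gaussian stream bitwise. Monte Carlo runs are chunked at $10^6$
  histories for memory; chunk order is fixed, so results are
  seed-deterministic bitwise.
- Bisection tolerances: $10^{-12}$ cm (`analytic_fwhm`); the weight fit
  is closed-form exact.
- Boundary conventions, all inclusive: $R_1 = P_1$ selects component 1;
  a ray exactly on an aperture edge is transmitted; the rightmost
  histogram edge is closed.
- Degenerate inputs are errors, not silent defaults: all-zero weights,
  non-positive widths, $R_2 = 0$, unnormalized direction cosines,
  zero-reference normalization, uncrossed metric levels, and transport
  runs in which no particle is transmitted ("empty field").
- Test and example problem sizes ($10^5$–$10^6$ histories for
  distributional checks, $10^7$ for the penumbra edge-spread
  verification) are chosen so statistical uncertainty sits an order of
  magnitude below each tolerance being exercised.

## Known limitations

- The occlusion model's output factors contain no head scatter or
  collimator exchange effect; they isolate the visible-source fraction
  and are meaningful as contrasts, not absolutes.
- The printed σ values are treated as electron-source parameters and the
  photon source is assumed to inherit them; target physics that would
  broaden the photon source is out of scope.
- Aperture planes for jaws and MLC are plausible defaults, not machine
  drawings; conclusions that depend on their exact values should vary
  them.
- Coarse-bin FWHM bias, as discussed above.
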