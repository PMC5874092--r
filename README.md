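# gauss2src

Monte Carlo treatment-head simulations of a medical linear accelerator are
only as good as the model of the electron beam striking the target. The
conventional choice — a single 2-D Gaussian spot — misses the halo that
real beams carry, and for small radiation fields (stereotactic cones,
sub-centimetre MLC fields) the resulting error in the reconstructed photon
source width propagates directly into penumbra widths and small-field
output factors through *source occlusion*: at small apertures the
collimator partially blocks the extended source as seen from the
measurement point.

`gauss2src` implements a double-Gaussian source model and the desk-scale
machinery needed to study its consequences:

- **Source model.** The normalized radial spot shape is the mixture

  f(r) = a₁ exp(−r²/2σ₁²) + a₂ exp(−r²/2σ₂²),  a₁ + a₂ = 1.

  Sampling uses area-weighted component selection — component *i* has
  occurrence probability Pᵢ = Aᵢ/ΣAⱼ with Aᵢ = aᵢσᵢ² (the r dr Jacobian of
  the radial integral) — followed by direct inverse-transform sampling of
  the radius, r\* = √(−2σᵢ² ln R₂). Weights are auto-normalized, widths may
  be given as σ or FWHM, and per-axis mixtures support non-rotationally
  symmetric spots. A Gaussian energy spectrum (mean, fractional FWHM)
  accompanies the spatial model.
- **Phase space.** A self-contained columnar phase-space format (binary and
  text dialects), vacuum propagation, straight-line back-projection of
  particle records to any plane, and energy-fluence-versus-position
  reconstruction of the source image.
- **Occlusion transport.** Photons ray-traced from the extended source
  through perfectly absorbing apertures (jaws, MLC, stereotactic cones) to
  a scoring plane: relative fluence profiles, central-axis values with a
  closed-form visible-source-fraction oracle, output factors, and an
  optional Gaussian detector blur.
- **Profile metrics.** FWHM, 20–80% penumbra, 50% field size, and
  maximum-profile-difference statistics, all by linear interpolation
  between bin centers with first-order uncertainty propagation.

The default `primus_source()` parameter set models a Siemens PRIMUS 6 MV
beam: a single Gaussian of FWHM 0.10 cm, or a double Gaussian with
σ₁ = 0.334 mm and σ₂ = 0.077 mm whose weights (a₁ ≈ 0.667) are fitted so
the mixture FWHM equals the reconstructed photon-source width of 0.051 cm.

## Worked example

```r
library(gauss2src)

src  <- primus_source("double")
summary(src)
#> Gaussian-mixture source summary (radial mode)
#>       weight  sigma probability
#> a1 0.6673308 0.0334   0.9741891
#> a2 0.3326692 0.0077   0.0258109
#> analytic FWHM of f(r): 0.051 cm

# reconstruct the source image from a scored phase space
spec <- energy_spectrum(6, 0.14)
ps   <- generate_source_phase_space(src, spec, n = 1e6, seed = 42, plane_z = 100)
bp   <- backproject(ps, target_z = 0)
prof <- energy_fluence_profile(bp[, c("x", "y")], bp$energy, bp$weight,
                               seq(-0.305, 0.305, by = 0.01), axis = "x",
                               strip_halfwidth = 0.005, density = TRUE)
fw <- estimate_fwhm(prof)
sprintf("FWHM %.4f +/- %.4f cm", fw$fwhm, fw$sigma)
#> [1] "FWHM 0.0544 +/- 0.0006 cm"
# analytic_fwhm(src) is 0.0510: 0.01 cm bins flatten the narrow peak and
# bias the half-maximum estimate upward -- see the methods vignette
```

```r

# output factors: the broad halo costs output at the smallest field
geoms <- list(`0.5` = square_field_geometry(0.5),
              `1`   = square_field_geometry(1),
              `10`  = square_field_geometry(10))
output_factors(src, spec, geoms, reference = "10", n = 2e5, seed = 7)
#>   field        of     of_sigma
#> 1   0.5 0.9648988 4.120490e-04
#> 2     1 0.9999849 8.757303e-06
#> 3    10 1.0000000 0.000000e+00

# a 2 mm stereotactic cone at 59 cm: profile, penumbra, field size
p <- simulate_profile(src, spec, cone_geometry(2),
                      seq(-0.35, 0.35, by = 0.0025), n = 1e6, seed = 11)
penumbra_20_80(p)
#> 20-80% penumbra [cm]:
#>   left : 0.040104 +/- 0.0011
#>   right: 0.042002 +/- 0.0018
#>   mean : 0.041053
field_size_50(p)
#> [1] 0.339701   # the geometrically magnified 2 mm aperture, 0.2 * 101.5/59
```

The summary shows why the two parameterizations behave so differently: the
broad component carries 97% of the emitted particles, so the double
Gaussian has a *narrower* core (σ₁ = 0.334 mm) than the commissioned single
Gaussian (σ = 0.42 mm) plus a faint halo. Less of its core is occluded at a
0.5 cm field, hence the higher output factor; at the 59 cm cone plane the
(D − d)/d lever arm is small and the two models nearly coincide.

A command-line driver wraps the same functions
(`exec/gauss2src sample | reconstruct | transport | of | analyze | compare |
fixtures | run`), with YAML experiment presets under `inst/extdata/`.

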