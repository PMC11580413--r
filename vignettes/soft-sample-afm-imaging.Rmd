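---
title: "Simulating AFM imaging of deformable samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AFM imaging of deformable samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softAFM)
```

## The imaging model

An AFM topography of a soft sample is not the sample surface. Two artefacts
act simultaneously: the finite width of the probe broadens features
(tip convolution, a grayscale dilation of the surface by the reflected tip
shape), and the imaging force indents the sample, so the recorded height is
the apex position at which the vertical tip–sample force equals the
instrument's set-point, not the position of first contact. softAFM models
an idealized constant-force image: for every lateral position the tip is
lowered from first contact, the vertical force is computed as a function of
apex height, and the image is the iso-force contour of the resulting
F(x, y, z) volume. Feedback errors, cantilever dynamics, imaging-mode
specifics, adhesion, and viscoelasticity are all outside the model; images
are the ideal constant-force limit.

The probe is rigid: a cone of half-opening angle `theta` terminated by a
spherical cap of radius `R`, tangent at lateral offset R·cos(theta) and
height R·(1 − sin(theta)) above the apex, making the profile C¹. Contact
stays on the cap for indentations up to R·(1 − sin(theta)); the package
exposes this bound (`sphericalValidityLimit`) because sphere-indenter
contact laws are exact only in that regime.

The sample is a linear-elastic, homogeneous, isotropic body with Young's
modulus `E` (MPa) and Poisson ratio `nu`, described geometrically by a
single-valued top surface h(x, y) ≥ 0 above a rigid substrate plane at
z = 0. Undercuts are discarded — a vertical-approach model cannot touch
them. Internal units are nm, pN and MPa throughout; since
1 MPa·nm² = 1 pN, the dimensionless groups F/(E\*R²) and δ/R carry no
conversion factors.

## Contact models

Three force–indentation laws are implemented, each linear in the reduced
modulus E\* = E/(1 − ν²):

* **Hertz** (sphere of radius R on a surface of local radius r):
  F = (4/3)·E\*·√R\*·δ^{3/2} with 1/R\* = 1/R + 1/r.
* **Conical Sneddon**: F = (2/π)·E\*·tan(theta)·δ²·f(δ). The correction
  f(δ) adapts the cone law to spherical samples; it is an empirically
  fitted function with no single canonical form, so it is a pluggable
  argument defaulting to f ≡ 1 (the exact Sneddon law,
  and the exact r → ∞ limit). Any user-supplied f(δ, R, r) slots in
  without touching the rest of the pipeline.
* **Double contact**: a particle resting on a rigid support is compressed
  both at the tip contact (Hertzian, radius R\*) and at its base contact
  with the substrate (Hertzian, radius r). The transmitted force is common
  to both springs in series, so the measured displacement is
  δ(F) = δ_I(F) + δ_C(F). The forward map is strictly increasing, so
  F(δ) is recovered by `uniroot` on the bracket [0, F_Hertz(δ; R\*)] at
  1e-12 relative tolerance; δ = 0 maps to F = 0 without a solve. With
  r = ∞ the base term vanishes and the model reduces exactly to Hertz.

Because all three laws scale linearly in E\*, the modulus fit
(`fitModulus`) is a one-parameter least-squares problem; it is minimized
over log E (positivity by construction) with a safeguarded scalar
minimizer rather than a generic NLS iteration, which cannot fail to
converge on these models. Following common AFM practice, the Hertz fit
substitutes R for R\* unless the sample curvature is supplied; fits can be
clipped to a dimensionless force ceiling F/(E\*R²) (closed interval),
computed with the generating material of the force volume.

## The elastic force engine

Volumetric finite-element contact solves are replaced by two engines that
reproduce the observable contract — force as a function of 3-D tip
position — at desk scale:

* **halfspace**: a boundary-element solver for a rigid indenter of
  arbitrary profile on an elastic half-space. The surface is discretized
  into uniform rectangular pressure patches; deflections use the exact
  Love integral of the Boussinesq point-load solution over a rectangle
  (no singular self-terms), and kernel–pressure products are evaluated by
  zero-padded FFT. The contact inequalities (pressure ≥ 0, no
  interpenetration, complementarity) are enforced by a projected
  conjugate-gradient active-set iteration in the style of Polonsky–Keer,
  at prescribed rigid approach. Convergence: relative total-force change
  below 1e-6 with no interpenetrating out-of-contact cells; iteration cap
  10 000; non-convergence is an error carrying the residual. A warning is
  issued when the contact patch touches the solver window, since truncated
  patches bias the force.
* **local-analytic**: the Hertz (or Sneddon) law driven by the sample's
  local radius of curvature at the contact point — exact for ideal
  sphere-on-sphere geometry, and orders of magnitude faster.

The half-space engine is validated in the test suite the same way an FEM
implementation would be: against the Hertz force, contact radius and
pressure distribution, the flat-punch law F = 2E\*aδ, and the conical
Sneddon law. The engines agree within ~10% at small indentation on smooth
on-axis geometry. Known deviations from a volumetric treatment: the
half-space engine has no finite-thickness stiffening (base compression
enters only through the analytic double-contact model, a deliberate split:
wide-based samples such as hemispheres make base compression small), and
contact is frictionless-normal rather than non-slip tangential; normal
forces in the Hertz regime are insensitive to this at small indentation.

### Local curvature

For parametric samples the analytic curvature is used where declared
(a hemisphere's metadata carries its radius); otherwise curvature comes
from centered second differences of the height field. Molecular height
fields are special: the envelope's atomic-scale bumps (sub-nm radii) are
below any continuum description and would make the analytic engine
absurdly soft, so a molecular sample carries a continuum proxy — half its
envelope height, i.e. the radius of the equivalent cylinder — as its
effective contact curvature. The half-space engine needs no such proxy; it
sees the full gap geometry.

## Imaging procedure and numerics

* **First contact**: for each lateral position, the apex height at first
  contact is max over sample cells of h − tipProfile(lateral offset),
  floored at 0 (substrate). Only cells within the tip's boundary radius at
  the sample's maximum height can contribute; the test suite verifies
  against an exhaustive no-cutoff oracle that this pruning never truncates
  a true contact. The scan loop is the package's one compiled (Rcpp) hot
  spot.
* **Force volume**: apex heights are first-contact minus a δ grid
  (default: 0 plus 29 geometrically spaced depths up to 0.65·R, the
  spherical-validity limit; the density is the package's choice). The δ = 0 layer is identically
  zero force by construction.
* **Iso-force extraction**: per column, the force is made monotone
  (cummax, guarding residual solver noise) and interpolated in z with a
  monotone shape-preserving cubic (`splinefun(method = "hyman")`) before
  root finding — a monotone interpolant cannot oscillate, which a plain
  bicubic could; lateral bicubic (tensor-product cubic spline) resampling
  of the height map is available afterwards. Columns whose sampled forces
  never reach the set-point are flagged saturated, logged, and floored at
  the substrate-contact height (0); this handling is the package's choice.
* **Degenerate inputs**: zero set-point returns the zero-force trace;
  an empty above-baseline footprint makes `apparentVolume` warn and
  return 0; a profile that never rises above the substrate is an error for
  `fwhm` (its baseline is the substrate, not the profile minimum).

## Fourier analysis of periodic topographies

A profile sampled uniformly over exactly one period, symmetric about
x = 0, is projected onto cosines: h(x) = A_0 + Σ A_n cos(2πnx/λ). The
projection is the discrete rectangle rule, which is the exact DFT on a
periodic grid; a duplicate endpoint is dropped when the stated period
shows both ends were sampled. Reconstruction and Parseval consistency are
property-tested. The aggregate of higher-order content (A_2..A_N,
N = 50 by default) is a configurable reduction — root mean square by
default, root-sum-of-squares optionally — the combining formula is a
design choice the package leaves open.

For an ideal image of a pure cosine surface the fundamental equals the
surface's cosine amplitude and all higher orders vanish; the acceptance
suite verifies this with a needle tip (R = 1e-7 nm, theta = 0.5°). Note
that "R → 0" alone is not sufficient: a 20° cone flank is less steep than
a λ = 10, amplitude-10 sinusoid near its inflection, so the cone would
still convolve the trace. The needle limit sharpens both cap and cone.

## Synthetic samples and presets

The generators define the package's standard study conditions:

* `makeHemisphere(r = 5)`: elastic hemisphere on the substrate, the
  canonical globular-feature benchmark; grid spacing defaults to r/25 and
  a warning fires below 8 cells per diameter.
* `makeSinusoid(lambda = 10, amplitude = lambda)`: surface periodic in x
  with peak-to-trough amplitude equal to the wavelength, troughs at the
  substrate, width 4λ, uniform along y.
* `buildBDNA(nBp = 80)`: an idealized, deterministic B-form double helix —
  rise 3.4 Å, twist 36° per base pair, two backbones offset 154° around
  the axis (hence distinct major/minor grooves), six pseudo-atoms per
  nucleotide from the phosphate backbone (8.9 Å radial) to the base-pair
  core, with UFF-derived van der Waals radii. It reproduces the canonical
  envelope (≈ 2.2 nm diameter, 10 bp/turn, ≈ 272 Å contour at 80 bp) but
  is a synthetic stand-in, not a crystallographic structure: no
  sequence-specific detail, no intramolecular flexibility. Real structures
  enter through `readPDB`.
* `dnaPreset()`: tip R = 1.8 nm, half-angle 5°, E = 100 MPa, ν = 0.3,
  0.55 nm bins, the molecule embedded by 20% of its height in the rigid
  base (5 nm × 20 nm footprint), 240 scan positions, set-point 100 pN.
  The 240 positions are distributed 30 along the axis × 8 across, a split
  that balances cross- and long-axis sampling. The preset uses the local-analytic engine with the
  cylinder-radius curvature proxy: at 100 pN the indentations approach the
  molecule's own height, far outside the half-space regime, so the
  analytic engine's transparent assumptions are preferable to a
  half-space solve pushed beyond its validity.

What passing tests on these generators show — and what they do not: the
generators are noise-free, perfectly periodic or perfectly spherical, with
known curvature everywhere. Agreement there validates the geometry,
contact mechanics and extraction machinery, but says nothing about
heterogeneous materials, adhesion, hydration layers, or tip wear in real
experiments.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes, chosen as the coarsest grids at which the closed-form benchmarks
hold to their stated tolerances: half-space solves on ~65×65 windows
(≥ 40 cells across a contact patch), hemisphere/sinusoid modulus maps at
5 and 2–3 scan positions with 14-point δ grids, and the volume-artefact
dilation on a 0.1 nm grid (~200×200 scan positions). Mesh-refinement
tests verify that halving the solver cell size moves the Hertz benchmark
force by under 2%.

## Known limitations

* Half-space elasticity: no finite-thickness or substrate-rigidity
  stiffening under thin features; at forces that compress a feature by a
  large fraction of its height (the 100 pN DNA preset does), absolute
  compressions are engine-dependent and only trends should be read.
* Frictionless normal contact; non-slip tangential contact conditions,
  as volumetric FEM treatments can impose, are not modelled.
* The Sneddon correction f(δ) defaults to 1; fits of strongly curved
  samples with the cone model inherit that choice.
* Molecular samples are upper-envelope rasters: undercuts and grooves
  narrower than the bin size are invisible by construction.
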