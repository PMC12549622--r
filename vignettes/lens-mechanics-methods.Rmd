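---
title: "Methods: lens geometry, spin mechanics and MRI water mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lens geometry, spin mechanics and MRI water mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensmech)
```

This vignette documents the mathematical model behind `lensmech`, the
parameter conventions, the numerical choices and their rationale, and the
known limitations. It is the reference for anyone auditing or extending
the package; the README gives the quick tour.

## Coordinate conventions

The lens is treated as a solid of revolution about its optical axis. All
geometry lives in the *lens frame*:

* the optical axis is the `x` axis, the transverse (radial) coordinate is
  `y` (or `r` when non-negative);
* the equatorial plane is `x = 0`, with the equator at radius
  `a = ED / 2`;
* the anterior pole sits at `x = +TA` and the posterior pole at
  `x = -TP`, so the lens thickness is `LT = TA + TP`.

All lengths are millimetres, angles are radians, moduli are pascals and
angular velocities are rad/s. The finite-element solver converts to SI
internally and converts back at its interfaces.

## Surface model

Each lens cap (anterior and posterior) is an aspheric surface with sag

$$Z(r) = \frac{r^2}{R\left(1 + \sqrt{1 - (1+\kappa) r^2 / R^2}\right)}
        + a_4 r^4 + a_6 r^6 + a_8 r^8,$$

measured from the cap vertex towards the equatorial plane. `R` is the
apical radius of curvature, `kappa` the conic constant and `a4, a6, a8`
polynomial deviation coefficients. A sphere of radius `r0` is the special
case `R = r0, kappa = 0`; an oblate spheroid with equatorial semi-axis
`a` and polar semi-axis `c` is `R = a^2/c, kappa = (a/c)^2 - 1`. The
latter identity is used as the closed-form oracle for the volume tests.

### Equatorial blend

Silhouette-derived caps rarely extend all the way to the measured
equator, so the two caps are joined to it by cubic *blends* in the axial
coordinate: on each side, the half-width `y(x)` between the cap junction
and the equatorial plane is a cubic constrained to match the cap's value
and slope at the junction vertex and to pass through the equator
`(0, a)` with zero gradient. Four constraints on four cubic coefficients
determine the blend uniquely; `fitEquatorialBlend` solves the square
constraint system directly, which is the numerically stable form of the
equality-constrained least-squares (KKT) solution — the scatter points
only act as a consistency check.

The cap/blend junction is placed where the cap half-width reaches
`junctionFraction` (default 0.95) of the equatorial radius. The default
keeps 95% of each cap as measured surface and leaves a short blend that
stays exactly cubic over the outermost 5% of the half-width — a property
the equator estimator relies on (below).

## Geometry extraction from silhouettes

`segmentOutline` thresholds the image midway between its intensity
extremes, keeps the largest connected component (raising an error when a
second comparably sized component exists), and extracts the sub-pixel
0.5-level boundary contour. The outline is then centred:

* the symmetry axis is the midline between the top and bottom envelopes,
  averaged over the axial extent;
* the axial origin is placed at the equator.

### Equator localisation

Locating the equator of a rasterised silhouette to sub-pixel accuracy is
the delicate step. The transverse envelope of a binary silhouette is a
staircase whose treads (runs of constant quantised height) carry no
sub-pixel information; including them in a least-squares fit biases any
smooth apex model. Conversely, a symmetric flank-midpoint estimator is
biased when the half-width curvature differs across the equator, which
it does for real lenses (the anterior and posterior blends are different
cubics, C1 but not C2 at the equator).

The estimator therefore collects flank *crossings* of the envelope at a
dense ladder of thresholds within 4% of the maximum — the risers of the
staircase, where linear interpolation is genuinely sub-pixel — and fits
the two-sided apex model

$$y(x) = y_0 - c_\pm (x - x_0)^2 + d_\pm (x - x_0)^3$$

with independent `(c, d)` on each side and zero gradient at the shared
apex `x0`. Given `x0` the model is linear, so `x0` is found by a grid
scan refined with a golden-section search. The 4% window depth is chosen
to span several pixel-quantisation levels while staying inside the blend
region, where the half-width really is a cubic and the model is exact.
On rendered test shapes this places the origin within about 0.01 mm at a
0.05 mm/px scale, versus ~0.1 mm for the midpoint estimator and ~0.5 mm
for a local quadratic through the discrete maximum.

### Aspheric cap fitting

`fitAspheric` estimates `(xv, R, kappa, a4, a6, a8)` per cap, where `xv`
is the vertex position. Two numerical issues shape the implementation:

1. The conic constant is only weakly separated from the polynomial
   terms over a finite span — the conic's Taylor expansion contributes
   `r^4, r^6, r^8` terms that `a4, a6, a8` can absorb, so the objective
   has a long shallow valley in `kappa`.
2. For `(1+kappa) r^2 > R^2` the conic is complex-valued, so naive
   optimisation can step outside the model's domain.

The fit uses *variable projection*: for a candidate `(log R, kappa)` the
remaining four parameters enter linearly and are solved exactly by least
squares, leaving a smooth 2-D profile objective (with a finite penalty
outside the real-valued domain). Nelder–Mead locates the valley, a
nested golden-section refinement (outer `kappa`, inner `log R`) descends
it, and a Levenberg–Marquardt polish of all six parameters is accepted
only when it actually lowers the residual. On noiseless synthetic caps
this recovers `R`, `kappa` and `a4` to at least six digits.

## Spin mechanics

### Forward model

The spin test is modelled as isotropic linear-elastic, axisymmetric,
small-strain deformation under the centrifugal body load
`f_r = rho * omega^2 * r`. The shear modulus varies spatially through
the *stiffness variation function*

$$G(\xi) = \alpha\, e^{\beta \xi},$$

where `xi` in [0, 1] is the dimensionless radius: 0 at the lens centre
(midpoint of the axial extent) and 1 on the surface, computed by scaling
each material point's position until it meets the boundary. `alpha` is
the central modulus in Pa and `beta` sets the centre-to-surface
contrast (negative `beta` means a stiffer centre; the surface modulus is
`alpha * exp(beta)`).

`forwardSpin` discretises the meridional half-section with a structured
polar mesh of linear (constant-strain) triangles (`lensMesh`, `nS`
layers by `nTheta` angular divisions; `nS = 32, nTheta = 64` gives 4096
elements). The default Poisson ratio is 0.4: constant-strain triangles
lock as `nu` approaches 0.5, and the element formulation becomes
singular at exactly 0.5, which the solver reports as an error rather
than returning a locked solution. One-point quadrature is used per
element; essential conditions pin the radial displacement on the axis
and the axial displacement at the node nearest the centre. The global stiffness matrix is assembled as
`sum_e G_e * Khat_e` with precomputed unit-modulus element matrices, so
re-solves over candidate `(alpha, beta)` reuse the geometry factors.
Verified properties: the solution is identically zero at rest, scales
exactly with `omega^2`, and the maximum displacement changes by under 1%
when refining from ~1k to ~4k elements.

### Inverse problem

`invertSVF` recovers `(alpha, beta)` from an observed deformed outline
by minimising a boundary-displacement misfit (`deformationObjective`, a
symmetric nearest-point distance in units of 0.01 mm) with L-BFGS-B on a
scaled box, a centre start plus Latin-hypercube restarts, and a cache
keyed on `beta` (displacements are proportional to `1/alpha` at fixed
`beta`, so each `beta` needs one solve). The fit reports bound-activity
and convergence flags and raises a quality error when the residual
misfit is implausibly large.

### Validation protocol

`validateForwardInverse` runs the closed loop: synthesise a spun outline
from known `(alpha, beta)`, invert it, and report the relative `alpha`
and absolute `beta` errors. By default the forward synthesis uses the
same mesh resolution as the inversion. This matched-mesh protocol
isolates the estimator: with it, both bundled modulus presets are
recovered to better than 1% from noiseless data. Deliberately
mismatching the meshes instead measures the *discretisation* bias of
linear triangles at ~4k elements — several percent in `alpha` — which is
a property of the mesh, not of the optimiser; the function exposes
`forwardNS`/`forwardNTheta` so that mesh study can be run explicitly.

## MRI water mapping

### Signal model and two-point fit

`spgrSignal` implements the spoiled gradient-echo steady state

$$S = PD \sin(b_1 \alpha)\,\frac{1 - e^{-TR/T_1}}{1 - \cos(b_1 \alpha)\, e^{-TR/T_1}}$$

with flip angles 4 and 23 degrees and TR = 15 ms as defaults. With two
flip angles the model linearises: plotting `S / sin(b1 a)` against
`S / tan(b1 a)` gives a line with slope `m = exp(-TR/T1)`, so `fitT1PD`
solves each voxel in closed form. Voxels whose slope falls outside
(0, 1) are flagged invalid and set to `NA` rather than clamped. The
transmit-field map `b1` multiplies the nominal flip angle; omitting it
visibly biases `T1` (the bias grows monotonically with the `B1`
deviation), which is why `b1` is a first-class input. `resampleB1`
bilinearly resamples a coarse acquired `B1` map onto the imaging grid.

### Water content

`waterContent` converts proton density to relative water content
`rho = PD / PD_water` by normalising to the mean `PD` inside a
free-water reference region. This makes `rho` invariant to scanner gain
(a pure ratio), which is verified by test. `equatorialLineProfile`
extracts the band of rows around the widest part of the lens mask and
returns the column means against the normalised position `r/a` in
[-1, 1]. Profile comparisons use `r/a < 0.2` as the nuclear region and
`r/a > 0.6` as the cortical region.

## Reporting

`averageProfiles`, `normaliseShear` and `compareConditions` resample
per-lens profiles onto a common `r/a` grid, normalise shear profiles to
the baseline nuclear maximum, and form per-position ratio (or
difference) bands with Student-t confidence intervals.
`geometryChangeTable` summarises before/after cohorts with paired
t-tests and the conventional star notation. `synthGeometryCohort` draws
synthetic cohorts from condition presets (isotonic, hypertonic,
hypotonic, high-potassium, ouabain) whose means and SDs define the
generator's study conditions. `runPipeline` chains the stages from a
plain list or YAML config and writes deterministic artefacts (its run
log contains no timestamps, so reruns are bit-identical).

## Numerical tolerances

* Geometry round trips (render, segment, fit) are tested to 1% of ED,
  LT and volume at 0.05 mm/px, and to one pixel in Hausdorff distance.
* Volume quadrature is tested to 0.05% against closed forms.
* Matched-mesh forward–inverse recovery is tested to 5% in `alpha` and
  0.05 in `beta`; in practice it achieves ~0.1–1%.
* The MRI two-point fit is exact to rounding on noiseless data and is
  tested at 1e-6 relative.

## Limitations

* The mechanical model is small-strain and linear-elastic; at 1000 RPM
  bovine lens deformations are a few hundred micrometres, where this is
  reasonable, but the model will understate stiffness changes at much
  higher loads.
* The stiffness variation function is a one-parameter-family radial
  exponential; real lenses show a plateau-like nucleus that it can only
  approximate.
* Constant-strain triangles cannot represent truly incompressible
  material (the default Poisson ratio is 0.4), and absolute
  displacements converge at the percent level on the default meshes —
  which is why the validation protocol matches meshes (see above) and
  why mesh refinement is exposed to the user.
* The silhouette segmenter assumes a single lens on a plain background,
  and the equator estimator assumes the outermost 5% of the half-width
  is blend-shaped; grossly non-axisymmetric lenses violate both.
* The MRI model ignores T2* decay at the (short) echo time, imperfect
  spoiling and noise-floor bias; the two-point fit is exact only for
  the ideal spoiled steady state.
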