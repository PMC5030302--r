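---
title: "Wind-displaced canopies: models, assumptions and numerical choices"
author: "windcanopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wind-displaced canopies: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windcanopy)
```

## The question the package addresses

Wind moves crop canopies.  Even a modest steady lean changes which leaf
surfaces face the sun, and gusts sweep a canopy through a family of
configurations fast enough that the solar angle is effectively frozen.
`windcanopy` quantifies what such displacement does to the light environment
and to daily carbon gain of a rice-like stand.  The pipeline is:

1. build a triangle-mesh plant and duplicate it into a 3×3 stand
   (`generate_plant()`, `build_canopy()`);
2. tilt every plant rigidly downwind by a chosen angle
   (`solid_body_rotate()`);
3. compute per-triangle photosynthetic photon flux density (PPFD) through
   the day by forward Monte Carlo ray tracing with periodic lateral
   boundaries (`trace_timepoint()`, `simulate_day()`);
4. convert light to net carbon with a non-rectangular hyperbola
   parameterised per canopy layer, and aggregate
   (`nrh()`, `daily_carbon_triangle()`, `total_light_per_area()`,
   `canopy_carbon_per_area()`);
5. drive the two experiments — a constant displacement held all day, and a
   gust sweep of 0–10° at fixed times — with `run_constant()` and
   `run_dynamic()`.

## The synthetic stand

The canopy experiments were designed around a 600-triangle reconstruction
of a vegetative-stage indica rice plant that is not publicly deposited, so
the package ships a procedural stand-in.  `generate_plant()` builds tapered
blades as triangle strips along centerlines whose inclination from vertical
grows linearly with arc length (a one-parameter droop), with blade length,
base angle and curvature graded by insertion rank: the top of the plant is
erect, the base planophile — the depth structure described for this canopy
type.  Two exact calibrations follow assembly:

* **Height.** The plant is scaled isotropically so its topmost vertex sits
  at 0.73 m.  This height is the unique value consistent, under the
  arc-displacement convention `h*sin(theta)`, with both printed
  tip-displacement correspondences (6° ↔ 7.6 cm, 10° ↔ 12.7 cm).
  Isotropic scaling preserves every leaf angle.
* **Area.** Blade vertices are `center ± halfwidth * u` with `u` a fixed
  horizontal unit vector per leaf, so each face normal is proportional to
  `dc × u`, independent of the width.  Scaling all halfwidths therefore
  scales every face area linearly without touching a single normal, and the
  one-sided area is set to 0.04 m² per plant *exactly*.  Nine plants on a
  0.3 m × 0.3 m plot then give LAI 4.0, matching the stand the experiments
  describe.

Duplicates receive independent uniform yaws in [0°, 360°) — the original
duplicate rotations have no stated distribution — and land on a 3×3 grid at
0.10 m spacing.  The periodic ray-tracing box spans the centers of the
outer plants (0.2 m × 0.2 m), the construction used to avoid boundary
interference.  Panicles and distinct stems are not modelled (the reference
canopy is a vegetative-stage one precisely to avoid them), and the
generator makes no claim to botanical tillering geometry: what it
reproduces are the *radiatively relevant* properties — triangle count, LAI,
height, depth-graded leaf angles, blade-scale connectivity for
"adjacent same-leaf triangle" sampling.  Tests passing on this stand
therefore validate the machinery and its calibrations, not any one real
plant's light climate; absolute interception numbers for the real
reconstruction would differ.

## Wind as solid-body rotation

A steady wind is mimicked by rotating each plant rigidly about a horizontal
axis through its own base, perpendicular to the wind azimuth, so plants
lean downwind and keep ground contact.  Rotating each duplicate about its
own base (rather than the assembled canopy about one axis) is an
assumption — the alternative detaches off-axis plants from the ground.
Rigid motion preserves areas and pairwise distances to machine precision,
which the tests assert.  Elastic bending, flutter and leaf–leaf collision
are out of scope: the solid-body lean is a first-order surrogate bracketing
the configurations a moving canopy passes through.

## Light: clear-sky model and ray tracing

Solar geometry is standard declination/hour-angle astronomy in local solar
time.  The sky is a two-component clear-sky model: direct beam
`S0 * tau^(1/sin(beta))` with `S0 = 2600` µmol m⁻² s⁻¹ (the conventional
400–700 nm photon-flux solar constant), `tau = 0.5`, and isotropic diffuse
`0.3 * S0 * (1 - tau^(1/sin(beta))) * sin(beta)`.  The diffuse coefficient
0.3 is the standard crop-modelling choice; the reference scenario fixes
only the beam transmittance, so results sensitive to the diffuse fraction
should be reported together with its value (it is a `solar_config()`
field).

The tracer launches rays through the box top: the direct beam parallel to
the photon direction, diffuse rays cosine-weighted from a uniform sky dome.
On a leaf hit the *incident* flux is tallied to the face (both sides — the
mesh has no meaningful winding), then the photon is absorbed, reflected
(Lambertian, incident side) or transmitted (Lambertian, far side) with
probabilities `1 - rho - tau_leaf`, `rho = 0.075`, `tau_leaf = 0.075`.
"Scattering 7.5%" is mapped to reflectance and "transmittance 7.5%" to
transmittance; both are exposed in `leaf_optics()`.  Rays crossing a
lateral box face re-enter from the opposite side; the ground absorbs (soil
reflectance defaults to 0 and is configurable); the top face lets photons
escape.  After `max_bounces = 3` scattering events a photon is terminated
as absorbed — at rho = tau = 0.075 the neglected tail carries under 0.3% of
scattered energy.  The estimator is normalised so an unobstructed
horizontal plate receives `direct_normal*sin(beta) + diffuse_horizontal`
exactly, which anchors the units.

Numerics: triangles live in a median-split BVH (compiled, Rcpp); a plain
all-faces intersector written in R is kept as the testing oracle.  The RNG
is a self-contained PCG32 stream per ray batch, so results are bit-for-bit
reproducible for a seed and independent of scheduling.  Rays are split into
`n_batches` independent batches whose spread yields Monte Carlo standard
errors for any tallied quantity.  The per-time-point budget defaults to
2×10⁵ rays per component; scaled studies pass smaller budgets explicitly.

On periodicity testing: the box content is the stand as assembled — parts
of boundary plants lying outside the box are simply never hit, which is the
intended "boundaries at the centers of the outer plants" construction.
Folding all nine plants into the box would double-count leaf area, so the
package does not canonicalise geometry by wrapping.  The periodic wrap is
instead validated by two consequences that only hold if it works: a plate's
PPFD under an oblique beam is independent of its depth (deep plates are
only reached after several wraps), and a small plate receives the same flux
anywhere in the box.

## Carbon: the non-rectangular hyperbola

Net assimilation at irradiance `L` is the smaller root of

```
theta * F^2 - F * (phi*L + (1+alpha)*Pmax) + phi*L*(1+alpha)*Pmax = 0
```

minus dark respiration `Rd = alpha * Pmax`, with `phi = 0.052`,
`theta = 0.845`, `alpha = 0.1` shared across layers and `Pmax` 32 / 21 / 5
µmol CO₂ m⁻² s⁻¹ for the top / middle / bottom layer.  Layers are
equal-depth thirds of the height of the highest face center — the layering
is stated but its boundaries are not, and equal thirds is the neutral
choice; a face center exactly on a boundary goes to the upper layer.

Two integration windows are kept deliberately distinct, matching the
reference protocol: light interception (TLLA) integrates 5.5–18.5 h,
daily carbon integrates 5–22 h, so carbon accrues dark respiration over the
longer window.  Since PPFD is zero outside daylight the light integral is
insensitive to its window.  Quadrature is trapezoidal on the simulation
grid (dt in seconds); a refinement oracle in the tests bounds the
discretisation error of a 10-minute grid at under 1% for daily totals.
Canopy summaries (TLLA, C) are computed over the central plant's faces:
with the box at the outer-plant centers, the outer halves of boundary
plants are unreachable by rays and would bias a whole-stand average low.

## The two experiments

`run_constant()` holds one lean angle (default 6°) all day for each wind
direction and reports TLLA and C with standard errors from `n_reps`
independent replicate day simulations, plus area-weighted PPFD histograms
per layer at 9:00/12:00/15:00 (bin width 100 µmol m⁻² s⁻¹, configurable)
and leaf-angle distributions.
Histogram differences are expressed in percentage points of leaf area, not
relative percent.

`run_dynamic()` sweeps 0–10° in 1° increments at fixed times, treating each
angle as an instantaneous configuration (the sweep is faster than any
solar-angle change).  Nine locations — three per layer on the central
plant, each an anchor face pooled with its four nearest same-leaf
neighbours — are drawn with a documented seed, because the original nine
locations are unrecoverable.  Carbon-gain series are min–max normalised per
face across the sweep and then averaged over a location's five faces, so an
averaged series need not attain 0 or 1; a constant series is degenerate and
reported as 0.5 with a flag.  Percent differences are relative to the 0°
configuration and identically zero there.

## Problem sizes and determinism

Full-resolution runs use a 1-minute grid and 2×10⁵ rays per component per
time point.  The package's own validation suite and the bundled
reproduction script run scaled-down configurations — a 10-minute grid with
2.5×10⁵ rays m⁻² (10⁴ rays per component) for the constant scenario, and
single snapshots at 10⁵ rays m⁻² for the sweep — sizes chosen so the
Monte Carlo standard errors remain an order of magnitude below the
distortion signal they are used to detect.  Every random choice (plant
jitter, yaws, ray paths, location draws) flows from explicit integer seeds,
and a pinned configuration reproduces every number bit-for-bit.

## Known limitations

* The stand is procedural; absolute fluxes are not those of any measured
  plant, and the direction of the distortion effect is mesh-specific.
* One spectral band (PPFD); no specular reflection, no soil reflectance by
  default, no stem/panicle optics.
* A constantly clear sky; no clouds or equation-of-time correction.
* Solid-body distortion only — no elastic deformation or dynamic flutter.
* No stomatal, temperature or acclimation response in the light-response
  model; parameters are fixed per layer.
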