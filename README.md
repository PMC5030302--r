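# windcanopy

Wind moves crop canopies, and even a modest lean reshuffles which leaf
surfaces face the sun.  `windcanopy` is an R package for quantifying what
wind-induced displacement does to the light environment and daily carbon
gain of a cereal stand.  It is aimed at crop and functional–structural
plant modellers who want a self-contained, reproducible pipeline from
canopy geometry to carbon.

The pipeline:

* **Synthetic stand** — a procedural vegetative-stage rice-like plant
  (600 triangles, top at 0.73 m, erect leaves above grading to horizontal
  at the base, one-sided area 0.04 m²), duplicated with random yaws onto a
  3×3 grid at 10 cm spacing (stand LAI 4.0).
* **Wind distortion** — solid-body rotation of each plant about its base,
  perpendicular to the wind azimuth, leaning the stand downwind by
  0–10°; at 0.73 m, a 6° lean displaces the canopy top by
  `h sin θ` = 7.6 cm, a 10° lean by 12.7 cm.
* **Light** — forward Monte Carlo ray tracing (Rcpp, BVH-accelerated) of
  the triangulated stand inside a laterally periodic box, with a
  clear-sky direct + diffuse model (`S0 τ^{1/sin β}` beam, isotropic
  diffuse), Lambertian leaf scattering (ρ = τ_leaf = 0.075), and
  per-face Monte Carlo standard errors.
* **Carbon** — a non-rectangular hyperbola per canopy layer,

  `θF² − F(φL + (1+α)P_max) + φL(1+α)P_max = 0`,  `F_net = F − αP_max`,

  with φ = 0.052, θ = 0.845, α = 0.1 and P_max = 32/21/5
  µmol CO₂ m⁻² s⁻¹ for the top/middle/bottom layer; per-triangle daily
  carbon `P_i = S_i ∫ F(L_i(t)) dt`, canopy carbon gain per unit leaf
  area `C = ΣP_i / ΣS_i`, and total light interception per unit leaf
  area `TLLA = Σ S_i ∫ L_i(t) dt / Σ S_i`.

## Worked example

```r
library(windcanopy)

plant <- generate_plant()
plant
#> <triangle_mesh> 620 vertices, 600 faces, 10 leaves
#>   area 0.04000 m^2, height 0.7300 m

tip_displacement(plant, 6)    # cm at the canopy top
#> [1] 7.630578
scene <- build_canopy(plant, seed = 1)
canopy_lai(scene)
#> [1] 4

nrh(c(0, 500), nrh_params(32))   # top layer: dark respiration, mid-range
#> [1] -3.20000 17.90457

res <- run_constant(scene, directions = c("none", "E"), angle = 6,
                    cfg = trace_config(rays_per_m2 = 2.5e5), step = 10,
                    n_reps = 3L, seed = 1L)
res
#> <scenario_result>
#> Constant-wind summary (central plant):
#>  direction angle  TLLA  TLLA_se       C      C_se
#>       none     0 8.122 0.008158 0.09613 1.053e-04
#>          E     6 7.431 0.009512 0.06979 3.945e-05
```

The table reads: the undistorted stand's central plant intercepts
8.12 mol photons m⁻² leaf d⁻¹ (TLLA) and fixes 0.096 mol CO₂ m⁻² leaf d⁻¹
(C); under a steady easterly wind leaning this particular synthetic stand
by 6° all day, both drop well beyond their Monte Carlo standard errors.
The magnitude *and sign* of the change depend on the mesh and yaw draw —
the robust statement is that a rigid lean measurably reorganises light
capture.  `run_dynamic()` produces the companion gust-sweep table
(11 angles × 3 times × 9 leaf locations) with normalised carbon gain and
percent differences against the upright stand.

A thin command-line wrapper lives at `inst/cli/windcanopy.R`
(`generate` / `constant` / `dynamic` subcommands writing CSV + a JSON
manifest).

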