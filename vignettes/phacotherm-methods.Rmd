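---
title: "Modeling heat and flow in the anterior chamber during phacoemulsification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heat and flow in the anterior chamber during phacoemulsification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During phacoemulsification the ultrasound tip dissipates heat into the
anterior chamber (AC). The corneal endothelium — a non-regenerating cell
monolayer on the inner corneal surface — is sensitive to thermal stress, so
the question of how hot the chamber gets, for how long, and how the filling
fluid (aqueous humor, AH; balanced salt solution, BSS; or a 200 Pa·s
sodium-hyaluronate viscoelastic, "Healon") changes that exposure, is directly
clinically relevant. `phacotherm` implements a 2-D finite-element model of
this situation, plus the biostatistics used to analyse the companion clinical
endpoints (endothelial cell density, morphometry, IOP, visual acuity).

## Model

### Geometry

The chamber cross-section is fully determined by printed dimensions: chord
10 mm, sagittal depth 3.2 mm, pupil 2.98 mm, iris thickness 0.45 mm. Several
shape questions are left open by those numbers; the package resolves them as
follows (all configurable through `geometry_params()`):

* **Corneal outline**: a circular arc through the two rim points with the
  stated sagittal depth. A circle is the standard AC model choice and is the
  unique conic fully determined by the chord and depth alone.
* **Floor**: a flat iris annulus at `y = 0` with a planar lens surface
  recessed by the iris thickness across the pupil. This is the simplest
  closed outline consistent with the stated dimensions, and it gives the
  heated tip (0.25 mm above the lens) a meaningful immersed position inside
  the pupillary recess.
* **Outflow pathway**: at each rim the arc is truncated at the trabecular
  meshwork height (300 µm) and a rectangular porous block of 85 µm flow
  length attaches horizontally, with a 163 µm Schlemm's-canal pressure
  outlet centred on its outer face. Flow therefore crosses the meshwork
  radially at the iridocorneal angle, which is the anatomical arrangement.
* **Aqueous inlets**: one 20 µm floor segment immediately outside each pupil
  edge, bordering the iris.

The outline polygon is frozen at geometry-build time (the arc is discretised
into `n_arc` chords). The mesh generator then *snaps* every boundary node
onto this polygon and keeps every polygon vertex as a mesh node, so the
triangulated area equals the outline area to machine precision at any
refinement level — mesh-convergence checks of the domain representation are
exact rather than approximate.

### Equations

In the bulk the package solves incompressible laminar flow with the
Boussinesq buoyancy force

$$\rho\,\partial_t \mathbf u + \rho(\mathbf u\!\cdot\!\nabla)\mathbf u =
  -\nabla p + \mu \Delta \mathbf u + \rho\alpha\,\mathbf g\,(T_{\mathrm{ref}}-T),
  \qquad \nabla\!\cdot\!\mathbf u = 0,$$

coupled to advective–diffusive heat transport
$\rho c_p(\partial_t T + \mathbf u\!\cdot\!\nabla T) = k\,\Delta T$.
Inside the trabecular-meshwork block the momentum equation gains the
Brinkman drag $-(\mu/\kappa)\mathbf u$ and the porosity-scaled inertial
coefficients ($\varepsilon_p = 0.1$, $\kappa = 5\cdot10^{-15}\,$m²); the
Forchheimer coefficient and porous mass source default to zero, so those
terms vanish identically. Pressure work and viscous dissipation in the heat
equation are implemented but default to off — at mm/s velocities they are
many orders of magnitude below the boundary source.

Boundary conditions: outer cornea fixed at 27 °C (exposed, irrigated
surface), all other walls at the core temperature 36.5 °C; no-slip walls;
2.4 µL/min total aqueous production split over the two inlets; Schlemm's
canal outlets at 10.5 mmHg. The inflow value is the canonical physiological
production rate (the source model cites it from the modeling literature
without printing it). Gravity points from cornea to lens — the supine
surgical position — which makes the heated plume rise from the tip towards
the cornea and produces the symmetric pupil-centred streamline pattern the
figures describe.

### The heat impulse and the 2-D/3-D conversion

The ultrasound burst is a boundary heat source on the immersed tip segment
(2.2 mm, 0.25 mm above the lens), active for the first 5 s, with total
power 0.66 / 1.2 / 2.4 / 3 W. The printed boundary condition
($\mathbf n\cdot\nabla T = Q$) is dimensionally inconsistent and is
implemented in the standard Neumann form $-k\,\partial T/\partial n = q''$.

Converting a 3-D power (W) into a 2-D areal flux (W/m²) requires an
effective out-of-plane width. Two conversions are used, deliberately
different:

* **Slab depth** for volumetric rates (the µL/min inflow): the tip diameter,
  2.2 mm, as a representative chamber slice thickness.
* **Heated width for the tip flux**: the tip is a *cylinder*; the power
  leaves through its lateral surface, which is $\pi d$ per unit length, so
  the default is $d_\mathrm{eff} = \pi \times 2.2\,$mm and
  $q'' = P/(L_\mathrm{tip}\,\pi d)$ (≈ 7.9·10⁴ W/m² at 1.2 W). Using the
  flat projection $d$ instead concentrates the same power on a third of the
  physical surface and overpredicts every published temperature by roughly
  that factor; with the cylindrical-surface reading the model lands on the
  published envelope (maximum point-probe temperature ≈ 54–56 °C at 3 W,
  viscoelastic rise ≤ 0.5 °C) without any further adjustment. Both widths
  are plain arguments (`heat_source(d_eff = ...)`).

### Discretisation and numerical choices

* **Elements**: equal-order P1 velocity/pressure/temperature on triangles,
  with consistent PSPG pressure stabilisation (`stab_delta`, default 0.1,
  scaled by $h^2/\mu$ in the bulk and $\kappa/\mu$ in the porous block).
  Keeping the body force in the stabilised continuity residual makes
  hydrostatic balance exact: a uniform temperature field produces machine-zero
  velocity, which is asserted in the tests.
* **Mesh**: ~5000 triangles at the reference resolution (the published model
  used 4981); mapped columns with mirrored diagonals make the mesh exactly
  mirror-symmetric, and one vertical level is snapped to the Schlemm's-canal
  endpoints and one recess level to the tip segment so all boundary features
  are unions of element edges.
* **Time stepping**: implicit Euler with the published dt = 0.02 s for the
  heat equation; the momentum system is refreshed every `flow_stride` = 5
  steps (0.1 s) with Picard linearisation about the previous velocity.  The
  flow field responds on the buoyancy/viscous timescale (seconds —
  $L^2/\nu \approx 14$ s), so a 0.1 s quasi-steady refresh resolves it; the
  refinement test (5000 vs 20 000 elements) bounds the combined space–time
  error at the probe to below 0.3 °C.
* **Stationary baseline**: damped Picard iteration (relaxation 0.6) to the
  published relative tolerance 10⁻³, with a pseudo-transient fallback; the
  baseline is computed once per fluid and shared across powers.
* **High-viscosity regime**: at µ = 200 Pa·s the Rayleigh number is ~10⁻⁵ of
  the aqueous value and the flow is quiescent; fluids above
  `stokes_mu_threshold` (1 Pa·s) are solved in conduction-only mode
  (u ≡ 0), which is also what the full momentum solve returns there, at a
  small fraction of the cost.
* **Heat capacities**: the printed per-gram numerals (4.2 / 2.5) are
  impossible for liquids as J kg⁻¹K⁻¹ and are read as kJ kg⁻¹K⁻¹
  (4200 / 2500 J kg⁻¹K⁻¹); the literal values remain available
  (`get_fluid(literal_cp = TRUE)`). Density and thermal expansion are
  printed for aqueous humor only and are reused for the other two
  near-water-density fluids. Healon is treated as Newtonian at the single
  printed viscosity.

### Post-processing conventions

The reference "point probe" sits 0.6 mm below the corneal apex on the
symmetry axis; `corneal_wall_interior` (0.1 mm below the apex) covers the
alternative reading of "corneal surface temperature" (the outer wall itself
is Dirichlet-fixed and cannot rise). Relaxation back to baseline is not
quantified in the source; the package defines it as max |T − T_ref| < 0.5 °C
plus a 5 % relative velocity criterion, sustained, and reports it both
field-wide and at the probe (the published 10–25 s window is reproduced by
both). Velocity extrema exclude a two-element band at the inlets and
outlets, where nodal values reflect mesh resolution rather than physics.

## The synthetic cohort

The raw patient data are not public; the generator reproduces the published
*group-level* structure: 47 BSS / 45 Healon eyes, sex counts, truncated-normal
ages with the printed means/SDs/ranges, and all tabulated endpoint
means/SDs (ECD at four timepoints, IOP at five, BCVA at four, morphometry
pre-op and day 1, surgical covariates). Within each endpoint family,
timepoints are drawn per patient from a correlated multivariate normal with
equicorrelation `rho_w` = 0.85 — close to the 0.88 implied by the published
one-month paired-loss SD (`calibrate_rho(436, 471, 226)`), which a purely
cross-sectional model cannot reproduce. Post-operative IOP means/SDs are
printed only as a figure; the defaults are chosen so that a transient
>20 mmHg peak occurs in roughly 9/47 vs 5/45 eyes at 6 h and normalises by
day 1, matching the narrative. An `age_ecl_slope` knob (default 2 cells/mm²
per year above the group mean age, applied to post-operative timepoints)
reproduces the direction of the reported age–cell-loss association without
asserting an effect size the source does not print.

What the generator does **not** emulate: between-family correlations (ECD vs
IOP vs BCVA are independent), per-patient consistency between counted ECD
and analysed mean cell area (the published table itself is inconsistent
there), measurement-device error structure, dropout, and complications. A
green statistical test therefore establishes that the *pipeline* behaves
correctly under the published group structure — not that it would reproduce
patient-level findings derived from unavailable raw data; the published
between-group p-values are accordingly not asserted anywhere.

The statistics stage follows the published procedure: Shapiro–Wilk and
Kolmogorov–Smirnov screening (parametric iff both p > 0.05), two-sample
t-tests (Welch by default; the classical equal-variance Student test behind
a flag, since robustness beats name-fidelity), repeated-measures ANOVA for
longitudinal courses, and Friedman for non-normal repeated measures. The
source's use of Friedman for a cross-sectional two-group comparison is
available behind `paper_compat = TRUE`; the default routes such comparisons
to the rank-sum test.

## Known limitations

* 2-D planar: out-of-plane recirculation and the true cylindrical tip are
  collapsed into the two conversion widths above.
* The published AH-vs-BSS contrast at high power (54 vs 40 °C) does not
  emerge from the printed constants: BSS's higher conductivity is offset by
  its lower heat capacity, leaving the two fluids nearly equivalent in this
  model. The package reports what the stated physics yields.
* Peak plume speeds during the impulse (~3–9 mm/s) exceed the 0.1–1.6 mm/s
  range read off the published 5-s velocity snapshots; the printed range is
  consistent with the *baseline* convection this model produces
  (~0.1–1.2 mm/s) rather than with transient plume maxima.
* No corneal solid conduction, tear-film evaporation, cavitation chemistry,
  or fluid–structure interaction.

## Worked example

```{r example}
library(phacotherm)
mesh <- generate_mesh(build_ac_geometry(geometry_params()), 4981)
steady <- solve_steady(mesh, "AH")
series <- run_transient(steady,
                        heat_source(1.2, tip_length = sum(mesh$tip_edges$length)),
                        config = solver_config(t_end = 30))
trace_extrema(point_probe(series))
relaxation_time(series, criterion = "probe")

cohort <- generate_cohort(cohort_spec(), seed = 1)
cohort_endpoint_report(cohort)$cell_loss_pct
```
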