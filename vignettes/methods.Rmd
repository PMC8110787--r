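---
title: "Models and methods behind turgorcfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind turgorcfm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

turgorcfm couples two views of the same quantity. The *apparent
stiffness* `k` of a micro-indented cell is the slope of the measured
force--displacement curve, in N/m. It is what the instrument delivers,
and it is **not** a material constant: wall elasticity, turgor pressure
and local geometry all enter it. The package therefore contains (i) the
experimental pipeline that extracts `k` from raw curves and aggregates
it into per-specimen statistics, and (ii) a nonlinear finite-element
model of a pressurized, two-layer closed shell that predicts `k` from
wall moduli and turgor, so the two can be compared.

All units are fixed package-wide: micrometres, micronewtons, MPa.
1 uN/um equals 1 N/m, and 1 MPa·um² equals 1 uN, so no unit conversion
appears anywhere in the code.

## Curve processing

A force curve is a monotone stage-displacement series `z` with measured
forces `F`. Processing has three steps, each exposed on its own:

1. **Contact detection** (`detect_contact_point`). The baseline is the
   mean of the first quarter of the samples; the raw contact index is
   the first of two consecutive samples exceeding the baseline by
   `noise_mult` (default 5) baseline standard deviations. A line fitted
   to the rising flank (up to 60% of the force excess) is extrapolated
   back to the baseline, which removes the upward bias of the threshold
   crossing on noisy data and reduces exactly to the kink for noiseless
   curves.
2. **Slope fitting** (`fit_stiffness`). Least squares of `F` against
   `z` restricted to a *force-fraction* window, by default the upper
   half of the force range, where the response of turgid samples is
   near-linear. The window is a parameter because acquisition software
   conventions differ; what the instrument protocol fixes is the
   maximum force, which is why the window is defined on force rather
   than depth.
3. **Compliance correction** (`correct_compliance`). Sample and
   instrument deform in series, so
   `k_sample = (1/k_measured - 1/k_system)^-1`, with `k_system`
   measured by indenting glass. The correction can only increase the
   stiffness and diverges as `k_measured` approaches `k_system`; a
   measured slope at or above `k_system` is an error, not a value.

When an indentation depth is needed (simulation comparisons), the probe
depth is `z - z0 - F/k_system`: the stage travel minus the contact
point minus the deflection the instrument chain absorbed.

## Per-specimen statistics

Raw stiffness populations of pollen grains scatter enormously between
grains while the *ratio* of colpus (intine) to exine stiffness within
one grain is stable. `per_grain_ratio` therefore averages the two
regions per grain and takes the quotient, and all population work is
done on these ratios. `summarize_population` fixes the quantile
convention to linear interpolation (R type 7). `normality_test` is a
Shapiro--Wilk omnibus test, with the method name carried in the output
so reports are self-describing. `compare_groups` runs an F-test on the
variances at alpha = 0.05 to choose between the pooled and Welch forms
of the double-sided two-sample t-test; both forms can be forced when a
fixed protocol is wanted.

## The pressurized two-layer shell model

The wall of the model grain is an ellipsoid of revolution (unpressurized
axes 128 x 97 um) carrying an inner intine layer (1.5 um, modulus
`E_i`) and an outer exine layer (0.5 um, `E_e`), with the exine absent
over the colpus band. The colpus is a band of angular half-width 25
degrees around the meridian through the indentation site, terminated at
85% of the major semi-axis; both numbers are configuration knobs since
real colpus geometry varies. The exposed colpus surface sits one exine
thickness below the surrounding surface.

**Elements.** Each surface triangle is extruded along the outward
normal into one 6-node wedge (prism) per layer, so in-thickness
compression of the wall is representable -- the reason to prefer solid
elements over classical shell elements at these thickness-to-probe
ratios. Kinematics are total-Lagrangian with Green--Lagrange strain;
stress is linear in strain (St. Venant--Kirchhoff). Two numerical
choices make the linear prism usable at shell slenderness:

* transverse shear strains are assumed constant in-plane (sampled at
  the element centroid in the covariant frame), which removes
  transverse shear locking;
* the default constitutive option (`law = "shell"`) uses the
  plane-stress-condensed in-plane law plus an uncoupled thickness
  modulus in a local shell frame, which removes Poisson thickness
  locking while keeping a finite in-thickness stiffness. The fully
  coupled 3D law (`law = "stvk3d"`) is available for comparison.

A flat cantilever strip and the closed-form point-load stiffness of a
thin sphere, `k = 4Et^2 / (R sqrt(3(1-nu^2)))`
(`reissner_stiffness`), serve as element benchmarks; the sphere check
converges monotonically from above (about +17%/+8%/+3% at
6k/12k/24k surface triangles).

**Loads and solver.** Turgor is a follower pressure on the inner
surface, ramped in load steps; the tangent includes the pressure load
stiffness, and since the pressure of a closed surface is conservative
the Jacobian is symmetrized and factorized by sparse Cholesky (LU as
fallback). Newton iterations use a backtracking line search on the
residual norm, tolerance 1e-6 relative, with load-step halving (floor
1/16) on divergence. Rigid-body motion during inflation is removed by a
minimal 3-2-1 nodal constraint; the Dirichlet clamp of the bottom half
(relative to the indentation axis) is applied afterwards, at the
indentation stage, holding those nodes at their inflated positions.

**Contact.** The probe is a rigid sphere of radius 1 um (the physical
tip diameter is below 2 um) continued by a coaxial cylindrical shaft,
so indentation depths beyond one radius remain geometrically sensible.
Contact is a frictionless node-to-surface penalty with stiffness 100x
the largest layer membrane stiffness `E*t`, C1-regularized over a 20 nm
gap so nodes entering and leaving contact do not destabilize the
iteration. The contact Jacobian keeps only the normal-gap term (the
tangential curvature term is omitted to preserve positive definiteness;
the exact residual plus line search absorbs the approximation). A
penetration check is implicit in the penalty scale: worst-case
penetration at 10 uN nodal force is below 1% of a depth step.

**Meshing.** The structured latitude/longitude triangulation is graded
by a density function with two flat-top refinement patches around each
indentation site: a wide patch (default 8 um) resolving the bending
boundary layer and a sharp sub-probe patch (2.5 um, ~0.25 um spacing)
so several nodes share the contact load. Meridian 0 and 180 degrees and
the equator are grid lines, so both sites are exact vertices.

**Outputs.** `inflate` reports the displacement field, per-element
Cauchy stress (computed as `F S F^T / J`), enclosed volume and the
convergence history. `indent` returns the depth--force samples;
`apparent_stiffness_at` evaluates the local tangent (central difference
over +/-0.1 um on a monotone spline) or the secant, because reported
stiffness "at a depth" is a tangent-type quantity while total force at
a depth is secant-type; both are exposed. `classify_linearity` fits a
line over 0.1--0.5 um of depth and classifies the curve by the sign of
the mean residual beyond the range midpoint, with a 1% relative
dead-band for "linear".

### Reduced sphere models

`sphere_shell_model` builds a 100 um sphere either as a single wedge
layer (0.5 or 1.5 um) or as bending-free membrane triangles (0.2 um).
The thickness sweep is the diagnostic for which part of a composite
wall is mechanically active: thick solid shells produce *sublinear*
early force curves (bending-plus-flattening), thin membranes
*superlinear* ones (stretching). The wedge variants of this study run
unpressurized, where the bending-vs-stretching contrast is cleanest;
the membrane variant carries a small stabilizing pretension
(P = 0.005 MPa) because a bending-free membrane has no transverse
stiffness at first contact. At working turgor (0.1--0.3 MPa) the
pressure term dominates all three variants and flattens the contrast --
that observation is itself part of the story the reduced models tell.

### Known numerical sensitivities

Finite-depth contact responses at the default pollen mesh (~3000
surface triangles) carry a mesh sensitivity of order 5--10%: the
pressurized bending boundary layer `sqrt(B/T)` is sub-micrometre, at
the edge of what the contact patches resolve. The zero-depth tangent
stiffness (`point_load_stiffness`, probe load spread over a 0.5 um
patch -- a literally nodal load on solid elements has mesh-divergent
local compliance) is the cleaner mesh-convergence probe and changes by
about 2% under mesh doubling at the default sphere resolution. The
reproduction checks of the indentation values therefore use a +/-20%
band; the inflated geometry is the quantity most sensitive to the
modulus assignment, and with the stated parameter ranges the model
inflates by several percent more than the quoted target dimensions
(membrane statics put wall stress at several tenths of the wall
modulus, so strains of that order are unavoidable in any
finite-strain continuum treatment).

## Worm stiffness maps

A nematode held in the trap is idealized as a cylinder; each line of
indentations shares one angular coordinate theta, axial positions are
20 um apart, and successive lines differ by the declared rotation plus
an unknown drift. `assign_coordinates` corrects drift as a
piecewise-constant per-line angular offset, estimated from fiducial
observations (the apparent angle of one fixed anatomical landmark per
line, with line 1 as reference) or supplied directly. `unfold` places
the sites on the sparse (s, theta) rectangle without interpolating
across holes. `band_comparison` takes *supplied* soft/stiff labels by
default -- band attribution is an anatomical judgement -- and offers an
explicit 2-means split that is never applied silently; it reports group
means, the two-sample test, and the mean angular gap between adjacent
band centers of opposite label (about 90 degrees for alternating
muscle/inter-muscle bands).

## Synthetic data

The generators exist so that every stage is testable without an
instrument, and their defaults are the study conditions:

* `curve_gen_spec`/`gen_force_curve`: flat baseline, then slope
  `(1/k_true + 1/k_system)^-1` -- the series-spring law the analysis
  inverts -- plus additive Gaussian force noise (default 0.02 uN,
  a typical capacitive-sensor noise floor at this range). No adhesion
  or hysteresis: approach curves only.
* `population_spec`/`gen_pollen_population`: per-grain exine stiffness
  from an equal-weight two-component normal mixture with components at
  0.7x and 1.4x a base value calibrated so the marginal reproduces
  mean 16.5 and SD 6.6 N/m (the bimodality itself is an assumption --
  only its presence, not its parameterization, is observed); intine =
  ratio x exine with ratio ~ N(0.56, 0.10) in water and N(0.66, 0.10)
  in CaCl2, truncated positive by resampling; measurement replicates
  get 4.8% multiplicative repeatability noise. The within- vs
  between-grain variance split is not observable from the published
  summaries; both knobs are exposed.
* `worm_gen_spec`/`gen_worm_map`: five lines of ten sites, stiff bands
  (0.75 +/- 0.11 N/m) centered at 90 and 270 degrees with 90 degree
  width, soft (0.53 +/- 0.07 N/m) elsewhere; the default rotation
  schedule (0, 90, 180, 270, 315 degrees) yields the 20/30 soft/stiff
  site split. Per-line drift and noisy fiducials exercise the drift
  correction.

What passing the synthetic recovery tests shows is that the pipeline is
an unbiased, correctly-plumbed estimator under the stated noise model;
it does not validate the noise model itself against a real instrument
(no adhesion, no baseline drift, no sensor nonlinearity).

## Problem sizes used in the checks

The reproduction runs use ~3000 surface triangles (about 12,500
degrees of freedom), 10 inflation and 24 indentation steps; a full
inflate-plus-indent cycle takes on the order of one to two minutes.
The thin-sphere oracle check runs a single linearized solve at 12,000
triangles. Pipeline recovery uses 30 grains x 10 curves per replicate;
power checks use the printed group sizes. These sizes were chosen so
the whole verification suite runs on a laptop-class single core in
well under half an hour.

## Limitations

* Single-field displacement elements: no incompressibility treatment
  (nu is 0.3 here; near 0.5 would need mixed elements).
* No viscoelasticity, anisotropy, wall growth, or exine
  micro-ornamentation; no fluid-structure coupling with the acoustic
  trap.
* Penalty contact is frictionless and node-based; tangential sticking
  and surface-to-surface resolution are out of scope.
* The worm is a straight cylinder: no taper or bending of the body
  axis, and band attribution to anatomy is left to the user.
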