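---
title: "Methods: turbulence inlet boundary conditions for post-stenotic RANS"
author: "stenoflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turbulence inlet boundary conditions for post-stenotic RANS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the study design

Truncating a vascular domain at a plane downstream of a stenosis requires
inlet boundary data for the mean flow *and* for the turbulence model. The
package implements a controlled comparison of two ways to supply the
turbulence data to a sub-model cut from a full "ground-truth" simulation:

1. **Turbulence intensity**: constant inlet TKE `k = (3/2)(U I)^2` with an
   assumed intensity `I` (5, 10, 15 %). This is the standard fallback when
   no turbulence measurement exists; `I = 0.16 Re^(-1/8)` gives the
   fully-developed-duct estimate (≈ 5.7 % at Re = 4000).
2. **Mapped TKE**: the TKE profile extracted from the full model on the cut
   plane, optionally degraded through a measurement emulator (voxel
   averaging + Gaussian noise) that mimics a 4D-flow-MRI TKE acquisition.

The study protocol is: solve the full model; extract velocity and TKE
profiles at the stenotic apex and 0.5D / 1.0D distal to it; re-solve the
three sub-models with (a) exactly mapped profiles, (b) intensity-based
turbulence, (c) degraded TKE maps over a 4-voxel-size × 5-SNR matrix; and
compare each sub-model against the full model by MAE of velocity magnitude
and TKE over a post-stenotic region of interest.

Reference conditions: diameter `D = 0.02` m, 50 % diameter severity,
stenosis from 6D to 8D, blood-like fluid (ρ = 1060 kg/m³, μ = 3.5 cP — the
density is widely printed with a kg/m² typo in the source literature),
uniform inlet 0.66 m/s (Re ≈ 4000), inlet intensity 5 %, mixing length
0.0014 m for the full model and 0.000375 m for all sub-models.

## Governing equations and closure

The solver integrates the steady incompressible RANS equations,
`∂U_i/∂x_i = 0` and
`ρ U_j ∂U_i/∂x_j = ∂/∂x_j [ -P δ_ij + 2 μ S_ij - ρ <u_i u_j> ]`,
with the Reynolds stress closed by the Boussinesq eddy-viscosity form and
the standard k–ε model: `μ_t = ρ C_μ k²/ε`, production
`P_k = μ_t (2 S_ij S_ij)`, with constants `C_μ = 0.09`, `C_ε1 = 1.44`,
`C_ε2 = 1.92`, `σ_k = 1.0`, `σ_ε = 1.3`. The body force is zero. Boundary
conditions are: prescribed velocity / k / ε profiles at the inlet, no-slip
rigid walls, zero reference pressure with zero-gradient outflow at the
outlet, and (axisymmetric mode) a symmetry axis at r = 0.

Dimensionality is the major reduction relative to 3-D practice: the domain
is a 2-D planar channel (an axisymmetric straight pipe is available and is
used for verification). The logic of the comparison — sensitivity of the
downstream solution to the inlet turbulence data — is dimension
independent, but absolute error magnitudes are not transferable, so all
acceptance checks are property-based. The 45° out-of-plane bend of 3-D
models is reduced to an optional in-plane rigid bend (default off).

### Wall treatment

Standard equilibrium wall functions replace sublayer integration: wall
shear from the log law `u+ = ln(E y+)/κ` (κ = 0.41, E = 9.8) above the
sublayer crossover `y* ≈ 11.25` and the linear law below; TKE production
in wall-adjacent cells from the wall shear; and a fixed equilibrium
dissipation `ε_wall = C_μ^{3/4} k^{3/2}/(κ y)` imposed in wall-adjacent
cells. Desk-scale grids cannot afford `y+ < 1` resolution, and because the
identical wall treatment is used for the ground truth and every variant,
the boundary-condition comparison stays like-with-like. Wall functions are
least reliable in the accelerating throat (y* of order 10); this produces
a near-wall TKE maximum at the apex that is carried into the mapped
profiles of all sub-models — again identically across compared cases.

## Numerics

* **Discretization**: cell-centred finite volumes on a body-fitted
  structured grid. Grid columns are vertical (constant axial station), so
  east/west faces are orthogonal and only the wall-following north/south
  faces are mildly non-orthogonal (≤ 11° for the 50 % cosine throat);
  diffusion uses the over-relaxed face-normal approximation
  `|S|²/(S·d_PN)`. Convection is first-order upwind implicitly with a
  minmod-limited second-order upwind deferred correction (default; pure
  first-order available for robustness), applied to momentum and to the
  turbulence pair.
* **Pressure–velocity coupling**: SIMPLE on the colocated arrangement with
  Rhie–Chow face interpolation; outlet fluxes are upwinded and globally
  scaled to the inlet mass flux before each pressure-correction solve, and
  the correction is anchored by the outlet Dirichlet `p' = 0`.
* **Linear solves**: the momentum and turbulence systems are relaxed by
  alternating-direction TDMA line sweeps (2 per outer iteration) and the
  symmetric pressure-correction system by Jacobi-preconditioned conjugate
  gradients to a loose inner tolerance (10⁻³ relative). Solving the inner
  systems tightly every outer iteration would cost much and change nothing
  at convergence; fixed sweep and reduction orderings keep every run
  bit-deterministic, which the experiment pipeline relies on.
* **Relaxation**: 0.7 momentum, 0.3 pressure, 0.5 turbulence. The
  turbulence factor is deliberately below the momentum value: with the
  limited second-order scheme the k–ε pair limit-cycles at 0.7 on the
  stenosis case (residuals plateau near 2·10⁻³ indefinitely), while 0.5
  converges in one to a few hundred iterations.
* **Convergence**: normalized L1 residuals,
  `|Ax − b|₁ / (Σ|diag·x| + |b|₁)` per equation (continuity: mass
  imbalance over inlet mass flux), threshold 10⁻⁴ for every equation. Both
  momentum components share the u-equation normalization scale so that a
  machine-zero transverse component reads as converged rather than 0/0.
* **Safeguards**: `k` clipped at 0 and `ε` floored at 10⁻¹² m²/s³ (clip
  counts are reported); `μ_t` capped at 10⁵ μ; divergence (10⁵-fold
  momentum-residual growth) and non-finite fields raise errors carrying
  the convergence report.
* **Verification**: developed laminar profiles reproduce plane Poiseuille
  (centreline/bulk 1.5) and Hagen–Poiseuille (2.0) within 2 % on 24–32
  cells across; global mass imbalance is at round-off on converged runs;
  the throat velocity changes by < 2 % between 1.5× grid refinements at
  the study resolution.

## Mesh and geometry choices

The stenosis wall is a cosine bump (C¹ at the junctions; a smooth-step
variant exists) since the original study does not specify the contour. The
outlet run defaults to 8D — long enough that the zero-gradient outlet does
not influence the 4D-long ROI — and is configurable. Transverse spacing is
a two-sided geometric progression (ratio 1.15 by default) clustered at the
walls; axial spacing is piecewise uniform between "stations" that are
forced onto grid columns (stenosis ends, the three cut planes), with a 2×
refined band around the stenosis. Because sub-model meshes are *slices* of
the full mesh, profile mapping at the default configuration is exact —
node-for-node — and needs no interpolation; resampled mappings interpolate
linearly and apply a uniform flux correction so the compared cases share
the mass flow exactly.

## Inlet construction choices

* **Dissipation**: the mixing-length relation
  `ε = C_μ^{3/4} k^{3/2} / l` with the printed lengths (0.0014 m full
  model, 0.000375 m sub-models, read as metres; 0.0014 = 0.07D is
  consistent with common practice). In mapped mode ε is computed pointwise
  from the mapped (or reconstructed) k — the measurement provides k only.
* **TI-mode velocity**: the velocity profile is mapped in *both* modes by
  default and only the turbulence quantities differ, so that TI-vs-mapping
  differences are attributable to the turbulence boundary condition alone;
  a config switch (`ti_uniform_velocity`) restores fully uniform inlets,
  whose mean is the area-averaged profile velocity so the mass flux still
  matches exactly.

## The measurement emulator

The emulator degrades only the TKE (the velocity profile passes through
untouched): the lumen is tiled by voxels of edge 1/5/10/15 % of the
*reference diameter* (the original, unconstricted D — matching the
source's definition of voxel size — rather than the local cut-plane
lumen); each voxel stores the average of the profile over its in-lumen
extent (intravoxel averaging; the profile is extended linearly from the
outermost face midpoints to the wall, exact for linear data); Gaussian
noise with σ = max(k)/SNR is added independently per voxel; negative
results are clipped to zero (clip counts logged) — clipping, not absolute
value, to avoid inflating low-k regions more than necessary; and the
inlet profile is reconstructed by piecewise-linear interpolation of voxel
values at the inlet face midpoints, clamped non-negative. Replicate seeds
derive deterministically from the root seed and the cell indices, so the
whole study is reproducible from one integer. What this emulator does
*not* model: MRI signal physics (intravoxel dephasing, velocity-encoding
limits), spatial noise correlation, or velocity-map noise — conclusions
about real 4D-flow-MRI data quality are therefore qualitative.

## Comparison metric

Errors are summarized over an ROI from 0.1D to 4D downstream of the
sub-model inlet, full lumen width, on a fixed 64 × 32 bilinear sample
lattice (the source never defines its ROI; the 0.1D standoff avoids
inlet-plane artifacts). Reported per run: MAE and maximum error of
velocity magnitude and TKE, and MAE as a percentage of the ground-truth
field maximum over the ROI. The degradation study reports 3 replicate
noise seeds per (model, voxel, SNR) cell with medians, because single
noisy realizations make trend statements fragile; `--replicates 1`
restores the one-realization protocol.

## Problem sizes

The default configuration targets 48 cells across the diameter (the
refinement check shows < 2 % throat-velocity change between successive
1.5× refinements well below this). The test suite and the acceptance
script run the full study matrix at one third of that (16 cells across,
76 × 16 full-model cells), where the complete 193-run study finishes in
well under a minute; grid-sensitivity checks compare scales 1/3 and 1/2.

## What the desk-scale study shows — and a known floor

At this scale the qualitative structure of the study reproduces: the jet
accelerates to ~2× the inlet velocity through the 50 % throat; sub-models
with exactly mapped boundary data reconstruct the velocity field within
~2–3 % of the ROI maximum; TKE errors grow monotonically with the assumed
turbulence intensity for every sub-model; and degradation errors drop
sharply from SNR 1 to SNR 5 and grow with voxel size in the
noise-dominated regime.

One quantitative feature does not carry over. The protocol maps TKE but
prescribes the inlet dissipation from the fixed sub-model mixing length;
at the mid-expansion cut planes the ground truth's actual dissipation is
several-fold larger than the mixing-length value, so the sub-model's
inlet eddy viscosity is too high and the regenerating shear layer
over-produces TKE for the first few diameters. Re-solving the sub-models
with the ground truth's own ε at the inlet collapses the TKE error from
7–17 % to 2–4 % of the ROI maximum, identifying the protocol
inconsistency — not the discretization — as the cause. In a 3-D
high-Reynolds jet this inconsistency is washed out by dominant shear-layer
production; in the 2-D desk-scale channel the inlet turbulence memory
persists through the ROI. Two consequences are visible in the results and
are reported rather than hidden: the exact-mapping TKE error exceeds a
5 %-of-maximum bound at the 0.5D and 1.0D cuts, and once SNR ≥ 5 the
degradation error sits on this protocol floor, so SNR-trend series
flatten into micro-wiggles there and the mapped-vs-TI-5 % headline margin
is inside the floor.

## Known limitations

Steady 2-D RANS with wall functions: no transition modelling, no
unsteadiness of the post-stenotic jet, Newtonian rheology, rigid walls,
and wall functions outside their comfort zone in the accelerated throat.
The emulator is a statistical, not physical, MRI model. Absolute error
magnitudes are specific to this configuration; the package's claims are
the relative, property-level ones exercised by the test suite and the
acceptance script.
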