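---
title: "Image-to-physics oxygen transport in microvascular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-to-physics oxygen transport in microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascox)
```

## The problem

Microvascular networks grown in organ-chip devices (or imaged in vivo) are
routinely characterized morphologically — vessel coverage, branching,
connectivity — but the quantity that actually matters physiologically is
how well the network delivers oxygen to the surrounding tissue. vascox
turns a 2D image of a vascular network into a physics prediction: a
steady-state oxygen concentration field over both the vessel lumen and the
tissue, plus scalar network-performance metrics.

The pipeline has four stages, each usable on its own:

1. **Imaging.** The fluorescence image is normalized to \[0, 1\] and
   binarized with a fixed threshold (default 0.2, strict inequality, so a
   pixel exactly at threshold is background). Vessel pixels are labeled
   into connected components (8-connectivity by default, matching the
   behaviour of the common labeling routines in image-analysis toolboxes;
   4-connectivity is available). Components touching an inlet image side
   (left/right by default) become the *connected vessel* domain (code 1);
   other components of at least `min_component_px = 10` pixels become
   *disconnected vessels* (code 0.5); everything else is *tissue*
   (code 0). The size filter removes speckle that would otherwise
   produce degenerate, sub-pixel mesh regions.
2. **Meshing.** The three-domain image (plus optional organ sub-regions)
   is converted into one conforming triangular mesh in which every
   element is tagged with its domain.
3. **Transport.** A Galerkin P1 finite-element solve in two phases:
   vessels first, then tissue, coupled through the interface nodes.
4. **Metrics.** Inlet oxygen flux, area-averaged vessel and tissue
   oxygenation, end-to-end connectivity, vessel coverage.

## Transport model

Both phases solve the stationary diffusion(-reaction) equation
$0 = \nabla\cdot(D\,\nabla C) - R(C)$ with linear triangular elements.

**Vessel phase** (connected vessels only). No bulk reaction is assumed in
the endothelium. Boundary conditions:

* Dirichlet $C = C_\mathrm{inlet}$ at vessel nodes lying within half a
  pixel of an inlet image side (default both vertical sides; the
  connectivity metric re-runs with the left side only);
* a constant *outward* wall flux $-D\,\nabla C\cdot\hat n = P_\mathrm{wall}$
  on every vessel–tissue interface edge, representing permeation of
  oxygen out of the network. Each interface edge of length $L$ subtracts
  $P_\mathrm{wall}\,L/2$ from the load vector at its two end nodes (the
  consistent P1 boundary integral). Note this is a prescribed flux, not a
  permeability times a concentration difference; at near-zero vessel
  concentration it can overdraw, which is visible as sub-zero values only
  in pathologically starved geometries.

**Tissue phase** (tissue + disconnected vessels). Solved on the
complement of the connected-vessel domain:

* Dirichlet at the interface nodes, taking the values just computed in
  the vessel phase (one-way coupling; the wall resistance is already
  accounted for by $P_\mathrm{wall}$ in the vessel phase);
* natural zero-flux on the exterior image border — the image frame is
  treated as a symmetry/no-leak boundary, an assumption the user should
  keep in mind for croppings of larger fields;
* disconnected-vessel elements participate with the *vessel* diffusivity
  and no consumption: they act as well-conducting inclusions that
  redistribute tissue oxygen without an inlet supply;
* tissue elements consume oxygen by one of three kinetic modes:
  `none`, `zero_order` (constant rate $R_0$), or `michaelis_menten`
  (rate $R_\mathrm{max}\,C/(K_M + C)$, the default).

Dirichlet conditions are imposed by row replacement, which attains the
prescribed values exactly; the loss of symmetry is irrelevant because a
direct sparse factorization is used (deterministic, no iterative-solver
tolerance in the linear algebra). The pre-constraint operator is retained
so that inlet fluxes can be computed by the residual (reaction-force)
method.

### Parameters and the unit convention

| parameter | default | meaning |
|---|---|---|
| `D_vessel` | 3e-9 | oxygen diffusivity in the vessel lumen |
| `D_tissue` | 2e-9 | oxygen diffusivity in tissue/hydrogel |
| `P_wall` | 2.75e-14 | outward trans-wall flux per unit interface length |
| `C_inlet` | 1.0 | inlet concentration (normalized) |
| `R_max` | 0.06e-12 | maximum consumption rate |
| `K_M` | 1e-3 | Michaelis constant |
| `R0` | `R_max` | zero-order rate when `kinetics_mode = "zero_order"` |

These are the standard literature magnitudes for oxygen transport in
vascularized tissue, quoted in SI units (m²/s, mol/(m²·s), mol/(m³·s),
mol/m³). The solver itself is unit-agnostic — it simply combines the
numbers it is given with mesh coordinates in µm. We deliberately apply
the SI magnitudes over micrometre coordinates rather than converting
lengths to metres. The reason is a scale argument: converting to strict
SI makes both dimensionless groups that control the physics,
$P_\mathrm{wall}L/(D\,w)$ and $R\,L^2/(D\,C_\mathrm{inlet})$, of order
$10^{-6}$ at millimetre image scale, i.e. every field is uniformly
$\approx C_\mathrm{inlet}$ and the tool degenerates into a connectivity
indicator. Applied over µm coordinates the same magnitudes give a wall
drawdown of order 0.1–0.5 across a millimetre of vessel and a tissue
penetration depth of order 100–250 µm — the classical capillary–tissue
oxygenation regime. All reported concentrations are normalized to
`C_inlet`, so the convention cancels from every dimensionless output;
it only sets where the model sits between "no gradients" and "starved".
Users with calibrated data can supply any consistent unit system.

With `C_inlet = 1` and `K_M = 1e-3`, tissue concentrations are almost
everywhere far above $K_M$, so Michaelis–Menten consumption runs near
$R_\mathrm{max}$ except in hypoxic pockets — where it correctly throttles
down and yields higher tissue oxygenation than the zero-order treatment.
That ordering ($C_\mathrm{MM} \ge C_\mathrm{zero}$ nodewise at equal
$R_\mathrm{max}$) is asserted in the test suite.

### Michaelis–Menten: Picard iteration

The nonlinearity is resolved by a semi-implicit Picard scheme: iteration
$k{+}1$ solves the linear system in which the reaction is
$[R_\mathrm{max}/(K_M + C^{(k)})]\,C$ — the coefficient lagged, the
concentration implicit — lumped onto the matrix diagonal with $A/3$ nodal
masses. Keeping the unknown implicit preserves the M-matrix property
(iterates stay positive) and converges noticeably faster than explicit
source lagging. The initial guess is the mean Dirichlet value;
convergence is declared when the maximum nodal change relative to the
field maximum falls below `picard_tol = 1e-6` (cap 100 iterations, error
with the residual trace attached on failure). On the shipped fixtures the
residual decreases monotonically and convergence takes 15–55 iterations.

### Zero-order positivity guard

A constant sink has no intrinsic positivity: tissue far from any
connected vessel would relax to a nonphysical negative plateau. After
each zero-order solve, elements whose three nodal values are all
non-positive have their sink disabled and the system is re-solved (at
most 20 passes). This clips the far field at approximately zero while
leaving the resolvable part of the profile untouched. Sub-pixel boundary
layers (sinks with decay lengths below the mesh resolution) are outside
the scheme's validity and are not defended against.

## Mesh generation

The mesher is a constrained Delaunay triangulator written for this
package (compiled core):

1. Region boundaries are traced along pixel edges and split into chains
   at junctions, so each vessel–tissue interface polyline exists exactly
   once and is shared verbatim by both adjacent domains — this is what
   makes the final mesh conforming, with interface nodes belonging to
   elements of both domains.
2. Chains are simplified by Douglas–Peucker with tolerance
   `simplify_tol = 0.5 * pixel_size` (sub-pixel fidelity; staircase
   diagonals collapse, per-domain area is conserved to well under 2%,
   exactly in the common case).
3. Simplified segments are resampled and the interior is filled with a
   graded point set: the target edge length starts at
   `boundary_spacing = 2 px` on domain boundaries and grows by
   `grad_limit` (default 0.2) per unit distance from the nearest
   boundary, capped so element areas stay below
   `max_area = 25 px² · pixel_size²`. `grad_limit` is thus a mesh-density
   gradient limit: 0.2 means adjacent element sizes change by at most
   ~20%. Interior candidates come from a triangular lattice, thinned and
   jittered by a deterministic integer hash — no RNG, so meshing is
   bit-reproducible.
4. Incremental Delaunay insertion with Lawson legalization; boundary
   segments are recovered by edge flipping (failed recovery triggers up
   to three retries at half the simplification tolerance).
5. Triangles with quality below 0.65 get their circumcenters inserted
   (Delaunay refinement, floor at one pixel circumradius), followed by
   Laplacian smoothing of free vertices with re-legalization; a vertex
   move that would invert an element is halved twice, then abandoned.
6. Triangles are classified by flood fill between constrained edges with
   a majority-area vote of pixel codes, so every element carries its
   domain code and organ label. Organ-region boundaries are traced and
   constrained exactly like domain boundaries, which means adding an
   organ label refines the mesh locally even when the organ's kinetics
   equal the surrounding tissue's (the transport result is unchanged to
   discretization accuracy; the test suite asserts this).

Element quality is the classical shape score
$q = 4\sqrt{3}\,A/(a^2+b^2+c^2)$ — area over squared RMS edge length,
normalized so an equilateral triangle scores 1 and a degenerate one 0,
invariant under uniform scaling. On the synthetic network suite at
`grad_limit = 0.2` the mesher delivers mean qualities of 0.906–0.914 per
image, above the 0.9 threshold conventionally regarded as safe for
accurate P1 solutions; a report flag is raised whenever a mesh falls
below it.

## Synthetic data and what the tests do (and do not) show

`generate_network()` emulates binarized images of self-assembled
microvascular networks: trunks enter from the left/right edges, perform
branching correlated random walks, are dilated to a 4 px vessel width,
and a few isolated elliptical blobs model disconnected fragments. The
defaults — 256×256 px at 5 µm/px (a 1.28 mm field), 20 µm vessels, walk
step 4 px, branching probability 0.08 — were chosen once to represent a
typical organ-chip vasculogenesis field of view. Coverage is controlled
to ±5 percentage points of target by scaling the number of walks.
Generation is seeded and deterministic, and restores the global RNG
state.

The five-band preset (10/25/40/60/75% coverage × 10 seeds, used at
256² in the acceptance checks) reproduces the qualitative behaviour
expected of real network populations: median vessel and tissue
oxygenation rise monotonically with coverage and saturate at high
coverage, while the across-seed variance below 40% coverage is an order
of magnitude larger than above it (coverage says how much vessel there
is, not where it is). Synthetic walks do not reproduce real
anastomosis statistics, lumen diameter distributions, or imaging noise —
so passing tests demonstrate correct physics and robust meshing on
realistic morphology, not biological calibration.

Independent verification uses two oracles that never touch the FEM code
path: a 5-point finite-difference discretization of the same
boundary-value problems on the pixel grid (agreement within 2% relative
L2 on channel/slab fixtures), and closed forms — the linear profile for
pure diffusion (reproduced to solver tolerance) and the slab parabola
$C_0 - (R_0/2D)\,x(L-x)$ for zero-order consumption (within 1%).

## Metric definitions and open choices

* **Total flux**: net inlet influx by the residual method (sum of
  reaction forces at inlet Dirichlet nodes) — a conserved, well-defined
  quantity that equals wall outflux plus consumption at steady state
  (asserted to 1%). The raw interface outflux
  $P_\mathrm{wall}\times$ interface length is reported alongside.
* **Vascular oxygen / oxygen delivery**: element-area-weighted means of
  the normalized concentration over the connected-vessel and
  tissue+disconnected domains respectively (element value = mean of its
  nodes; the difference from nodal weighting is $O(h^2)$).
* **Connectivity**: with the left edge as the only inlet, the
  length-weighted mean normalized concentration over vessel boundary
  edges on the *right* image edge. Where exactly an "end-to-end"
  line-average should be taken is genuinely open; the right-edge
  definition is the most literal reading of end-to-end transport, it is
  0 by construction when no left-fed vessel reaches the right edge, and
  1 for an unobstructed channel. Batches of synthetic networks give the
  expected strongly right-skewed, near-bimodal distribution.

## Problem sizes and determinism

The shipped tests run channel/slab fixtures at 120×80 px, small networks
at 64–128 px, and the acceptance checks at the full 256² study
conditions (10 meshes for quality, 50 full solves for the coverage
trend); a 256² network solve takes a few seconds. Everything in the
pipeline is deterministic: meshing uses hash-based sampling, the linear
algebra is a direct factorization, and all synthetic randomness is
seeded per spec.

## Known limitations

* 2D, unit thickness, stationary: no convection, no time stepping, no
  3D — the intended regime is diffusion-dominated microvascular
  transport (Péclet around or below 1).
* One-way vessel→tissue coupling with a prescribed constant wall flux;
  no oxygen–hemoglobin carriage.
* The interface Dirichlet hand-off (tissue takes the vessel edge value)
  is not flux-consistent with the prescribed wall flux; it reproduces
  the standard formulation for this class of image-to-physics solvers
  and the conservation error is monitored by the residual balance test.
* Disconnected vessels influence oxygenation only through the tissue
  phase (passive conductors); they receive no inlet supply.

## A worked run

```{r example, eval = FALSE}
img <- generate_network(network_spec(seed = 3, target_coverage = 30))
dom <- classify_domains(binarize(gray_image(img$pixels, img$pixel_size)))
sol <- solve_full(dom)                       # mesh + vessel + tissue solve
transport_metrics(dom, image_id = "net3")    # one-row performance summary
```

See the README for the numbers this prints and how to reproduce the
acceptance quantities with `scripts/acceptance.R`.
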