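---
title: "Methods: dynamically triangulated vesicles with active filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamically triangulated vesicles with active filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the numerical methods, conventions and validation
strategy behind **trivesicle**. All quantities are in reduced units:
bead diameter `sigma = 1`, thermal energy `k_BT = 1`, bead mass `m = 1`,
so the time unit is `tau = sigma * sqrt(m / k_BT)`.

## 1. Membrane model

The membrane is a closed, genus-0 triangulated surface with `N_v`
vertices, `N_l` edges and `N_t = 2 (N_v - 2)` triangles satisfying the
Euler identity `N_v - N_l + N_t = 2`. The `tri_mesh()` constructor
validates closure (every edge shared by exactly two triangles), global
outward orientation (positive signed volume), *local* orientation
consistency (each directed edge must appear exactly once — a check added
after a locally mis-wound mesh passed the global tests and corrupted a
flip-energy oracle), index ranges and non-degeneracy.

The potential energy is

* **Bending**: the Helfrich energy `2 kappa * integral(M^2 dA)` with the
  discrete mean curvature `M_i` from the cotangent Laplacian and Meyer
  mixed vertex areas `A_i`; the discrete energy is
  `2 kappa * sum_i M_i^2 A_i`. For a fine icosphere this converges to
  the continuum `8 pi kappa` (acceptance criterion: within 1%).
* **Area / volume constraints**: `U_X = k_X (X - X_0)^2 / (2 X_0)` for
  `X in {A, V}` with exact analytic gradients.
* **Tether bonds** on mesh edges: a two-part harmonic that is repulsive
  below `r_rep = 0.8`, attractive above `r_att = 1.2`, and exactly zero
  in the dead zone between — the standard tether potential keeping edge
  lengths bounded while leaving room for flips.
* **Self-avoidance**: half-harmonic repulsion between non-bonded vertex
  pairs closer than `sigma_vv`, evaluated with a cell grid (a brute-force
  reference implementation backs the unit tests).

**Bending forces by local finite differences.** The Meyer mixed-area rule
is piecewise (obtuse triangles switch formulas), so the exact analytic
gradient of the discrete bending energy is discontinuous at the switch
surfaces. Instead the forces are centered finite differences of the
*exact* energy restricted to the local stencil (the vertex and its
1-ring), step `fd_h = 1e-5`. This is O(N) per evaluation and agrees with
dense numerical gradients to better than `1e-8` relative in the tests;
the acceptance threshold is `1e-5`.

## 2. Membrane fluidity: bond flips

A Metropolis Monte Carlo sweep attempts to flip the diagonal of the quad
formed by each edge's two adjacent triangles (frequency `omega` per time
unit, per-edge attempt probability `q`). The energy change is computed
*locally*: bending over the four quad vertices, area/volume from the two
retriangulated faces, and the bond term from the swapped diagonal. The
unit tests verify local-vs-global agreement to `1e-9` on every flippable
edge and exact restoration of the face set when the new diagonal is
flipped back. Flips preserve `N_v`, `N_l`, `N_t` and the Euler identity
by construction, and every sweep output is re-validated by the
constructor.

## 3. Filaments

Each filament is a bead-spring chain: harmonic bonds
`k_fb (r - r_0)^2 / 2`, harmonic angles `kappa_f (theta - pi)^2 / 2`,
and a tangential propulsion force of magnitude `f_p` per bead directed
along the local chain tangent (the tail bead either driven along its
incoming bond, `tail_mode = "drive"`, or left passive, `"free"`).
Dimensionless controls: Peclet number `Pe = sigma f_p / k_BT`, stiffness
ratio `chi = kappa_f / kappa`, rescaled contour length
`L = (r_0 (N_bf - 1) + sigma) / sigma`, and concentration
`phi = N_f N_bf (sigma / 2R)^3`. Filament–membrane and
filament–filament excluded volume use the same half-harmonic repulsion
as the membrane self-avoidance.

## 4. Dynamics

All beads and vertices follow underdamped Langevin dynamics integrated
with the GJF (Gronbech-Jensen/Farago) scheme:
`b = 1 / (1 + gamma dt / 2m)`, `a = (1 - gamma dt / 2m) b`, Gaussian
noise with variance `2 gamma k_BT dt` shared between the position and
velocity updates. At `gamma = 0` the scheme reduces to velocity Verlet;
the acceptance tests verify energy conservation to `1e-4` relative over
`1e5` steps and, with the thermostat on, equipartition of bead
velocities within 5%. Deflation to a target reduced volume is done by
linearly ramping `V_0` during a burn-in phase (a sudden deep quench can
collapse the mesh). Three independent RNG streams (thermostat, flips,
initial placement) are derived from one master seed so runs are
bit-reproducible.

## 5. Shape analysis

* **Reduced volume** `v = 6 sqrt(pi) V / A^(3/2)` (1 for a sphere).
* **Membrane asymmetry** `da = integral(M dA) / (2 sqrt(pi A))`
  (1 for a sphere, larger for elongated shapes, below the sheet branch
  for cups).
* **Reference models**: the capped cylinder (tube) and toroidal-disc
  sheet have closed-form `A, V, v, da` as functions of their aspect
  parameters; `reference_asymmetries()` inverts `v -> da_T, da_S` by
  root-finding. `reference_table()` reproduces the published nine-point
  table: the tube row matches the printed 2–3 significant digits; the
  sheet row printed values sit ~0.7–1.2% below the direct evaluation of
  the closed forms (documented offset; the acceptance tolerance is a 1%
  row-level relative difference).
* **Shape index** `alpha = da / da_T(v)` is ~1 for tubes, >1 for pearled
  tubes, well below 1 for cups; `classify_shape()` applies banded
  thresholds between the sheet and tube branches.

## 6. Junction counting and turnover

There is no canonical algorithm for counting tube junctions on a
deforming triangle mesh, so the package implements a radius-adaptive
skeletonization chosen for robustness:

1. Poisson-disk seeding: vertices are accepted as skeleton seeds when at
   least `spacing = 2.4 * radius` from every previous seed (just above
   the tube diameter, so one node per cross-section ring); `radius`
   defaults to `2V/A`.
2. Lloyd-style relaxation: vertices are assigned to the nearest node,
   nodes move to their cluster centroids (pulling them onto the
   centerline), and node pairs closer than `0.9 * spacing` merge.
3. Node adjacency from mesh edges spanning clusters (with a proximity
   fallback for fixture meshes assembled from disjoint tube pieces);
   the junction count is `J = sum(max(degree - 2, 0))` over nodes of
   degree >= 3. Disconnected or cyclic skeletons set a `low_confidence`
   attribute — in particular, non-tubular (cup/sphere-like) shapes do
   not admit a meaningful curve skeleton and their `J` should not be
   read as a junction count.

The fixtures give exactly `J = 0, 1, 2` for straight, Y- and H-tubes,
invariant under rigid motion and mesh refinement. `turnover_rates()`
counts persistent level changes of `J(t)` (a change must survive a
persistence window to count; multi-level jumps count multiply) and
reports emergence, retraction and total rates `r = r_e + r_r`.

## 7. Membrane tension

The virial estimator averages per-vertex stresses:
`lambda_bar = < (V_i + 2 k_BT) / (2 A_i) >` with `V_i` the per-vertex
virial of the **constraint + bond** forces only (bending acts normal to
the surface; the repulsion term is available behind an
`include_repulsion` switch). Sign conventions, fixed by two oracles:

* the area/volume constraint term uses the mechanical form about the
  mesh centroid, so a pressurized sphere reproduces the Laplace tension
  `P R / 2`;
* the bond term enters with the gradient sign (internal pair forces
  enter a tension estimate with the opposite sign of external loads), so
  a uniformly pre-stretched spring network recovers the 2D network
  tension `sum(t_e r_e) / (2 A)` — verified to machine precision.

The diagnostic `mesh_bond_forces()$edge_virial` reports the plain
mechanical pair virial `-U'(r) r` per edge. The reference scale is
`lambda_0 = R^2 k_BT / (pi sigma^4)`; ratios well below 1 mark the
floppy regime.

## 8. Validation scales and honest limits

The shipped tests are sized for a ~25 minute single-CPU budget:

* force/energy oracles on 42–2562-vertex meshes (dense finite
  differences, flip local-vs-global, tetrahedron and stretched-network
  virials);
* energy conservation over `1e5` steps on a 42-vertex icosphere;
* equipartition/Boltzmann statistics on a 162-vertex passive vesicle
  with three short chains, `gamma = 2` to shorten correlation times
  (the bond-length and bending-angle moments are compared against the
  `r^2`-weighted Gaussian and Rayleigh forms);
* the dynamic-regime criterion runs the exact study conditions
  (`v = 0.25`, `phi ~ 2.55%`, `Pe = 3.75`, `chi = 25`, `L = 6.12`) on a
  642-vertex vesicle for 8 + 16 time units. At that time scale the
  vesicle deflates into a cup and the tension ratio settles in the
  floppy 0.08–0.22 band; the full branched-tube regime (junction counts
  in the 1–5 band, emergence fraction ~0.5) develops over
  hundreds-of-tau trajectories ("hours on one CPU") and is exercised
  through the `exec/trivesicle` CLI at user-chosen scale rather than in
  the test suite.

Default parameters not fixed by the study conditions (`k_b = 80`,
`l_0 = 1`, `r_rep = 0.8`, `r_att = 1.2`, repulsion stiffnesses 200,
`k_A = k_V = 250`, `kappa = 20`, `gamma = 1`, `dt = 1e-3`, `omega = 10`,
`q = 0.3`) are field-typical values for tethered-membrane simulations;
all are overridable through `model_params()` / `run_config(...)`.
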