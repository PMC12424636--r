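---
title: "Morphoelastic simulation of epithelial folding through a smooth-muscle lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelastic simulation of epithelial folding through a smooth-muscle lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological question

Embryonic reptile lungs fold a smooth epithelial shell into a honeycomb of
gas-exchange cavities (faveolae). The epithelium is wrapped by a mesh of
smooth muscle that leaves open holes; folding happens when the epithelium is
pushed outward through those holes. Two physical mechanisms can do the
pushing: luminal fluid pressure inflating the shell (a "stress ball" squeezed
through a net), or growth of the epithelium itself, which must buckle outward
because the stiff lattice blocks in-plane expansion. `faveosim` implements a
three-dimensional finite-element model of both mechanisms and the
morphometric readouts (aspect ratio, epithelial thickness, per-hole
protrusion amplitude) used to tell them apart.

## Model

### Kinematics and growth

A material point $X$ of the reference configuration maps to
$x(X) = X + u(X)$ with deformation gradient $F = I + \nabla u$. Growth is
modeled by the multiplicative decomposition $F = F_e F_g$ with isotropic
growth tensor $F_g = g I$; only the elastic part $F_e = F/g$ generates
stress. A growth factor $g$ applied to an unconstrained body is therefore
stress-free — the body simply scales by $g$ (this invariant is tested).
Growth is restricted to the epithelium region; the muscle keeps $g = 1$.

### Material law

Both tissues are compressible neo-Hookean with energy density

$$\psi(F_e) = \tfrac{\mu}{2}\left(\mathrm{tr}(F_e^T F_e) - 3 - 2\ln J_e\right)
            + \tfrac{\lambda}{2}(\ln J_e)^2, \qquad J_e = \det F_e,$$

with Lamé parameters $\mu = E/2(1+\nu)$ and
$\lambda = E\nu/(1+\nu)(1-2\nu)$. The first Piola–Kirchhoff stress is
$P = \mu(F_e - F_e^{-T}) + \lambda \ln J_e\, F_e^{-T}$; the solver works with
the pull-back $\partial\psi(F/g)/\partial F = P(F/g)/g$ and its consistent
tangent. The default moduli are $E = 1$ (epithelium) and $E = 10$ (smooth
muscle) with $\nu = 0.3$ for both; all quantities are nondimensional
(lengths in shell radii, stresses in epithelial moduli). The incompressible
limit $\nu = 1/2$ is excluded by construction.

### Loads, constraints, discretization

The luminal pressure is a follower load on the deformed inner surface,
pulled back to the reference configuration with Nanson's formula
$n\,da = J F^{-T} N\, dA$. The sign convention follows the outward reference
normal of the *solid*, which on the luminal surface points into the lumen:
a **negative** $p$ inflates, and the study load is $p = -0.2$ (inflation
magnitude 0.2). For linear triangles the consistent nodal load is exactly
$p\,\mathbf{a}/3$ per node, with $\mathbf{a}$ the deformed area vector, so a
centroid evaluation integrates the boundary term exactly; the same closed
form shows the load is the gradient of $p \times$ (enclosed volume), which
is why the assembled follower-load tangent of a closed surface is symmetric.

Rigid translations and rotations are removed by six Lagrange-multiplier
constraints: $\sum_a u_a = 0$ and $\sum_a (X_a - \bar X) \times u_a = 0$.
At convergence of a self-equilibrated load case the multipliers vanish to
solver tolerance (tested at $10^{-8}\times$ the load scale). The
linearized-rotation form drifts from a finite rotation at large deformation;
this is accepted and only affects the (immaterial) gauge.

The domain is meshed with first-order tetrahedra, one quadrature point per
element. Equilibrium is solved by incremental Newton–Raphson: $g$ and $p$
ramp linearly over `n_increments = 20` increments; each increment iterates
to a residual below $\max(10^{-10},\ 10^{-8}\,\|r_0\|)$; a failing increment
(divergence or element inversion) is halved adaptively up to four times.

### Linear algebra

The Newton systems are bordered saddle problems (six dense constraint rows).
A direct sparse LU of the bordered matrix suffers catastrophic fill-in, so
the solver factors the symmetric part of the stiffness with the six rigid
modes removed by a sparse 3-2-1 pinning (supernodal Cholesky), restores the
exact mean/moment constraints through a rank-12 Woodbury correction, and
wraps the whole thing in preconditioned GMRES. When the follower-pressure
Hessian renders a few soft shell modes indefinite the Cholesky factor is
diagonally shifted and acts as a preconditioner; a guarded direct bordered
LU remains as fallback. Every solve is verified against the true residual,
and the whole pipeline is deterministic (fixed assembly order, fixed
orderings), so repeated runs are byte-identical.

## Synthetic geometry

The generator builds the study anatomy in code: a capsule-shaped epithelial
shell (cylinder with hemispherical caps, outer radius 1) with a bonded,
conforming lattice of muscle bands on its outer surface — polar caps,
`n_rings` interior circumferential rings, and `n_longitudinal` meridian
bands — leaving $(n_{\text{rings}}+1) \times n_{\text{longitudinal}}$
rectangular holes. A latitude–longitude surface grid is triangulated
(diagonals chosen by a global smallest-node-index rule), extruded radially
into prisms, and each prism is split into three tetrahedra with the same
index rule, which guarantees a conforming mesh everywhere, including the
epithelium–muscle interface (shared nodes, no contact mechanics). Band
placement snaps to the grid so bands are always at least one element wide.

Default geometry (the study conditions): shell length 4, wall thickness
0.3, five rings and eight meridians of width 0.25 and radial thickness
0.15, edge length 0.2 — 48 holes and roughly half the outer surface
covered. Three of these defaults deserve comment:

* **Wall thickness 0.3.** Pressure-controlled inflation of a compressible
  neo-Hookean shell has a limit pressure that grows with wall thickness;
  the radial benchmark shows shells thinner than about $0.35R$ have no
  equilibrium at the study load $|p| = 0.2$ (they balloon without bound), and
  lattice runs with thin walls invert elements near $|p| \approx 0.11$–$0.15$.
  The model figure of the source anatomy shows a thick-walled shell, and the
  thickness was set to 0.3 so that the stated load is attainable — a
  geometric calibration, documented here, not a fitted parameter.
* **Polar caps.** On a capsule the two poles are always capped by muscle;
  with $k$ covered rings between the caps there are $k+1$ uncovered annular
  rows, so equal ring/hole row counts are only possible with capped poles.
  Five interior rings and eight meridians give the 48-hole lattice.
* **Edge length 0.2.** Under confined growth the epithelium bonded beneath
  the bands is biaxially compressed by $1/g$; past $g \approx 1.5$ this
  exceeds the surface-creasing threshold of a compressible neo-Hookean
  solid. Meshes fine enough to express sub-band wrinkles (edge
  $\lesssim 0.18$) lose quasistatic existence near $g \approx 1.7$–$1.9$
  (elements invert at crease tips); the default resolution deliberately does
  not resolve creasing and follows the smooth solution branch to the full
  $g = 2$, which is the smooth corrugated morphology the scenarios are meant
  to produce. Finer meshes remain available and reproduce the instability —
  a genuine feature of confined-growth mechanics, discussed under
  limitations.

The mesh generator also validates externally supplied meshes
(`validate_mesh()`): positive volumes, exact facet-set cover, luminal facets
owned by epithelium, no duplicated interface nodes, edge-connected regions.
Meshes exchange as Gmsh MSH 4.1 with physical groups
`epithelium`/`muscle`/`luminal`/`external`; results export as VTU/PVD series
readable by standard visualization tools.

## Scenarios and morphometrics

Three presets mirror the study: `pressure_only` ($g = 1$, $p = -0.2$),
`growth_only` ($g = 2$, $p = 0$), and `combined`. The morphometric report
contains:

* **Aspect ratio** — extent of the luminal surface along its principal axis
  divided by the maximal width perpendicular to the axis in the middle 20%
  slab; the axis is fixed from the reference configuration so trajectories
  over a ramp are comparable. For a capsule this is length/diameter.
* **Epithelial thickness** — from each luminal facet centroid a ray is cast
  along the inward normal to the deformed outer epithelial surface
  (Möller–Trumbore); this matches how thickness is read off a 2D optical
  section. Rays that miss (severely folded states) are flagged and excluded
  from summaries with a count. A nearest-point alternative
  (`method = "nearest"`) is available; it never misses but reads a lower
  bound, underestimating thickness on tilted walls, so ray casting is the
  default.
* **Protrusion amplitude** — holes are enumerated by flood-filling the
  uncovered outer-surface facets; per hole, the maximum outward-normal
  displacement inside the hole minus the mean outward displacement of the
  adjacent band-covered surface. Positive values mean the epithelium bulges
  through the hole.
* **Thinning ratio** — mean final / mean initial thickness (1 at rest,
  < 1 for wall thinning).

To compare thinning between mechanisms fairly the two scenarios are matched
at equal deformation: the per-increment trajectories of mean protrusion are
interpolated at the largest level both runs reach, and the thinning ratios
are compared there. This avoids re-solving one scenario at a tuned load and
is deterministic. The model predicts — and the tests assert — that at
matched protrusion the growth-driven route stays markedly closer to a
thinning ratio of 1 than the pressure-driven route: growth folds the
epithelium *without* thinning it, which is the mechanical signature
separating the two morphogenetic strategies.

## Verification strategy

All checks are built from independent oracles:

* central finite differences (with Richardson extrapolation) verify the
  stress against the energy and the tangent against the stress over random
  admissible states of both materials;
* a 1D radial collocation solver (graded grid, load continuation,
  Richardson-checked) provides the spherically symmetric reference for
  inflation and growth of thick shells; its small-strain limit is checked
  against the closed-form Lamé solution, and the 3D solver is checked
  against it at finite strain (2% at the default benchmark resolution,
  improving under refinement);
* analytic invariants: stress-free states, frame indifference, rigid-gauge
  invariance, closed-surface force balance, the $g^3$ volume ratio of free
  growth, and the classical isotropic elasticity tensor as the tangent at
  the grown stress-free state.

Benchmark problem sizes (sphere: edge 0.15 with 4 wall layers, refined
0.12/5; lattice: edge 0.2, ~2200 nodes) were chosen as the coarsest
meshes whose discretization error sits comfortably inside the tolerance
they are tested against; they are package defaults, not tuned constants.

## What the synthetic data do and do not show

The generator reproduces the *relative* anatomy — an elongated closed shell,
a stiffer bonded lattice with open holes, the stated moduli and loads — but
not specimen geometry: no image-derived shapes, no muscle remodeling over
developmental time, no contact (the interface is bonded), no lumen fluid
dynamics, no apical constriction. Passing tests therefore demonstrate the
mechanical sufficiency of pressure or growth to corrugate a lattice-wrapped
shell, and the thinning contrast between mechanisms, under idealized
geometry; they do not quantify real embryonic tissue. The experimental
statistics of the source study (staged specimen measurements and their
t-tests) require dissected-lung raw data and are out of scope.

## Known limitations

* First-order tetrahedra are stiff in bending; coarse meshes underestimate
  displacements (the convergence benchmarks quantify this).
* Load-controlled inflation cannot pass a limit point; near-limit loads
  need thicker shells or a stiffer lattice (see the geometry discussion).
* Confined growth beyond $g \approx 1.5$ is physically unstable to surface
  creasing beneath the bands; the solver follows the smooth branch only at
  resolutions that do not express the creases, and reports a failure with
  the last converged increment otherwise. Arc-length continuation and
  self-contact, which true creasing requires, are not implemented.
* The rigid-body constraint uses linearized rotations; at $g = 2$ the gauge
  can drift from a true rotation frame (immaterial for the reported,
  gauge-invariant morphometrics).
* Isotropic growth only; no anisotropic or surface-restricted growth.
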