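---
title: "Mechano-chemical simulation of sprouting angiogenesis with a meshless RPIM solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-chemical simulation of sprouting angiogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiomech)
```

## The model

`angiomech` simulates sprouting angiogenesis on a 2D square of soft
tissue. Three coupled pieces drive the simulation:

1. **A steady-state VEGF field.** The concentration $\Phi$ of vascular
   endothelial growth factor obeys a Helmholtz-type balance
   $D_x \partial_{xx}\Phi + D_y \partial_{yy}\Phi - g\Phi + Q = 0$ with
   $g = 0$ and $Q = 0$ under the study conditions: the gradient is set
   entirely by essential concentrations — a basal value
   $2.35\times10^{-13}\,\mathrm{g\,mm^{-3}}$ on the capillary lumen and
   $6.43\times10^{-13}\,\mathrm{g\,mm^{-3}}$ in the VEGF release region.
   The basal diffusion coefficient is
   $D = 1.16\times10^{-6}\,\mathrm{mm^2\,s^{-1}}$.

2. **A pressure-to-diffusivity coupling.** A hydrostatic pressure
   (0.0067 MPa, i.e. 50 mmHg) acts on a circular region and decays
   parabolically from its centre: $f = \alpha\,(1 - d^2/r_c^2)$ inside
   the circle and $f = 0$ outside. The local diffusion coefficient
   becomes $D^H = D\,(1 + f)$. Compression carries negative $\alpha$
   (denser medium, slower diffusion), traction positive $\alpha$. At
   $|\alpha| = 1$ the centre coefficient reaches exactly zero under
   compression; at $|\alpha| = 1.5$ it would turn negative — the map is
   then flagged invalid and the assembly refuses it, which reproduces
   the instability reported for that setting.

3. **Tip-cell migration with branching.** Endothelial tip cells climb
   the VEGF gradient: the direction is $\nabla\Phi$ rotated by an angle
   $\theta$ (clockwise-positive rotation matrix), normalised, and
   scaled by the average cell-to-cell distance. A tip branches into two
   children once the distance since its last branch exceeds an
   order-dependent threshold $d_0 \cdot 2^{\,1-\text{order}}$ (orders
   1–3, larger calibre branches less often); inside the compressed
   circle the threshold is halved, which is the mechanism by which
   compression promotes angiogenesis here. Tips stop at the domain
   boundary, on entering the release region, or within half an
   internodal distance of another capillary (anastomosis).

Everything is discretised with the Radial Point Interpolation Method
(RPIM): multiquadric radial basis functions
$R(d) = (d^2 + c^2)^p$ with $c = 10^{-4}$, $p = 0.9999$ plus a linear
polynomial basis, interpolating over the 9–16 nearest nodes of each
evaluation point. The resulting shape functions carry the Kronecker
delta property, so essential values are imposed directly in the rows of
the stiffness matrix. Both field problems — diffusion and plane-stress
elastostatics (used to translate an applied pressure into a local
hydrostatic pressure field when $\alpha$ is not set directly) — are
integrated on a background Gauss–Legendre cell mesh aligned with the
nodal grid.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| domain side | 5 | mm | square tissue patch |
| nodes per side | 51 | — | 2601 nodes, 0.1 mm spacing |
| Gauss order | 3 | — | 9 points per background cell |
| influence-domain size | 16 | nodes | within the advised 9–16 band |
| MQ-RBF $c$, $p$ | $10^{-4}$, 0.9999 | — | optimised values, applied verbatim to mm distances |
| $D$ | $1.16\times10^{-6}$ | mm²/s | basal VEGF diffusivity |
| lumen / release conc. | $2.35/6.43\times10^{-13}$ | g/mm³ | essential values |
| pressure | 0.0067 | MPa | 50 mmHg |
| loaded circle | centre (2.5, 2.5), $r_c = 1$ | mm | radius read off the published sketches; never stated numerically |
| $\alpha$ | 1.0 | — | analysed magnitudes 0.5 / 1.0 / 1.5 |
| step length | 0.1 | mm | one internodal spacing per iteration |
| $d_0$ | 1.0 | mm | branching-law base distance (see below) |
| branch angle | ±30° | — | initial deflection of child tips |
| $\theta$ | 0 or U(−45°, 45°) | — | deterministic ascent / stochastic mode |

**The branching constants are the one genuinely free piece.** The
order law's base distance was calibrated against in vivo data that are
not public, so this package declares its own: candidate values
$d_0 \in \{0.8, 1.0, 1.25, 1.5\}$ mm were compared once on the
Example 1 compression experiment (10 seeds) and $d_0 = 1.0$ mm — which
also keeps control networks visually similar to the published sparse
trees — gave percent responses closest to the reported ones. It was
frozen before the remaining scenarios were evaluated and is fully
configurable.

**The rotation law $\theta$ is not specified in the source
description.** Single simulations default to deterministic gradient
ascent ($\theta = 0$); multi-seed experiments use
$\theta \sim U(-\pi/4, \pi/4)$ per step from a seeded generator so that
seeds differ. Child tips leave a branch point along the parent
direction rotated by ±30°; after their first step they follow the
gradient like any tip.

## What the scenario presets emulate — and what they do not

The four presets place a parent vessel (lumen strip one internodal
spacing thick, carrying the basal concentration) and a release region
per the published sketches: Examples 1–2 run bottom-to-top with one and
two sprouts, Example 3 sends one sprout toward a 1 × 1 mm upper-right
corner release block, Example 4 grows four sprouts from both
horizontal boundaries toward a mid-height release strip. Strip
thicknesses, sprout abscissae and the corner-block size are read
qualitatively off the figures — they are not printed numbers — and all
live in one editable preset table (`angiomech:::preset_table`).

The growth model is deliberately reduced: no endothelial proliferation,
no lumen formation or blood flow, no matrix remodelling, static
loading, and a three-order calibre classification. Passing experiments
therefore show that the *mechanical coupling and branching rules*
produce the reported direction and rough magnitude of effects, not that
the model predicts real vascular morphometry.

## Numerical choices

- **Influence domains** are the 16 nearest nodes (boundary evaluation
  points fall back to fewer, never below 4); ties are broken by
  ascending node id. The tie rule is deterministic but not
  mirror-invariant, which bounds mirror symmetry of solved fields at
  about $10^{-4}$ relative — visible in the symmetry tests.
- **Moment matrices** $G$ are solved per evaluation point by direct
  factorisation; a condition number above $10^{12}$ raises a
  degenerate-geometry error (collinear node sets).
- **Quadrature** is 3 × 3 Gauss per cell by default. Node insertion
  during growth never moves integration points; only the influence
  domains (and hence stiffness contributions) of points near a new
  node are recomputed, and the factorisation is redone on the grown
  matrix each iteration (supernodal Cholesky on the
  essential-reduced, symmetric operator).
- **Patch-test behaviour.** Meshless Galerkin test functions of
  interior nodes do not vanish *along* essential edges (only at the
  boundary nodes), which leaves a boundary-flux inconsistency of order
  $10^{-3}$ that no quadrature order removes; across influence-domain
  switches the interpolation is additionally nonconforming. The
  package therefore (i) offers a variationally consistent boundary
  term (`consistency_edges`) that subtracts
  $\oint \varphi_i D\, \partial_n \varphi_j$ along fully essential
  edges, and (ii) verifies exact linear reproduction on a *conforming
  patch* — a grid small enough that one influence domain spans it —
  where the corrected solve reproduces linear fields to below
  $10^{-6}$. On larger grids the solution error sits at the
  $10^{-3}$ level and is verified against finite-difference and
  series-resistance oracles at the 2% level instead. Recovered
  stresses show the same effect as a 2–5% boundary layer next to
  essential edges while mean stresses match applied tractions to
  better than 0.1%.
- **Degenerate diffusivity.** Compression at $|\alpha| = 1$ drives the
  centre coefficient to exactly zero; the assembly clamps
  integration-point values below $10^{-3} D$ to that floor (with a
  warning) so the operator stays positive definite. Negative values
  (the $|\alpha| = 1.5$ regime) are never clamped — the map is refused.
- **Periodic conditions** are realised by master–slave elimination
  (the slave column is folded into the master). Replacing *both*
  paired rows by the same two-term constraint, as a literal reading of
  the printed equations suggests, makes the system singular; the
  elimination realises the same intent and is cross-checked against a
  Lagrange-multiplier formulation in the tests.
- **Stalled gradients** are declared below an absolute floor of
  $10^{-30}$ plus a relative floor of $10^{-10} \max|\Phi|$: a
  numerically constant field differentiates to roundoff, not to exact
  zero.
- **Duplicate nodes.** Tip positions within a tenth of the internodal
  spacing of an existing node reuse that node, keeping the radial
  moment matrices well conditioned.

## Problem sizes used by the test-suite and experiments

Unit tests exercise the solvers on 6–21 nodes-per-side grids where
independent oracles (5-point finite differences, a hand-assembled Q4
element, Lagrange multipliers, closed forms) are cheap; the
shape-function properties, the two-region interface value and the
experiment pipeline run at the full 51 × 51 study resolution.
Experiments compare loaded versus control arms over 10 seeds with
paired per-seed percent changes, which is more stable at small seed
counts than a ratio of means; the single-seed networks of the first
seed are kept in the report for plotting.

## Known limitations

- Percent responses of the network metrics vary strongly across seeds
  (standard deviations of the same order as the means at 10 seeds);
  the directional conclusions are robust, individual percentages are
  not.
- The traction arm leaves the branching law untouched by design, so
  its metric changes are indistinguishable from noise. Its signature —
  migration drawn toward the loaded region — is crisp at trajectory
  level (deterministic gradient ascent from off-axis sprouts passes
  markedly closer to the circle centre under traction and farther
  under compression), but is masked in whole-network node statistics
  once the ±45° per-step rotation noise is on.
- Anastomosis is purely geometric (half-spacing proximity); no flow or
  pruning follows it.
- The elasticity module is used for the `from-field` $\alpha$ mode and
  verification; the published experiments set $\alpha$ directly, and
  the medium's elastic constants (E = 0.01 MPa, ν = 0.45,
  soft-tissue-like) are package defaults, not published values.
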