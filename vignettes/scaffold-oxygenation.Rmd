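---
title: "Perfusion and oxygenation of channeled hydrogel scaffolds: models, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion and oxygenation of channeled hydrogel scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scaffoldflow simulates filtered blood plasma flowing through a channeled
poroelastic hydrogel scaffold — the configuration used in bioartificial
pancreas devices, where the gel houses transplanted islets and
ultrafiltrate channels are cut through it to carry oxygen — and then asks
the design question: which channel architecture keeps the largest fraction
of the gel above the oxygen level needed for uninhibited insulin
production? This vignette explains the models, the diffuse-interface
numerics, the parameters, and the design decisions that are ours rather
than forced by the problem.

## The coupled flow model

The scaffold occupies a 0.9 x 0.42 cm rectangle (plus two 0.06 x 0.1 cm
outlet stubs below it). Plasma in the channel network `\(\Omega_F\)` obeys
the time-dependent Stokes equations

$$\rho_F \partial_t v = \nabla\cdot\sigma_F, \qquad \nabla\cdot v = 0,
\qquad \sigma_F = -p_F I + 2\mu_F D(v),$$

and the hydrogel `\(\Omega_P\)` is a Biot poroelastic medium: an elastic
skeleton with displacement `\(\eta\)` (Saint Venant–Kirchhoff stress,
Lamé parameters from `\(E = 2.5\times 10^5\)` dyn/cm², `\(\nu = 0.49\)`),
Darcy filtration `\(q = -\kappa \nabla p_P\)` with permeability
`\(\kappa = 10^{-5}\)` cm³·s/g, and the storage equation
`\(\partial_t(c_0 p_P + \alpha \nabla\cdot\eta) + \nabla\cdot q = 0\)`.
A spring term `\(\gamma_E \eta\)` (`\(10^6\)` dyn/cm⁴) stands in for the
out-of-plane elastic support that a 2D slice otherwise lacks; without it,
disconnected gel blocks would drift with the flow.

The two regions are coupled at the channel walls by mass continuity of the
normal velocities, the Beavers–Joseph–Saffman (BJS) tangential slip law
with slip rate `\(\gamma = 10^3\)` g/(cm²·s), and pressure/stress balance.
Flow enters through two inlet segments on the top edge at
`\(v_{in} = 3.5\)` cm/s and leaves through the outlet stubs (zero normal
stress). All quantities are CGS.

## Diffuse-interface formulation

Instead of meshing each channel network exactly, a phase field
`\(\Phi:\Omega\to[0,1]\)` marks the channels (`\(\Phi\approx 1\)`) and the
gel (`\(\Phi\approx 0\)`). Volume integrals over `\(\Omega_F\)` become
`\(\Phi\)`-weighted integrals over the whole domain, integrals over
`\(\Omega_P\)` get `\(1-\Phi\)`, and interface integrals become
`\(|\nabla\Phi|\)`-weighted volume integrals, with the interface normal
`\(-\nabla\Phi/|\nabla\Phi|\)` and tangential projections taken against
`\(\nabla\Phi\)`. Because extended unknowns would otherwise produce zero
matrix rows deep inside the "wrong" region, `\(\Phi\)` is regularized
affinely to `\((1-2\beta)\Phi + \beta\)`; the floor `\(\beta = 10^{-4}\)`
is not printed in the problem statement we implement, so it is exposed as
a parameter and a sensitivity check (halving `\(\beta\)` moves the peak
channel speed by well under 1%) is part of the test suite.

Discretization: MINI elements (P1 + cubic bubble) for velocity with P1
pressure, P1 for the Darcy pressure and displacement, P2 for the oxygen
concentration, backward Euler in time with `\(\Delta t = 10^{-3}\)` s to
`\(T = 1\)` s for the flow (steady state is reached much earlier; the
relative change over the final step is reported as a diagnostic). All
system matrices are time-invariant, so they are factored once (sparse LU
with two-sided norm equilibration — the monolithic blocks span eleven
orders of magnitude) and only back-substitutions run per step.

## Phase-field construction and mesh adaptation

Each architecture is defined by explicit channel polygons on the domain,
calibrated so the channel area between the two horizontal gasket channels
equals the straight-architecture reference (three 0.06 cm verticals,
0.054 cm²) to 1e-6 relative. The sharp indicator is smoothed by an
Allen–Cahn solve (double-well `\(F(\Phi)=2\Phi^2(\Phi-1)^2 - 1/8\)`,
semi-implicit: implicit diffusion, explicit well, lumped mass so the step
is monotone on the non-obtuse bisection meshes used here), and the mesh is
refined by conforming longest-edge bisection where `\(|\nabla\Phi|\)` is
large, with the cycle rasterize–adapt–smooth run twice. Two deliberate
departures from the naive recipe, both motivated by measurable artifacts:

* **Ramp rasterization.** Sampling the 0/1 indicator at mesh nodes has an
  O(h) area bias that does not average out on structured meshes (channel
  edges can sit at a fixed fraction between node columns for *every*
  channel at once, biasing the channel area by several percent). The
  Allen–Cahn initial datum is therefore the indicator softened to a
  one-element linear ramp of the signed distance to the channel boundary,
  which is unbiased to O(h²). `rasterize_indicator()` still returns the
  sharp 0/1 raster.
* **Geometric marking safeguard.** On the first cycle, elements whose
  centroid lies within one diameter of a sharp channel boundary are marked
  in addition to the gradient criterion, because a channel thinner than
  the base grid pitch can otherwise fall between nodes and never generate
  a gradient to refine on.

### The diffuse-layer width is a numerical width, and it matters

The published smoothing pair (`\(D_\Phi = 0.01\)`, `\(T_\Phi = 0.02\)`)
implies a smoothing length `\(\sigma = \sqrt{2 D_\Phi T_\Phi} = 0.02\)`
cm — wider than the narrow (0.02 cm) and hexagonal (~0.016 cm) channels
themselves, which would erase those channels entirely (the double-well
term is negligible over that horizon: its derivative is bounded by 0.39,
a factor `\(e^{-0.08}\)`). The layer width is therefore treated as what
it is — a numerical regularization width, emergent and reportable, not a
study condition — and the default `\(D_\Phi\)` is chosen so that
`\(\sigma\)` sits at the resolution limit of the adapted interface
elements.

The reason to make the layer as thin as the mesh allows is quantitative,
not aesthetic. With `\(\gamma = 10^3\)` the BJS law is within a hair of
no-slip, and in the diffuse form the slip penalty
`\(\gamma\int (v)_{\tilde\tau}(w)_{\tilde\tau}|\nabla\Phi|\,dV\)`
suppresses tangential flow across the *entire* band where
`\(|\nabla\Phi|\)` is appreciable: the Brinkman screening length
`\(\sqrt{\mu_F/(\gamma|\nabla\Phi|)}\)` is of order microns. Each channel
therefore loses roughly the full `\(|\nabla\Phi|\)`-support — about one
interface element plus `\(2\sigma\)` — of effective width per side. A
plane-Poiseuille comparison makes this visible directly: with a wide
layer the channel pressure slope inflates several-fold over the analytic
value and the velocity profile collapses from a parabola toward a
triangle. This effective narrowing is the dominant discretization error
of the method at coarse resolution, and it acts like a uniform reduction
of all channel widths.

## Oxygen transport

On the frozen steady flow, oxygen obeys an advection–reaction–diffusion
equation with blended coefficients `\(u = v\Phi + q(1-\Phi)\)` and
`\(D = D_F \Phi + D_P(1-\Phi)\)` (`\(3\times10^{-5}\)` and
`\(1.3\times10^{-5}\)` cm²/s). Consumption is Michaelis–Menten,
`\(R_{max} c/(c + c_{MM})\)` with `\(R_{max} = -3.4\times10^{-8}\)`
mol/(cm³·s) and `\(c_{MM} = 10^{-9}\)` mol/cm³, gated by a necrosis
switch (no consumption at or below `\(c_{CR} = 10^{-10}\)` mol/cm³) and
confined to the gel by a `\(1-\Phi\)` mask thresholded at 0.5 — the
pointwise switch needs a sharp fluid/gel assignment that the diffuse
setting does not otherwise provide. The reaction enters the right-hand
side lagged at the previous step, so the transport matrix is also
time-invariant and factored once; `\(\Delta t_t = 5\times10^{-2}\)` s to
`\(T_t = 200\)` s. Negative concentrations are never clipped; inside the
saturating ratio they are evaluated as zero so the solve cannot cross the
`\(c = -c_{MM}\)` pole.

Boundary conditions follow the physical narrative: inlet concentration
`\(c_{in} = 2\times10^{-7}\)` mol/cm³ on the inlet segments, zero
concentration on the remaining top boundary, zero diffusive flux at the
outlets and no flux on the remaining exterior. The printed condition
"c = 0 on the exterior fluid boundary" taken literally would clamp the
side and bottom walls too, contradicting the stated no-flux condition on
the poroelastic exterior; we apply it only on the top-wall segments, which
is the reading consistent with both statements. Note the corner where an
inlet (at `\(c_{in}\)`) meets the top wall (at 0) carries a genuine
boundary discontinuity; the concentration min/max reported by
`run_transport()` will show localized under/overshoots there at any
resolution. Advection is discretized in convective form as written; an
optional streamline-diffusion stabilizer exists for coarse meshes (the
coarse pipeline preset enables it, finer presets do not).

## The design metric

For each architecture the package reports
`\(\int \chi_{opt} (1-\Phi)\,dV\)`, where `\(\chi_{opt} = 1\)` wherever
`\(c \ge c_{opt} = 5\times10^{-8}\)` mol/cm³ (closed comparison), both in
cm² and relative to the diffuse poroelastic area `\(\int(1-\Phi)dV\)`,
plus peak channel speed (masked by `\(\Phi > 0.5\)`) and peak Darcy
speed. Under-oxygenated architectures rank low (straight channels leave
most inter-channel gel hypoxic); the hexagonal network ranks highest.

## Inlet layout

The inlet segment positions and widths are not printed in the study we
follow; the package default is two 0.06 cm segments centred over the
outlet stubs at x = 0.225 and 0.675 cm — i.e. each inlet spans the top
opening of the left/right vertical channel of the straight reference
layout. They are `layout` overrides like every other geometric constant.

## Verification strategy

Because no analytic solution exists for the coupled problem, verification
is layered:

* manufactured solutions for each element family (P1 order 2, P2 order 3,
  MINI velocity order ~2, all in L²);
* a plane-Poiseuille oracle for the all-fluid limit (3% on centerline
  speed);
* a classical sharp-interface monolithic Stokes–Biot solver on a two-layer
  rectangle with a flat interface, implementing the interface conditions
  as line integrals on a conforming mesh. The diffuse solution approaches
  it monotonically as the layer thins (width varied through the smoothing
  horizon), with pressure the most sensitive field — the expected
  behaviour for this class of method. The flat benchmark exercises every
  interface term with none of the meshing machinery of a branching
  geometry;
* a well-mixed limit of the transport solver against a high-accuracy
  Michaelis–Menten ODE integration;
* conservation and dissipation properties (zero-data ⇒ zero, interface
  mass balance of the sharp solver, discrete energy decay with
  homogeneous data).

## Problem sizes and resolution presets

The pipeline presets are `coarse` (base grid 0.02 cm), `medium`
(0.015 cm) and `fine` (0.011 cm). The adaptation depth follows the
narrowest feature: two cycles of two bisection passes by default
(interface elements ~4x smaller than the base grid), with a third cycle
added automatically for architectures whose channel width falls below
0.03 cm (narrow, zigzag, hexagonal), so that interface elements stay
below about one fifth of the channel width; element size inside channels
is additionally capped at 0.01 cm so the velocity space can represent the
cross-channel flow profile. The coarse preset produces adapted meshes of
roughly 12–32k triangles depending on architecture and runs a full
architecture pipeline in one to five minutes on one CPU; it is the preset
used by the test suite and by `scripts/acceptance.R`. The quantitative cost of coarseness
is the effective channel narrowing discussed above: wide channels lose a
modest fraction of their cross-section, thin channels a large one, so
coarse runs systematically overestimate channel resistance — most visibly
for the narrow and hexagonal architectures — and shift oxygenation
upward in the wide-channel architectures. The architecture *ordering* is
robust to this; the individual percentages carry several points of
resolution sensitivity.

## What the generator does and does not emulate

The architectures are idealized polygonal networks: evenly spaced
verticals; symmetric two-level bifurcation trees (a parent that splits
into two, each child splitting again — the same topology as the
verification geometry of the sharp-interface literature), with widths
halving per generation and the leaves spread to cover the domain width;
in-phase zigzags; and a regular flat-top honeycomb — all calibrated to
the common channel area. The bifurcating layout deserves a caveat: its
published oxygenation value depends strongly on the (unprinted) tree
density, and plausible two-level reconstructions cluster several points
below it while three-level trees overshoot well above; the two-level
reading is retained as the one the verification-geometry description
supports. Real fabricated scaffolds have
rounded corners, width tolerances and out-of-plane structure; a 2D slice
also cannot capture the front/back-wall boundary layers that reduce
oxygenated volume in 3D. Passing tests on these geometries validates the
solver and the ranking mechanism, not any particular fabricated device.

## Known limitations

* The linear (fixed-domain) coupling ignores channel constriction by gel
  swelling.
* At coarse resolution the diffuse BJS narrowing inflates channel
  resistance; percentages drift with mesh refinement even though the
  ranking is stable.
* The transport boundary discontinuity at the inlet/top-wall corner
  produces localized concentration under/overshoots (monitored, not
  clipped).
* The sharp-interface oracle covers a flat interface only; curved-
  interface accuracy is inferred from the layer-width convergence study,
  not proven.
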