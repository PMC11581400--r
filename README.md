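# scaffoldflow

Finite-element simulation of perfusion and oxygen transport in channeled
poroelastic hydrogel scaffolds, as used in bioartificial pancreas design —
and a quantitative ranking of channel architectures by how much of the gel
they keep oxygenated.

## The problem

An encapsulated bioartificial pancreas is a slab of biocompatible hydrogel
housing transplanted islets, perfused by filtered blood plasma. Oxygen is
the limiting nutrient: gel more than a fraction of a millimetre from a
perfusion path turns hypoxic, and insulin production by the β-cells is
inhibited below an oxygen concentration c_opt = 5·10⁻⁸ mol/cm³.
Ultrafiltrate channels are therefore cut through the gel; the design
question is which channel *architecture* — straight drilled channels,
branching trees, a hexagonal honeycomb network, narrow or zigzag variants,
all with the same total channel area — keeps the largest fraction of the
gel above c_opt.

## The model and method

scaffoldflow couples the time-dependent Stokes equations in the channel
network to the Biot equations (elastic skeleton + Darcy filtration +
storage) in the hydrogel, with mass continuity, Beavers–Joseph–Saffman
tangential slip and pressure/stress balance at the channel walls. The
steady flow field then advects oxygen in an advection–reaction–diffusion
model with Michaelis–Menten consumption, R_max·c/(c + c_MM), gated by a
necrosis switch below c_CR.

The geometry is represented by a diffuse interface: a phase field
Φ ∈ [0, 1] (channels ≈ 1, gel ≈ 0) built by rasterizing each channel
layout and smoothing it with an Allen–Cahn step on a triangulation that is
adaptively refined where |∇Φ| is large. Subdomain integrals become Φ- and
(1−Φ)-weighted volume integrals; interface integrals become |∇Φ|-weighted
ones. One mesh serves every architecture — no interface-conforming meshing.
Discretization: MINI/P1 for Stokes, P1 for Darcy pressure and displacement,
P2 for oxygen, backward Euler in time with factor-once sparse direct
solves. Everything is written in R on top of the Matrix package.

The design metric is the insulin-support area

    area_opt = ∫ χ_opt (1 − Φ) dV,   χ_opt = 1 where c ≥ c_opt,

reported absolutely (cm²) and relative to the poroelastic area ∫(1−Φ)dV.

## A worked example

Run one architecture end to end at the coarse preset (a few minutes):

```r
library(scaffoldflow)

r <- run_pipeline(run_config("hexagonal", resolution = "coarse",
                             output_dir = "out_hex"))
r$report
#>    geometry total_area_cm2 relative_area_pct poro_area_cm2
#> hexagonal       0.204           94.6             0.216
#>    peak_channel_speed_cms peak_darcy_speed_cms
#>                  6.6                 0.55
```

(numbers from a coarse-preset run on one CPU; the exact values shift a
little with resolution). `total_area_cm2` is the gel area kept above the
uninhibited-insulin-production threshold, `relative_area_pct` the same as
a percentage of the gel area — the headline design metric: ~95% of the
hexagonal scaffold supports full insulin production, versus ~8% for plain
straight channels. The output directory holds a VTU
snapshot of all fields (phi, velocity, pressures, displacement, Darcy and
total velocity, oxygen) for ParaView, the metrics as CSV/JSON, and a run
log.

Compare several architectures:

```r
tab <- compare_architectures(c("straight", "hexagonal"),
                             resolution = "coarse")
```

Lower-level entry points (`make_architecture()`,
`build_adapted_phasefield()`, `solve_flow_to_steady()`,
`run_transport()`, `insulin_support_area()`, `line_profile()`, …) expose
each stage; `sharp_interface_reference()` provides the classical
sharp-interface solver used for verification on a two-layer benchmark.

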