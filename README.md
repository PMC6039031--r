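# capnet

Simulation of blood flow and carrier-mediated drug uptake on in-silico
cerebral capillary networks.

Getting a drug into the brain is hard: the blood-brain barrier (BBB) blocks
passive entry, and drugs like L-Dopa — the mainstay of Parkinson's therapy —
only cross via a saturable carrier (the LAT1 transporter). How much drug the
tissue accumulates therefore depends jointly on the microvascular
hemodynamics that deliver it and on the nonlinear transport kinetics that
extract it. capnet is for modelers who want a transparent, fully
reproducible network-scale model of that interplay: it builds calibrated
cubic-lattice capillary beds, solves the blood flow on them, computes
steady-state drug concentrations in blood and tissue, and asks the scaling
question — how coarse a network can you simulate and still predict what a
full anatomical network (10^7 vessels per cm³) would do?

## The model

A 1 cm³ tissue block is the lattice graph G_n: (n+1)³ nodes, 3n(n+1)²
vessels of length 1/n. Vessel radii are Γ(α = 5) distributed with mean
pinned by the tissue:vessel volume ratio B = 30,

    r̄ = 1 / ((n+1) √(3πB)),

so every refinement level holds the same total vessel volume (1/B cm³); at
n = 149 this gives the anatomical capillary mean radius ≈ 3.9 μm. Radii are
reassigned so vessels nearer an entrance/exit are wider (feeding vessels
taper into capillaries).

Flow: Hagen-Poiseuille resistances ΔP = 8μLQ/(πr⁴) with the
Fåhræus-Lindqvist diameter-dependent viscosity
μ(d) = 220e^(−1.3d) + 3.2 − 2.44e^(−0.06 d^0.645) cP (d in μm, hematocrit
45%), Kirchhoff balance at every node, entrances at ΔP mmHg, exits at 0.

Transport, per vessel i (f_i = Q_i/V_i is the transit rate, P_i the
upstream vessels):

    dv_i/dt = −f_i v_i − k₁v_i/(K+v_i) + f_i · Σ_{j∈P_i} V_j v_j / Σ V_j
    B dw_i/dt = k₁v_i/(K+v_i) − k₂w_i

with entrance-fed vessels receiving the constant blood concentration v₀.
The aggregate tissue amount W = B Σ V_i w_i is fitted across grid levels
against the exchange area A by the saturating law W(A) = cA/(d+A) and
extrapolated to W* = W(120 cm²); total flow is extrapolated in log-log
space down to capillary-scale mean radius.

## Worked example

```r
library(capnet)

g <- build_lattice(6, seed = 42)
g
#> <vessel_graph> 343 nodes, 882 edges (lattice n = 6); 24 entrances / 24 exits; side 1 cm
#>   mean radius 83.5 um, total vessel volume 0.03904 cm^3

fl <- solve_flow(g, delta_P = 100)
glance(fl)
#>   delta_P_mmHg total_flow_mL_min n_edges n_stagnant kirchhoff_residual
#> 1          100              18.4     882          0           1.06e-14

st <- steady_state_sweep(fl, transport_params(v0 = 5))
glance(st)
#>   W_uM_cm3 v_min v_max w_min w_max partition n_stagnant
#> 1    0.510  4.96  5.00 0.432 0.435     0.102          0
```

Reading: this coarse 882-vessel network carries 18.4 mL/min at a 100 mmHg
drop (mass-conserving to 10⁻¹⁴), blood leaves barely depleted (4.96 of
5 μM), the tissue equilibrates at w ≈ 0.43 μM everywhere, the cube holds
W ≈ 0.51 μM·cm³ of drug, and the tissue:plasma partition ratio is ≈ 0.10 —
inside the 10-20% measured for L-Dopa by microdialysis.

The full scaling experiment (8 grid levels, 5 replicates each, ~1 min):

```r
res <- run_scaling_analysis(scaling_config(seed = 1))
res
#> <scaling_analysis> levels n = 4,6,8,10,12,14,16,18, 5 replicates
#>   fit: c = 0.5087 uM cm^3, d = 0 cm^2; W* = W(120 cm^2) = 0.5087
#>   extrapolated Q(3.9 um) = 0.005143 mL/min; partition W*/v0 = 0.102
autoplot(res$fit)                        # uptake vs area with fitted law
plot_flow_extrapolation(res$flow_extrapolation)
```

The n = 18 grid already attains essentially all of the extrapolated uptake
W*, i.e. a ~20k-vessel simulation predicts the saturated tissue amount of
the 10^7-vessel network. The extrapolated perfusion is sensitive to the
monotone radius reassignment (it creates a mid-network bottleneck that
steepens the flow-radius scaling); see the methods vignette,
`vignettes/capillary-network-model.Rmd`, for the analysis.

Graphs round-trip through GraphML/JSON/CSV (`write_vessel_graph`,
`read_vessel_graph`), and `inst/cli/capnet.R` exposes
build/flow/steady/profile/scaling subcommands for shell use.

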