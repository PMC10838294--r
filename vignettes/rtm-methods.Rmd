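---
title: "Methods: reactive transport of microbial POC degradation and hydrate formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactive transport of microbial POC degradation and hydrate formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hydrateRTM` simulates a sediment interval deposited at the seafloor and
buried at a constant sedimentation rate. The frame is Lagrangian — the grid
is fixed to the sediment parcel — so with the package's constant-porosity,
no-compaction idealization all advection terms vanish and the interval is a
closed system: no carbon crosses its top or bottom (zero-flux Neumann
boundaries), which makes total tracked carbon an exact invariant and the
single most powerful correctness check on the code.

Carbon moves through six pools per node. Solid POC (`P`) is hydrolyzed into
high-molecular-weight DOC (`H`) at rate `(K_o + K_eh E) P`: a small
pore-water background (`K_o = beta E0 K_eh`) plus a term proportional to the
local extracellular enzyme concentration `E`. Hydrolysis is cell-free —
enzymes act where diffusion has carried them, which is what lets microbes
degrade POC they are physically separated from. Fermenting microbes convert
`H` to low-molecular-weight DOC (`L`) at `K_fm N_f H`, diverting a small
fraction `eps` of the fermented carbon into new extracellular enzymes;
methanogens convert `L` to methane and CO2 at `K_m N_m L`, with a fraction
`gamma_ch4` of the metabolized carbon emitted as methane. Enzymes decay with
half-life `lambda` into a decayed-carbon ledger. Dissolved methane `M`
equilibrates with hydrate: wherever `M` exceeds the local solubility
`C_eq(d)` the excess precipitates (`S` grows), and hydrate re-dissolves
wherever `M` falls below `C_eq` — the local-thermodynamic-equilibrium
assumption, implemented as an exact conservative projection of the node
methane inventory `T = M (1 - S) + c_h S`.

Cell abundances enter as numbers per cm^3 of sediment and are multiplied by
1000 inside the rate laws: concentrations are mmol per litre, so per-cell
rate constants are paired with cells per litre. This pairing is what makes
the published per-cell constants (~1e-21.5 s^-1 for fermentation at the
thick-sand site) quantitatively consistent with the site-scale behavior the
model is asked to reproduce; pairing them with per-cm^3 counts leaves the
sand's integrated fermentation capacity three orders of magnitude too small
to form any hydrate while keeping DOC at observed levels.

## Parameters

| parameter | meaning | unit | default | origin |
|---|---|---|---|---|
| `K_eh` | enzyme-driven hydrolysis | mM^-1 s^-1 | 10^-12.6 / 10^-12.7 | site calibration (thick/thin sand presets) |
| `K_fm = K_m` | fermentation = methanogenesis | s^-1 per cell | 10^-21.5 / 10^-23 | site calibration |
| `beta`, `E0` | background-hydrolysis factor, reference enzyme level | –, mM | 0.01, 0.5 | fixed model constants |
| `lambda` | enzyme half-life | yr | 1e4 | fixed; below ~5 kyr degradation stalls, above ~15 kyr it runs away |
| `eps` | enzyme yield of fermentation | – | 0.025 / 0.0085 per preset (0.01 generic) | calibrated, see below |
| `gamma_ch4` | methane fraction of metabolized C | – | 0.5 (0.75 thin-sand preset) | stoichiometry, see below |
| `D_enz, D_hmw, D_lmw, D_ch4` | effective diffusivities | m^2/s | 2.5e-11, 1e-10, 2.5e-10, 2.5e-10 | porewater compilations x tortuosity, size-ordered |
| `porosity` | shared by mud and sand | – | 0.5 | typical; constant by assumption |
| `grain_density` | for wt% to mM conversion | g/cm^3 | 2.65 | quartz/clay standard |
| `n_sand`, `n_mud` | cell densities | cells/cm^3 | 1e9, 1e6 | subsurface census plateaus |
| `c_ref`, `d_scale` | solubility anchor and depth scale | mM, m | 45/700 and 32/2000 per preset | calibrated stand-in curve |
| `mud_multiplier` | pore-size solubility excess in mud | – | 1.006 (presets), 1 generic | calibrated, see below |
| `c_h` | hydrate carbon molarity | mM | 7623 | structure I: 0.912 g/cm^3, hydration number 5.75 |
| `s_hfz`, `s_top` | HFZ and onset thresholds on S | – | 0.01, 0.05 | reporting definitions, config-exposed |

POC is stored as mM carbon per pore-fluid volume
(`wt%/100 * grain_density * (1-phi)/phi / 12.011 * 1e6`), so 0.5 wt% mud POC
is 1103 mM at the defaults.

## Numerical scheme

Each time step is a three-fractional-step (Strang) update: diffusion of the
four solutes over `dt/2`, the reaction network over `dt`, the equilibrium
hydrate partition, diffusion over `dt/2`, and a final re-projection so every
emitted state satisfies the equilibrium dichotomy (`S > 0` implies
`M = C_eq`; otherwise `M <= C_eq`). The double projection is a conservative
no-flux correction; its cost is negligible and it makes the dichotomy
machine-checkable at every node of every snapshot.

*Grid.* Cell-centered finite volumes (nodes at `dz/2, 3dz/2, ...`). With
zero-flux boundary faces, `sum(field) * dz` is conserved to round-off —
node-centered mirror ghosts are not exactly conservative under uniform
quadrature, and the closed-system tests demand 1e-12.

*Diffusion.* Crank–Nicolson with face conductances `theta D` where
`theta = 1 - S` is the residual fluid fraction (frozen within the step), so
what is conserved is the physical fluid inventory `theta u`. Backward Euler
is available per scenario. The thin-sand preset uses it: at `dz = 5 mm`,
`dt = 20 yr` the mesh ratio `D dt / dz^2` is ~1300 and undamped CN leaves a
standing node-to-node ripple at the sand contact (the package's own
diagnosis of that artifact is the reason the option exists). CN's marginal
undershoots below zero next to sharp fronts are clamped; the run-level
carbon ledger bounds what clamping can inject, and anything beyond 0.1 mM
aborts.

*Reactions.* Explicit midpoint (RK2), second order like the splitting. The
integrator sub-cycles internally whenever `dt` times the fastest rate
constant exceeds 0.1, so coarse-fidelity sweeps remain accurate. Because
`theta` is frozen during the step, the tracked-carbon combination
`P + G + Edec + theta (H + L + E + M)` is a *linear* invariant of the ODE
system and is therefore conserved exactly by any Runge–Kutta step — the
1e-10 per-step conservation test checks bookkeeping, not integrator luck.

*Partition.* Solving `C_eq (1-S') + c_h S' = T` gives
`S' = (T - C_eq)/(c_h - C_eq)`, clipped at 0 (full dissolution; then
`M' = T`). `S' >= 1` aborts as unphysical. When `S` changes, the other
dissolved pools are rescaled by the fluid-volume ratio so their bulk
inventories are untouched. Below the base of the hydrate stability zone
`C_eq = Inf`, which the same formula handles as forced dissolution.

*Degenerate inputs.* Zero-POC columns, zero rate constants, zero
diffusivities, `lambda = Inf`, and all-mud columns (no sand bed) are all
valid and are fixed points or reduced models, covered by tests. Domain and
bed lengths that are not multiples of `dz` snap to the nearest node with a
warning; `t_end` off the `dt` grid takes a shortened final step.

## Calibration of the presets (one-time, frozen)

The published site scenarios pin the geometry, burial rates, POC content,
cell-density plateaus and the star rate constants, but not the solubility
curve, diffusivities, enzyme yield or the depth profile of mud cell
density. These were calibrated once against the target site behavior and
frozen in `scenario_wr313h()` / `scenario_u1325()` and the shipped `.cfg`
files; they are ordinary configuration for any other use.

Three structural choices deserve explanation:

1. **Near-seafloor mud cell densities.** The generic column uses the two
   plateaus (1e9 sand, 1e6 mud). Both presets enable the optional
   exponential decay of mud density from 1e9 at the seafloor toward the 1e6
   plateau (e-folding 200 m thick-sand, 1000 m thin-sand — the thin-sand
   site never leaves the upper few hundred meters where observed counts
   remain high). Without this, mud consumption capacity `K_fm N H` is so
   small that DOC produced in the mud can only be consumed after diffusing
   to the sand, which caps the conversion rate orders of magnitude below
   what any hydrate accumulation requires at the published constants.

2. **Pore-size solubility contrast.** `mud_multiplier = 1.006` raises
   `C_eq` by 0.6% in the mud. This small contrast is the engine of
   hydrate-free-zone growth: mud hydrate equilibrates at slightly higher
   dissolved methane than the sand, so methane continuously drains toward
   the sand contacts, re-precipitating there — which is also why the sand's
   saturation maxima sit at its upper and lower contacts. At 1.0 no HFZ
   develops; at 1.05 the entire mud drains.

3. **Methane yield.** `gamma_ch4 = 0.5` is the canonical
   2 CH2O -> CH4 + CO2 split and the package default. The thin-sand preset
   uses 0.75 (plausible for more reduced organic matter): at 0.5, reaching
   the observed sand saturation requires a conversion rate whose standing
   DOC is roughly twice the observed porewater level. This is a documented
   site-calibration trade-off, not a claimed measurement.

One published behavior is *not* reproduced and deliberately left so: at the
thin-sand site the model's DOC after 400 kyr stays near 1.1–1.4 mM rather
than falling below 1 mM. Sustaining hydrate growth to `S = 0.5` by 1200 kyr
requires a late methanogenesis rate `K_m N L` whose `L` cannot be pushed
lower, because `K_m` and `N` are pinned by the published constants; fits
that do drop DOC below 1 mM starve the sand to `S ~ 0.25`. The shipped
preset reports the honest value.

## What the presets do and do not emulate

The presets emulate idealized end-member columns: one sand bed, uniform
initial POC, constant porosity, no compaction or advection, no sulfate
reduction (the model applies below the sulfate-methane transition), no
CO2-reduction methanogenesis, no hydrate recycling or free gas at the base
of the stability zone, prescribed (not dynamic) microbial populations, and a
linear stand-in solubility curve rather than a full CH4-seawater-hydrate
equation of state. Tests passing therefore demonstrate internal consistency
(conservation, equilibrium, convergence) and agreement with the published
site-scale quantities under these idealizations — not predictive skill for
real margins, where advection, heterogeneous POC and the true solubility
field matter.

## Problem sizes

The frozen presets run 400 nodes x 30,000 steps (thick sand) and 500 nodes
x 60,000 steps (thin sand), about one and two minutes on one core —
saturation changes by well under 1% on further `dt` halving
(self-convergence is part of the test suite). Parameter sweeps default to a
coarsened fidelity (`dz` and `dt` doubled) with the star cell re-run at full
fidelity; sweep tables record the fidelity per point.
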