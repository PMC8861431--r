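---
title: "Models and methods in haptk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in haptk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(haptk)
```

haptk models the tissue pharmacokinetics and bystander killing of a
hypoxia-activated nitrogen mustard prodrug (CP-506) and its reduced
metabolites. This vignette describes the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

## The cellular PK model

A monolayer culture is treated as two well-mixed compartments per
compound: extracellular medium ($C_e$, volume $V_e$) and the summed
intracellular volume ($C_i$, volume $V_i = n_{cells} \cdot v_{cell}$).
For each compound $N$ in the metabolite chain,

$$\frac{dC_e^N}{dt} = -k_{loss}^N C_e^N
  - \frac{V_i}{V_e}\left(k_{in}^N C_e^N - k_{out}^N C_i^N\right)$$

$$\frac{dC_i^N}{dt} = k_{in}^N C_e^N - k_{out}^N C_i^N
  + k_{met0}^{N-1} C_i^{N-1} - k_{met0}^{N} C_i^{N}$$

with first-order membrane transfer ($k_{in}$, $k_{out}$, min^-1^),
chemical loss in medium $k_{loss} = \ln 2 / T_{1/2}$, and intracellular
conversion $k_{met0}$ feeding the next chain member. Only the prodrug's
metabolism is oxygen gated: $k_{met} = k_{met0}\, g(O_2)$ with
$g(C) = 1/(1 + (C/K)^h)$, $K = 0.1$ µM, $h = 2$, so that $g(0) = 1$ and
activation is >99% inhibited above 1 µM O~2~. The gate's functional
form is a modelling choice — the data constrain only "complete
inhibition above 1 µM" — and every quantitative experiment in the
package is run at 0 or ≥200 µM O~2~ where the form is irrelevant.
Metabolite conversion is treated as oxygen-independent chemical
instability.

The default chain is CP-506 → CP-506H (hydroxylamine) → CP-506M
(amine) → CP-506M-Cl~2~ (dichloro-amine) → sink. Branch products
(the diol and dichloro-hydroxylamine species) are inactive or
low-abundance and appear only in the media-stability generator.
Terminal metabolism and all extracellular degradation are routed to
explicit sink states, so the audited mass balance of a simulation is
exactly 1; `mass_balance()` on measured profiles (no sinks) displays
the loss the assay actually sees.

Two closed forms anchor the model and its tests: with no metabolism and
an effectively infinite medium, $C_i/C_e \to k_{in}/k_{out}$ (61.7 with
the reference constants); under anoxia
$C_i/C_e \to k_{in}/(k_{out}+k_{met0})$ (20.6). With the realistic
monolayer geometry (5×10^5^ cells of 2.5 pL under 400 µl) the simulated
aerobic plateau is ~50–60-fold, in line with the measured uptake
ratios. The cell volume is not identifiable from these data and is a
configurable default; because $V_i/V_e \approx 0.3\%$, the fits are
insensitive to it.

### Sequential fitting

`fit_aerobic_uptake()` estimates $k_{in}, k_{out}$ with metabolism
fixed to zero (the gate is closed aerobically); those estimates are
frozen and `fit_anoxic_metabolism()` then estimates the prodrug
$k_{met0}$ together with each observed metabolite's transfer and
instability constants. The objective uses proportional (relative)
residuals, $(pred - obs)/\max(obs, LLOQ)$, because LC-MS/MS error
scales with concentration; censored points (< 0.01 µM) are excluded.
Optimisation is bounded Levenberg–Marquardt on log-parameters with a
small number of seeded multi-starts. The finite-difference Jacobian
step is set to ~1% of each log-parameter (`epsfcn = 1e-4`) so that
steps stay above the ODE/PDE integration noise — with the library
default the optimiser stalls at its starting point.

A practical identifiability note: the metabolite influx constants
($k_{in}$ of CP-506H/M) are poorly identified by monolayer data because
almost all metabolite is formed inside cells; their efflux constants
and instabilities, which control what the assay actually measures, are
recovered well. Only the fitted line's prodrug $k_{met0}$ is updated by
a fit; other lines keep their configured values.

## The diffusion-chamber transport model

Flux across stirred donor / MCL / support membrane / stirred receiver
is one-dimensional diffusion with reaction:

$$\frac{\partial C_e^N}{\partial t} = D \frac{\partial^2 C_e^N}{\partial x^2}
  - k_{loss}^N C_e^N - \varphi\,(k_{in}^N C_e^N - k_{out}^N C_i^N)$$

$$\frac{\partial C_i^N}{\partial t} = k_{met0}^{N-1} C_i^{N-1}
  + \varphi\,(k_{in}^N C_e^N - k_{out}^N C_i^N) - k_{met0}^N C_i^N$$

with $D = D_{MCL}$ inside the cell layer and $D = D_{sup}$ in the
acellular support (where the exchange terms vanish). The metabolic
scaling factor $\varphi$ multiplies the transmembrane exchange terms in
*both* equations, exactly as the model equations are written; it does
not additionally scale $k_{met0}$. The alternative reading (scaling the
metabolic parameters directly) is not implemented because the equations
as printed are unambiguous while the prose is not; since the same
placement is used for generation and fitting, the recovery tests are
unaffected by this choice.

Numerics: method of lines on a uniform grid per layer (default 50
nodes/layer, minimum 20), conservative finite-volume fluxes with
harmonic-mean interface conductance, stiff implicit integration
(`deSolve::lsodes`, rtol 1e-8 for simulation, 1e-6 inside fit loops).
Halving the grid step changes reservoir outputs by <0.5%. The solver is
verified against the analytic two-reservoir slab permeation law — an
exponential approach with rate $(DA/L)(1/V_d + 1/V_r)$ after the
diffusion lag $L^2/6D$ — to better than 1%.

The staged protocol mirrors the fix-then-fit analysis: `D_sup` from
bare-membrane curves; MCL thickness from the ^14^C-urea internal
standard with urea's tissue diffusivity fixed at 3.67×10^-7^ cm²/s;
`D_mcl` from supraoxic curves with cell kinetics frozen; $\varphi$ from
anoxic curves with everything else frozen. Chamber geometry (8.5 ml
reservoirs, 0.6 cm² exposed area, 130 µm support) and the urea support
diffusivity (3.0×10^-6^ cm²/s, small-solute scaling) are defaults the
source experiments do not pin down; the generators embed them in each
dataset's provenance so that fits are always self-consistent, which is
what the recovery tests require.

## The spheroid models

### Continuum surrogate

`simulate_spheroid_gradients()` solves the spherically symmetric
analogue: radial shells carry an extracellular pool per compound (per
unit extracellular volume, diffusing with the tissue coefficient
$D_s$ through the extracellular phase) and one intracellular pool per
compound per cell line. With cellular volume fraction $\varepsilon_c$
(default 0.5) split between activator and target lines,

$$\varepsilon_e \frac{\partial C_e}{\partial t} =
  \varepsilon_e D_s \nabla^2 C_e - \varepsilon_e k_{loss} C_e
  - \sum_{line} \varepsilon_{line} (k_{in} C_e - k_{out} C_i^{line})$$

and each line's $C_i$ follows the monolayer equations. This explicit
phase-volume bookkeeping conserves mass exactly and keeps the
monolayer-derived constants meaningful at tissue density. The medium is
a finite well-mixed compartment (default 100 µl) coupled by boundary
flux; a constant-concentration boundary is available for idealised
runs. Cytotoxic-metabolite exposure (AUC) accumulates per shell and
line as extra states.

### Lattice agent-based model

Cells occupy 10 µm cubic sites. Growth: per-cell exponential volume
growth at the line's doubling time (21.7 h activator, 22.95 h target)
scaled by $O_2/(O_2 + K)$; division at $V_{div}$ = 1000 µm³ into a free
von Neumann neighbour (uniform random) or, when none is free, along the
shortest of the six axial chains to an empty site, shifting that chain
outward by one — the minimal-displacement reading of "cells are moved
radially outward". (A most-radial-direction push was tried first and
produces axis-aligned dendrites; shortest-chain keeps the ball
compact.) Oxygen is solved quasi-statically as a radial
Michaelis-consumption profile; cells below 0.15 µM are tagged and lyse
24 h later, vacating their site. The oxygen consumption default
(30 µM/s per unit cell biovolume) is a configuration knob chosen so a
multi-day spheroid develops a hypoxic core; no quantitative claim
depends on it because bystander exposures are run under clamped anoxia.

Drug exposure runs in a compiled conservative finite-volume kernel: the
extracellular field lives on occupied sites (intercellular fraction
$\varepsilon_e$ = 0.5), empty sites belong to the well-mixed medium,
and all fluxes within a time step use pre-step concentrations so mass
is conserved to rounding at every step. The explicit step obeys the
diffusion stability limit (default 45% of $dx^2/6D_s$, about 0.4 s).
Sites with ≥4 faces open to the medium exchange directly with it: an
isolated cell has no intercellular space, which makes the single-cell
configuration the exact monolayer-ODE limit (verified to <1%).

Lattice and surrogate agree within 15% per radial bin (bins with ≥50
cells; the innermost bins of a discrete ball hold a handful of cells
whose positional quantisation is amplified by the ~600-fold gradient).
Radial profiles bin cells by depth from the volume-equivalent radius
$(3n/4\pi)^{1/3} dx$, which removes the surface-roughness bias of the
discrete ball.

### Kill model

The kill probability is proportional to the intracellular concentration
of the cytotoxic metabolites and zero for the prodrug; integrating that
hazard over the exposure gives per-cell survival
$\exp(-k_d \sum_N \mathrm{AUC}_N)$ with the same $k_d$ for all
metabolites (0.01 µM^-1^min^-1^ in monolayers, 0.0256 in spheroids).
Whether the hazard acts on instantaneous concentration or the survival
on integrated exposure is mathematically the same thing here; the AUC
form is used because it is the hazard integral. The default survival
readout is the expected value (deterministic, stable for acceptance
runs); a seeded Bernoulli mode resolves individual fates for regrowth
simulations and is bit-for-bit reproducible under a fixed seed.

## Synthetic data

Generators replace the wet-lab inputs with seeded draws around the
model truth: multiplicative lognormal noise with 10% CV (an LC-MS/MS
scale assumption; the source assays report only triplicate SEMs),
censoring below the 0.01 µM LLOQ, three replicates or chambers, and
binomial colony counts at 60% plating efficiency for clonogenic data.
Every file embeds its generating parameters and seed in a provenance
header, and identical seeds give byte-identical CSVs.

What passing recovery tests show: the estimation machinery is unbiased
and adequately conditioned *under the stated error model*. What they do
not show: robustness to structured errors real assays have —
run-to-run calibration drift, correlated residuals, partial-volume
artefacts in the intracellular extraction, chamber-to-chamber geometry
variation — nor identifiability of parameters the assays genuinely do
not constrain (metabolite $k_{in}$, the cell volume, the oxygen-gate
shape).

## Problem sizes and defaults used in checks

Recovery checks run 20 seeded replicates of the monolayer experiment
(8 time points, 3 replicates) and 3–20 replicates of each chamber
stage; gradient predictions use the 300 µm, 50%-activator, 20 µM × 4 h
anoxic configuration on a 5 µm radial grid; lattice checks use
spheroids up to ~150 µm radius and 4-day growth from 400 seeded cells,
sizes at which the lattice and continuum answers already coincide to
within the stated tolerances.

## Known limitations

* Lysosomal sequestration is not modelled mechanistically; the large
  cell-uptake factor simply emerges from $k_{in}/k_{out}$.
* Nitro-radical intermediates are lumped into $k_{met0}$.
* The spheroid surrogate assumes uniform viable cellularity; it has no
  necrotic-core porosity correction.
* In vivo plasma PK and microvascular-network geometry are out of
  scope.
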