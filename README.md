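# haptk — spatially-resolved PK/PD for hypoxia-activated prodrugs

Hypoxia-activated prodrugs are inert until one-electron reductases in
severely hypoxic tumour cells convert them into diffusible cytotoxins.
Whether such a drug works depends on quantities no single assay
measures: how fast cells take it up and activate it, how far the
prodrug and its metabolites diffuse through tissue, and how much of the
killing is delivered to *neighbouring* cells that cannot activate the
drug themselves (the bystander effect). haptk implements the full
modelling chain used to answer those questions for the nitrogen
mustard prodrug CP-506 and its reduced metabolites (CP-506H, CP-506M,
CP-506M-Cl₂), for modellers and pharmacologists working with monolayer,
multicellular-layer (MCL) and spheroid data.

The package provides:

* **Cellular PK** — a two-compartment first-order model per compound,

  dCᵢ/dt = k_in·Cₑ − k_out·Cᵢ + k_met0⁽ᴺ⁻¹⁾Cᵢ⁽ᴺ⁻¹⁾ − k_met0·Cᵢ,

  with oxygen-gated prodrug activation (complete inhibition above
  1 µM O₂) and a sequential fix-then-fit protocol
  (`fit_aerobic_uptake()`, `fit_anoxic_metabolism()`).
* **MCL transport** — Fick's second law with reaction across stirred
  donor / MCL / support membrane / stirred receiver,

  ∂Cₑ/∂t = D ∂²Cₑ/∂x² − k_loss·Cₑ − φ(k_in·Cₑ − k_out·Cᵢ),

  and staged estimation of D_sup, L_MCL (via a ¹⁴C-urea internal
  standard), D_MCL and the metabolic scaling factor φ
  (`solve_chamber()`, `fit_support_diffusivity()`, …,
  `fit_metabolic_scaling()`).
* **Spheroid ABM** — a lattice agent-based model (oxygen-limited
  growth, necrosis, division with radial push, compiled
  reaction-diffusion drug transport, per-cell metabolite AUC and
  exp(−k_d·AUC) clonogenic kill) plus a fast spherically-symmetric
  continuum surrogate for radial gradient predictions
  (`grow_spheroid()`, `simulate_exposure()`,
  `simulate_spheroid_gradients()`).
* **Dose-response utilities** — 4-parameter logistic fitting, IC50 as
  the 50%-of-control crossing, surviving fractions, fold ratios.
* **Synthetic data** — seeded generators for every assay the pipeline
  fits (uptake time courses, media-stability decays, chamber flux with
  the urea standard, clonogenic tables), with lognormal noise, LLOQ
  censoring and provenance headers.
* **Pipeline** — `run_pipeline()` chains everything (fit → freeze →
  fit) and writes parameter tables, figure-equivalent CSVs and a run
  log.

## Worked example

Simulate the reference spheroid experiment — a 300 µm-radius 50:50
activator/target co-culture exposed to 20 µM prodrug for 4 h under
anoxia — and read off the intracellular gradients:

```r
library(haptk)

g <- simulate_spheroid_gradients(radius = 300, f_act = 0.5,
                                 C0 = 20, duration = 240, anoxic = TRUE)
g
#> <spheroid_grad> R = 300 um, 50% activators, 20 uM x 240 min, anoxic
#>   CP-506       periphery/centre Ci ratio 1.04e+03
#>   CP-506H      periphery/centre Ci ratio 18.2
#>   CP-506M      periphery/centre Ci ratio 2.87
#>   CP-506M-Cl2  periphery/centre Ci ratio 0.662

penetration_depth(g, "CP-506", fraction = 0.01)
#> [1] 164.9472
```

The prodrug collapses ~1000-fold from periphery to core and is
effectively gone ~165 µm in, while its cytotoxic metabolites fall only
3–18-fold — they out-diffuse their own consumption, which is the
bystander effect in spatial form. The dichloro-amine ratio below 1
means it *accumulates* in the core, marking it as the dominant
bystander metabolite. Parameter recovery runs the other direction:

```r
su <- monolayer_setup()
d  <- gen_monolayer_dataset(su, "aerobic", noise = noise_model(seed = 1))
fit_aerobic_uptake(d, su)
#> <hap_fit>
#>   k_in.CP-506    3.8247 (se 0.164)
#>   k_out.CP-506   0.0637114 (se 0.00375)
#>   fixed: k_met0=0
#>   R^2 = 0.9846 on 48 points
```

i.e. the uptake/efflux constants (true values 3.7 and 0.06 min⁻¹) come
back within a few percent from one noisy triplicate experiment.

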