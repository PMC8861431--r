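## Shared fixtures: small, fast configurations used across test files.

## monolayer setup with effectively infinite medium (no depletion), for
## closed-form steady-state checks
inf_medium_setup <- function(oxygen = 200, duration = 6000) {
  monolayer_setup(medium_volume = 4e5, C0 = 100, oxygen = oxygen,
                  duration = duration,
                  sample_times = c(60, 600, 2000, duration))
}

## a stable one-compound chain (no metabolism, no loss)
inert_compound <- function(name = "X", k_in = 0, k_out = 0) {
  compound_set(compound_params(name, k_in = k_in, k_out = k_out))
}

## reference chain with the prodrug made chemically stable (clean
## conservation checks)
stable_prodrug_chain <- function() {
  cs <- cp506_compounds()
  cs[["CP-506"]]$halflife_extracellular <- Inf
  cs[["CP-506"]]$k_loss <- 0
  cs
}

## small lattice spheroid (~n sites in a compact ball)
small_spheroid <- function(radius_sites = 8, f_act = 0.5, seed = 1,
                           config = abm_config()) {
  n <- round(4 / 3 * pi * radius_sites^3)
  seed_spheroid(n, f_act = f_act, config = config, seed = seed)
}
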