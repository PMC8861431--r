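## Staged estimation protocol for the chamber model:
##   1. D_sup from bare-membrane flux,
##   2. L_MCL from the urea internal standard (urea tissue D known),
##   3. D_mcl from supraoxic MCL flux (cell kinetics fixed, metabolism off),
##   4. phi from anoxic MCL flux (everything else fixed).

.flux_prepare <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time_min", "compartment", "compound",
                  "concentration_uM") %in% names(data)))
  if (is.null(data$censored)) data$censored <- FALSE
  obs <- data[!as.logical(data$censored) & data$time_min > 0, , drop = FALSE]
  if (nrow(obs) == 0L) stop("under-determined: no usable observations")
  obs
}

.flux_lookup <- function(sim_res, obs) {
  key_sim <- paste(sim_res$time_min, sim_res$compartment, sim_res$compound)
  key_obs <- paste(obs$time_min, obs$compartment, obs$compound)
  idx <- match(key_obs, key_sim)
  if (anyNA(idx)) stop("observation grid missing from simulation output")
  sim_res$concentration_uM[idx]
}

## shared single-stage fitting driver over solve_chamber
.flux_stage_fit <- function(obs, simulate_fn, start, lower, upper,
                            lloq = 0.01, multistart = 3L, seed = 1L) {
  residual_fn <- function(pars) {
    sim <- simulate_fn(pars)
    .hap_objective(.flux_lookup(sim$reservoirs, obs),
                   obs$concentration_uM, lloq)
  }
  fit <- .hap_ls_fit(residual_fn, start, lower = lower, upper = upper,
                     multistart = multistart, seed = seed, spread = 0.3)
  out <- .hap_fit_result(fit, obs$concentration_uM)
  est <- setNames(exp(fit$par), names(start))
  pred <- .flux_lookup(simulate_fn(as.list(est))$reservoirs, obs)
  out$r_squared <- .r_squared(obs$concentration_uM, pred)
  out
}

#' Fit the support-membrane diffusion coefficient
#'
#' Estimates `D_sup` from donor/receiver flux curves measured across a
#' bare (cell-free) support membrane. A first-order chemical instability
#' term is included only when `include_loss = TRUE` (the prodrug shows no
#' loss of mass balance on the experimental timescale).
#'
#' @param data Long-format flux data: `time_min`, `compartment`
#'   (`donor`/`receiver`), `compound`, `concentration_uM`, optional
#'   `censored`/`chamber_id`.
#' @param geometry A [chamber_geometry()]; `mcl_thickness` is forced to 0.
#' @param C0 Initial donor concentration, µM.
#' @param compound A single [compound_params()] (defaults to the prodrug).
#' @param include_loss Also estimate a loss rate constant?
#' @param lloq LLOQ used for weighting, µM.
#' @param rtol,atol Forward-solver tolerances.
#' @return A `hap_fit` with estimate `D_sup` (cm^2/s).
#' @export
fit_support_diffusivity <- function(data, geometry = chamber_geometry(),
                                    C0 = 20,
                                    compound = cp506_compounds()[["CP-506"]],
                                    include_loss = FALSE, lloq = 0.01,
                                    rtol = 1e-6, atol = 1e-9) {
  obs <- .flux_prepare(data)
  if (all(obs$compartment != "receiver"))
    stop("under-determined: no receiver signal above the LLOQ")
  geometry$mcl_thickness <- 0
  cs <- compound_set(compound_params(compound$name, k_in = 0, k_out = 0,
    halflife_extracellular = compound$halflife_extracellular))
  times <- sort(unique(obs$time_min))
  simulate_fn <- function(pars) {
    if (!is.null(pars$halflife)) {
      cs[[1L]]$halflife_extracellular <- pars$halflife
      cs[[1L]]$k_loss <- halflife_to_rate(pars$halflife)
    }
    solve_chamber(geometry, transport_params(D_sup = pars$D_sup,
                                             compounds = cs),
                  C0 = C0, duration = max(times), times = times,
                  rtol = rtol, atol = atol)
  }
  start <- c(D_sup = 1e-6)
  lower <- c(D_sup = 1e-9); upper <- c(D_sup = 1e-3)
  if (include_loss) {
    start <- c(start, halflife = 600)
    lower <- c(lower, halflife = 1); upper <- c(upper, halflife = 1e6)
  }
  .flux_stage_fit(obs, simulate_fn, start, lower, upper, lloq = lloq)
}

#' Fit the MCL thickness from the urea internal standard
#'
#' Radiolabelled urea crosses the chamber without instability, uptake or
#' metabolism, so with its tissue diffusion coefficient fixed at the
#' published value its donor/receiver curves identify the MCL thickness.
#'
#' @param urea_data Long-format urea flux data.
#' @param geometry A [chamber_geometry()] (its `mcl_thickness` is the
#'   starting value).
#' @param C0 Initial donor urea concentration (concentration units).
#' @param D_urea_mcl Known urea diffusion coefficient in the MCL, cm^2/s.
#' @param D_urea_sup Urea diffusion coefficient across the bare support,
#'   cm^2/s.
#' @param lloq,rtol,atol As in [fit_support_diffusivity()].
#' @return A `hap_fit` with estimate `L_mcl` (µm).
#' @export
fit_mcl_thickness <- function(urea_data, geometry = chamber_geometry(),
                              C0 = 20, D_urea_mcl = 3.67e-7,
                              D_urea_sup = 3.0e-6, lloq = 0.01,
                              rtol = 1e-6, atol = 1e-9) {
  obs <- .flux_prepare(urea_data)
  cs <- compound_set(compound_params("urea"))
  times <- sort(unique(obs$time_min))
  simulate_fn <- function(pars) {
    geometry$mcl_thickness <- pars$L_mcl
    solve_chamber(geometry,
                  transport_params(D_sup = D_urea_sup, D_mcl = D_urea_mcl,
                                   compounds = cs),
                  C0 = C0, duration = max(times), times = times,
                  rtol = rtol, atol = atol)
  }
  .flux_stage_fit(obs, simulate_fn, start = c(L_mcl = 80),
                  lower = c(L_mcl = 1), upper = c(L_mcl = 2000), lloq = lloq)
}

#' Fit the MCL diffusion coefficient for the prodrug
#'
#' Estimates `D_mcl` from supraoxic MCL flux curves. Cellular uptake
#' parameters (from the monolayer stage) and the layer thickness (from
#' the urea stage) are fixed; the oxygen gate closes metabolism, so the
#' only free quantity is extracellular diffusion slowed by reversible
#' cellular uptake.
#'
#' @param data Supraoxic long-format flux data for the prodrug.
#' @param geometry A [chamber_geometry()] with the fitted `mcl_thickness`.
#' @param params A [transport_params()] carrying fixed cell kinetics,
#'   `phi` and `D_sup`.
#' @param C0 Initial donor concentration, µM.
#' @param lloq,rtol,atol As above.
#' @return A `hap_fit` with estimate `D_mcl` (cm^2/s).
#' @export
fit_mcl_diffusivity <- function(data, geometry = chamber_geometry(),
                                params = transport_params(), C0 = 17.4,
                                lloq = 0.01, rtol = 1e-6, atol = 1e-9) {
  obs <- .flux_prepare(data)
  ## restrict the model chain to the prodrug: no metabolism when supraoxic
  prodrug <- params$compounds[[1L]]
  cs <- compound_set(prodrug)
  times <- sort(unique(obs$time_min))
  simulate_fn <- function(pars) {
    p <- transport_params(D_sup = params$D_sup, D_mcl = pars$D_mcl,
                          phi = params$phi, compounds = cs,
                          line = params$line)
    solve_chamber(geometry, p, C0 = C0, duration = max(times),
                  times = times, condition = "supraoxic",
                  rtol = rtol, atol = atol)
  }
  .flux_stage_fit(obs, simulate_fn, start = c(D_mcl = 3e-7),
                  lower = c(D_mcl = 1e-9), upper = c(D_mcl = 1e-4),
                  lloq = lloq)
}

#' Fit the metabolic scaling factor phi
#'
#' Estimates `phi` from anoxic MCL flux: prodrug depletion in the donor,
#' attenuated receiver breakthrough, and metabolite appearance in both
#' reservoirs. `D_mcl`, `D_sup` and all monolayer-derived cell kinetics
#' are fixed; `phi` scales the transmembrane exchange terms of the
#' tissue-density reaction-diffusion equations.
#'
#' @param data Anoxic long-format flux data (prodrug and any observed
#'   metabolites).
#' @param geometry A [chamber_geometry()].
#' @param params A [transport_params()] with fixed `D_sup`/`D_mcl` and
#'   cell kinetics (its `phi` is ignored).
#' @param C0 Initial donor concentration, µM.
#' @param lloq,rtol,atol As above.
#' @return A `hap_fit` with estimate `phi` (dimensionless).
#' @export
fit_metabolic_scaling <- function(data, geometry = chamber_geometry(),
                                  params = transport_params(), C0 = 17.4,
                                  lloq = 0.01, rtol = 1e-6, atol = 1e-9) {
  obs <- .flux_prepare(data)
  ## drop chain members downstream of the last observed compound: their
  ## dynamics do not feed back on the observed ones
  nm <- names(params$compounds)
  last <- max(match(unique(obs$compound), nm))
  cs <- params$compounds[seq_len(last)]
  class(cs) <- "compound_set"
  times <- sort(unique(obs$time_min))
  simulate_fn <- function(pars) {
    p <- transport_params(D_sup = params$D_sup, D_mcl = params$D_mcl,
                          phi = pars$phi, compounds = cs,
                          line = params$line)
    solve_chamber(geometry, p, C0 = C0, duration = max(times),
                  times = times, condition = "anoxic",
                  rtol = rtol, atol = atol)
  }
  .flux_stage_fit(obs, simulate_fn, start = c(phi = 0.5),
                  lower = c(phi = 1e-4), upper = c(phi = 1), lloq = lloq,
                  multistart = 2L)
}
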