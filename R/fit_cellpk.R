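## Sequential fitting protocol for the cellular PK model:
## aerobic data fix k_in/k_out of the prodrug (no metabolism above the
## oxygen gate), then anoxic data estimate k_met0 of the prodrug plus the
## transfer/instability constants of the observed metabolites with the
## aerobic permeabilities held fixed.

## Long-format observations (time_min, compound, compartment,
## concentration_uM, censored, replicate) -> the subset entering the
## objective, plus a simulator closure on the same time grid.
.cellpk_prepare <- function(data, setup) {
  stopifnot(is.data.frame(data),
            all(c("time_min", "compound", "compartment",
                  "concentration_uM") %in% names(data)))
  if (is.null(data$censored)) data$censored <- FALSE
  keep <- !as.logical(data$censored) & data$time_min > 0
  obs <- data[keep, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no usable (uncensored) observations")
  obs
}

## Predict concentrations for rows of `obs` from a simulation data frame.
.cellpk_lookup <- function(sim, obs) {
  key_sim <- paste(sim$time_min, sim$compound, sim$compartment)
  key_obs <- paste(obs$time_min, obs$compound, obs$compartment)
  idx <- match(key_obs, key_sim)
  if (anyNA(idx)) stop("observation times/compounds missing from simulation grid")
  sim$concentration_uM[idx]
}

#' Fit aerobic membrane transfer constants (k_in, k_out)
#'
#' Under aerobic conditions the oxygen gate closes prodrug metabolism, so
#' monolayer uptake profiles identify the membrane transfer constants
#' alone. `k_in` and `k_out` are estimated for every compound present in
#' `data` (normally just the prodrug) by proportionally weighted least
#' squares against [simulate_monolayer()], with censored points excluded
#' and metabolism fixed at zero.
#'
#' @param data Long-format concentration data: columns `time_min`,
#'   `compound`, `compartment`, `concentration_uM`, optional `censored`
#'   and `replicate`.
#' @param setup The [monolayer_setup()] used for the experiment.
#' @param compounds A [compound_set()]; transfer constants of compounds
#'   absent from `data` are held at their current values.
#' @param line Cell line (metabolism is gated off regardless).
#' @param multistart,seed Multi-start control for the optimiser.
#' @return A `hap_fit` with estimates `k_in.<compound>`,
#'   `k_out.<compound>`.
#' @export
fit_aerobic_uptake <- function(data, setup, compounds = cp506_compounds(),
                               line = cp506_cell_lines()$activator,
                               multistart = 5L, seed = 1L) {
  obs <- .cellpk_prepare(data, setup)
  fit_comps <- intersect(names(compounds), unique(obs$compound))
  if (length(fit_comps) == 0L) stop("no fit compounds present in data")
  free <- c(paste0("k_in.", fit_comps), paste0("k_out.", fit_comps))
  if (nrow(obs) < length(free))
    stop("under-determined: fewer usable points than free parameters")
  times <- sort(unique(obs$time_min))
  ## aerobic: force gate closed by setting oxygen high
  setup_a <- setup
  setup_a$oxygen <- max(setup$oxygen, 200)
  residual_fn <- function(pars) {
    cs <- compounds
    for (cn in fit_comps) {
      cs[[cn]]$k_in <- pars[[paste0("k_in.", cn)]]
      cs[[cn]]$k_out <- pars[[paste0("k_out.", cn)]]
    }
    sim <- simulate_monolayer(setup_a, cs, line, times = times)
    .hap_objective(.cellpk_lookup(sim, obs), obs$concentration_uM, setup$lloq)
  }
  start <- setNames(rep(c(1, 0.1), each = length(fit_comps)), free)
  fit <- .hap_ls_fit(residual_fn, start, multistart = multistart, seed = seed)
  out <- .hap_fit_result(fit, obs$concentration_uM,
                         fixed = list(k_met0 = 0))
  ## goodness of fit on the concentration scale
  est <- setNames(exp(fit$par), free)
  cs <- compounds
  for (cn in fit_comps) {
    cs[[cn]]$k_in <- est[[paste0("k_in.", cn)]]
    cs[[cn]]$k_out <- est[[paste0("k_out.", cn)]]
  }
  pred <- .cellpk_lookup(simulate_monolayer(setup_a, cs, line, times = times), obs)
  out$r_squared <- .r_squared(obs$concentration_uM, pred)
  out$compounds <- cs
  out
}

#' Fit anoxic metabolism with aerobic permeabilities fixed
#'
#' Second stage of the sequential protocol: prodrug `k_in`/`k_out` are
#' frozen at their aerobic estimates and anoxic profiles identify the
#' maximum metabolism rate `k_met0` of the prodrug together with
#' `k_in`, `k_out` and `k_met0` of each metabolite observed in `data`.
#' Unobserved downstream compounds keep their configured constants.
#'
#' @param data Long-format anoxic concentration data (as in
#'   [fit_aerobic_uptake()]), containing prodrug and metabolite profiles.
#' @param fixed A `hap_fit` from [fit_aerobic_uptake()], or a named list
#'   with `k_in.<prodrug>` / `k_out.<prodrug>` entries.
#' @param setup The [monolayer_setup()] (oxygen is clamped to 0).
#' @param compounds A [compound_set()].
#' @param line Cell line whose `k_met0` applies to the prodrug.
#' @param multistart,seed Multi-start control.
#' @return A `hap_fit`; estimates include `k_met0.<prodrug>` and
#'   per-metabolite constants.
#' @export
fit_anoxic_metabolism <- function(data, fixed, setup,
                                  compounds = cp506_compounds(),
                                  line = cp506_cell_lines()$activator,
                                  multistart = 5L, seed = 1L) {
  obs <- .cellpk_prepare(data, setup)
  prodrug <- names(compounds)[1L]
  fx <- if (inherits(fixed, "hap_fit")) fixed$estimates else as.list(fixed)
  kin_p <- fx[[paste0("k_in.", prodrug)]]
  kout_p <- fx[[paste0("k_out.", prodrug)]]
  if (is.null(kin_p) || is.null(kout_p))
    stop("`fixed` must provide aerobic k_in/k_out for the prodrug")
  compounds[[prodrug]]$k_in <- kin_p
  compounds[[prodrug]]$k_out <- kout_p
  mets <- intersect(names(compounds)[-1L], unique(obs$compound))
  free <- c(paste0("k_met0.", prodrug),
            as.vector(t(outer(c("k_in.", "k_out.", "k_met0."), mets, paste0))))
  if (nrow(obs) < length(free))
    stop("under-determined: fewer usable points than free parameters")
  times <- sort(unique(obs$time_min))
  setup_x <- setup
  setup_x$oxygen <- 0
  apply_pars <- function(cs, pars) {
    ## only the fitted line's metabolism is informed by these data;
    ## other lines keep their configured rates
    v <- pars[[paste0("k_met0.", prodrug)]]
    if (is.null(names(cs[[prodrug]]$k_met0)))
      cs[[prodrug]]$k_met0 <- v
    else cs[[prodrug]]$k_met0[[line$label]] <- v
    for (cn in mets) {
      cs[[cn]]$k_in <- pars[[paste0("k_in.", cn)]]
      cs[[cn]]$k_out <- pars[[paste0("k_out.", cn)]]
      cs[[cn]]$k_met0[] <- pars[[paste0("k_met0.", cn)]]
    }
    cs
  }
  residual_fn <- function(pars) {
    sim <- simulate_monolayer(setup_x, apply_pars(compounds, pars), line,
                              times = times)
    .hap_objective(.cellpk_lookup(sim, obs), obs$concentration_uM, setup$lloq)
  }
  start <- setNames(rep(0.1, length(free)), free)
  start[grep("^k_in\\.", free)] <- 1
  start[grep("^k_out\\.", free)] <- 0.3
  fit <- .hap_ls_fit(residual_fn, start,
                     lower = setNames(rep(1e-6, length(free)), free),
                     upper = setNames(rep(50, length(free)), free),
                     multistart = multistart, seed = seed)
  out <- .hap_fit_result(fit, obs$concentration_uM,
                         fixed = list(k_in = kin_p, k_out = kout_p))
  est <- setNames(exp(fit$par), free)
  cs <- apply_pars(compounds, as.list(est))
  pred <- .cellpk_lookup(simulate_monolayer(setup_x, cs, line, times = times), obs)
  out$r_squared <- .r_squared(obs$concentration_uM, pred)
  out$compounds <- cs
  out
}
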