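#' Goodness of fit between predicted and observed surviving fractions
#'
#' Pools matched (line, concentration) records and reports
#' `R^2 = 1 - SSR/SST` on untransformed surviving fractions, pooled and
#' per line.
#'
#' @param predicted Data frame `line`, `C0_uM`, `surviving_fraction`.
#' @param observed Data frame with the same columns (replicates allowed).
#' @return List with `r_squared` (pooled), `per_line`, and the merged
#'   table of residuals.
#' @export
compare_predictions <- function(predicted, observed) {
  m <- merge(observed[, c("line", "C0_uM", "surviving_fraction")],
             predicted[, c("line", "C0_uM", "surviving_fraction")],
             by = c("line", "C0_uM"), suffixes = c("_obs", "_pred"))
  if (nrow(m) == 0L) stop("no matched doses/lines between the two tables")
  per_line <- vapply(split(m, m$line), function(d)
    .r_squared(d$surviving_fraction_obs, d$surviving_fraction_pred),
    numeric(1L))
  list(r_squared = .r_squared(m$surviving_fraction_obs,
                              m$surviving_fraction_pred),
       per_line = per_line,
       residuals = transform(
         m, residual = surviving_fraction_obs - surviving_fraction_pred))
}

#' Run the full staged analysis pipeline on synthetic data
#'
#' Reproduces the fix-then-fit analysis chain end to end on seeded
#' synthetic data generated from the reference parameter truth:
#' monolayer PK fits (aerobic then anoxic), staged chamber fits
#' (D_sup, L_MCL, D_mcl, phi) with upstream estimates frozen, a
#' spheroid gradient prediction with the fitted parameters, and a
#' comparison of predicted vs "observed" (synthetic) spheroid co-culture
#' survival. Artefacts (parameter JSON, figure-equivalent CSVs, run log)
#' are written under `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stage derives its own seed from it.
#' @param compounds Generating truth (and the fit starting structure).
#' @param lines Cell-line panel.
#' @param survival_C0s Doses for the spheroid survival comparison, µM.
#' @param spheroid_radius Radius of the gradient-prediction spheroid, µm.
#' @param quick Reduce problem sizes (coarser sampling) for smoke tests.
#' @return List with all stage fits, the gradient summary, the survival
#'   comparison, and `paths` of the written artefacts.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         compounds = cp506_compounds(),
                         lines = cp506_cell_lines(),
                         survival_C0s = c(0.1, 0.3, 1, 3),
                         spheroid_radius = 300,
                         quick = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    ## no wall-clock stamps: the log must be byte-identical across
    ## reruns with the same seed
    log <<- c(log, sprintf(...))
    invisible(NULL)
  }
  say("pipeline start, master seed %d", seed)

  ## -- stage 1: cellular PK ------------------------------------------
  su <- monolayer_setup()
  d_aer <- gen_monolayer_dataset(su, "aerobic",
                                 compounds = compounds,
                                 line = lines$activator,
                                 noise = noise_model(seed = seed))
  d_anx <- gen_monolayer_dataset(su, "anoxic",
                                 compounds = compounds,
                                 line = lines$activator,
                                 noise = noise_model(seed = seed + 1L))
  fit_aer <- fit_aerobic_uptake(d_aer, su, compounds, lines$activator,
                                seed = seed)
  fit_anx <- fit_anoxic_metabolism(d_anx, fit_aer, su, compounds,
                                   lines$activator,
                                   multistart = if (quick) 2L else 5L,
                                   seed = seed)
  fitted_compounds <- fit_anx$compounds
  say("cellular PK fitted: k_in=%.3g k_out=%.3g k_met0=%.3g (R2=%.4f)",
      fit_aer$estimates[["k_in.CP-506"]],
      fit_aer$estimates[["k_out.CP-506"]],
      fit_anx$estimates[["k_met0.CP-506"]], fit_anx$r_squared)

  ## -- stage 2: chamber transport ------------------------------------
  geo_bare <- chamber_geometry(mcl_thickness = 0)
  geo_mcl <- chamber_geometry()
  tp_truth <- transport_params(compounds = compounds,
                               line = lines$activator)
  d_bare <- gen_flux_dataset(geo_bare, tp_truth, condition = "supraoxic",
                             noise = noise_model(seed = seed + 2L),
                             urea = FALSE)
  d_sup <- gen_flux_dataset(geo_mcl, tp_truth, condition = "supraoxic",
                            noise = noise_model(seed = seed + 3L))
  d_anxf <- gen_flux_dataset(geo_mcl, tp_truth, condition = "anoxic",
                             noise = noise_model(seed = seed + 4L),
                             urea = FALSE)
  f_dsup <- fit_support_diffusivity(
    d_bare[d_bare$compound == names(compounds)[1L], ], geo_bare)
  f_L <- fit_mcl_thickness(d_sup[d_sup$compound == "urea", ], geo_mcl)
  geo_fit <- geo_mcl
  geo_fit$mcl_thickness <- f_L$estimates$L_mcl
  tp_stage <- transport_params(D_sup = f_dsup$estimates$D_sup,
                               compounds = fitted_compounds,
                               line = lines$activator)
  f_dmcl <- fit_mcl_diffusivity(
    d_sup[d_sup$compound == names(compounds)[1L], ], geo_fit, tp_stage)
  tp_stage$D_mcl <- f_dmcl$estimates$D_mcl
  f_phi <- fit_metabolic_scaling(d_anxf, geo_fit, tp_stage)
  say("chamber fitted: D_sup=%.3g L=%.4g D_mcl=%.3g phi=%.3g",
      f_dsup$estimates$D_sup, f_L$estimates$L_mcl,
      f_dmcl$estimates$D_mcl, f_phi$estimates$phi)

  ## -- stage 3: spheroid gradient prediction -------------------------
  pred_compounds <- fitted_compounds
  for (nm in names(pred_compounds))
    pred_compounds[[nm]]$D_s <- f_dmcl$estimates$D_mcl
  grad <- simulate_spheroid_gradients(radius = spheroid_radius,
                                      f_act = 0.5,
                                      compounds = pred_compounds,
                                      lines = lines,
                                      dr = if (quick) 10 else 5)
  prodrug <- names(compounds)[1L]
  grad_summary <- list(
    periphery_centre_prodrug = periphery_centre_ratio(grad, prodrug),
    penetration_depth_um = penetration_depth(grad, prodrug),
    metabolite_ratios = vapply(
      names(compounds)[-1L], function(cm) periphery_centre_ratio(grad, cm),
      numeric(1L)))
  say("gradients: prodrug ratio %.3g, depth %.4g um",
      grad_summary$periphery_centre_prodrug,
      grad_summary$penetration_depth_um)

  ## -- stage 4: survival prediction vs synthetic observation ---------
  obs_surv <- gen_survival_dataset(survival_C0s, "spheroid", f_act = 0.5,
                                   radius = if (quick) 100 else 150,
                                   compounds = compounds, lines = lines,
                                   noise = noise_model(seed = seed + 5L))
  pred_surv <- do.call(rbind, lapply(survival_C0s, function(c0) {
    g <- simulate_spheroid_gradients(radius = if (quick) 100 else 150,
                                     f_act = 0.5, C0 = c0,
                                     compounds = pred_compounds,
                                     lines = lines, dr = 10)
    sf <- surrogate_survival(g)
    data.frame(line = sf$line, C0_uM = c0,
               surviving_fraction = sf$surviving_fraction)
  }))
  comp <- compare_predictions(pred_surv, obs_surv)
  say("survival comparison: pooled R2 = %.4f", comp$r_squared)

  ## -- artefacts ------------------------------------------------------
  params_out <- lapply(unclass(fitted_compounds), function(cmp) list(
    k_in_per_min = cmp$k_in, k_out_per_min = cmp$k_out,
    k_met0_per_min = as.list(cmp$k_met0),
    halflife_h = if (is.infinite(cmp$halflife_extracellular)) NULL
                 else cmp$halflife_extracellular / 60))
  paths <- list(
    parameters = file.path(out_dir, "fitted_parameters.json"),
    transport = file.path(out_dir, "transport_parameters.json"),
    gradients = file.path(out_dir, "radial_gradients.csv"),
    survival = file.path(out_dir, "survival_comparison.csv"),
    log = file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(params_out, paths$parameters, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  jsonlite::write_json(list(D_sup_cm2_s = f_dsup$estimates$D_sup,
                            L_mcl_um = f_L$estimates$L_mcl,
                            D_mcl_cm2_s = f_dmcl$estimates$D_mcl,
                            phi = f_phi$estimates$phi),
                       paths$transport, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(grad$radial, paths$gradients, row.names = FALSE)
  write.csv(comp$residuals, paths$survival, row.names = FALSE)
  writeLines(log, paths$log)

  list(cellpk = list(aerobic = fit_aer, anoxic = fit_anx),
       chamber = list(D_sup = f_dsup, L_mcl = f_L, D_mcl = f_dmcl,
                      phi = f_phi),
       gradients = grad_summary, survival = comp, paths = paths,
       seed = seed)
}
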