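#' Measurement noise model for synthetic datasets
#'
#' Multiplicative lognormal noise with a given coefficient of variation
#' (LC-MS/MS-like), censoring below the lower limit of quantification,
#' and a replicate structure. Every generator is strictly seeded:
#' identical seed and scenario give byte-identical output.
#'
#' @param cv_proportional Proportional CV of the lognormal noise.
#' @param lloq Lower limit of quantification, µM; noisy values below it
#'   are flagged censored.
#' @param replicates Number of independent replicates.
#' @param seed RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_proportional = 0.10, lloq = 0.01,
                        replicates = 3L, seed = 1L) {
  stopifnot(cv_proportional >= 0, lloq >= 0, replicates >= 1)
  structure(list(cv = cv_proportional, lloq = lloq,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_model")
}

.lognorm_noise <- function(x, cv) {
  if (cv == 0) return(x)
  sdl <- sqrt(log(1 + cv^2))
  x * exp(rnorm(length(x), sd = sdl))
}

## replicate + noise + censor a clean long-format table with a
## concentration_uM column
.noisify <- function(clean, noise) {
  out <- do.call(rbind, lapply(seq_len(noise$replicates), function(r) {
    d <- clean
    d$replicate <- r
    d$concentration_uM <- .lognorm_noise(d$concentration_uM, noise$cv)
    d
  }))
  out$censored <- out$concentration_uM < noise$lloq
  rownames(out) <- NULL
  out
}

.provenance <- function(kind, truth, noise, extra = list()) {
  c(list(kind = kind, truth = truth,
         noise = list(cv = noise$cv, lloq = noise$lloq,
                      replicates = noise$replicates, seed = noise$seed)),
    extra)
}

#' Generate a synthetic monolayer uptake/metabolism dataset
#'
#' Simulates extracellular and intracellular concentration-time profiles
#' for the compound chain under the given condition, then applies
#' seeded lognormal noise per replicate and censors below the LLOQ. The
#' generating parameters are recorded in the `provenance` attribute so
#' that any refit can be compared against truth.
#'
#' @param setup A [monolayer_setup()] (its `oxygen` is overridden by
#'   `condition`).
#' @param condition `"aerobic"` or `"anoxic"`.
#' @param compounds Generating [compound_set()].
#' @param line Generating [cell_line_params()].
#' @param noise A [noise_model()].
#' @param keep_compounds Restrict the emitted profiles to these
#'   compounds (default: prodrug only under aerobic conditions, where no
#'   metabolites form; all compounds under anoxia).
#' @return Long-format data frame `time_min`, `compound`, `compartment`,
#'   `concentration_uM`, `replicate`, `censored`, with attribute
#'   `provenance`.
#' @export
gen_monolayer_dataset <- function(setup = monolayer_setup(),
                                  condition = c("aerobic", "anoxic"),
                                  compounds = cp506_compounds(),
                                  line = cp506_cell_lines()$activator,
                                  noise = noise_model(),
                                  keep_compounds = NULL) {
  condition <- match.arg(condition)
  setup$oxygen <- if (condition == "anoxic") 0 else 200
  sim <- simulate_monolayer(setup, compounds, line)
  clean <- sim[sim$time_min > 0, c("time_min", "compound", "compartment",
                                   "concentration_uM")]
  if (is.null(keep_compounds))
    keep_compounds <- if (condition == "aerobic") names(compounds)[1L]
                      else names(compounds)
  clean <- clean[clean$compound %in% keep_compounds, ]
  out <- .with_seed(noise$seed, .noisify(clean, noise))
  truth <- lapply(unclass(compounds), function(cmp)
    list(k_in = cmp$k_in, k_out = cmp$k_out,
         k_met0 = .kmet0_for_line(cmp, line$label),
         halflife_min = cmp$halflife_extracellular))
  structure(out, provenance = .provenance(
    "monolayer_uptake", truth, noise,
    list(condition = condition, C0 = setup$C0, line = line$label)))
}

#' Generate a synthetic media-stability (decay) dataset
#'
#' Mono-exponential decays in cell-free stirred medium from per-compound
#' half-lives, with seeded noise and censoring.
#'
#' @param halflives Named vector of half-lives, minutes (`Inf` = stable).
#' @param C0 Spike concentration, µM.
#' @param times Sampling times, minutes.
#' @param noise A [noise_model()].
#' @return Long-format data frame `time_min`, `compound`,
#'   `concentration_uM`, `replicate`, `censored` with `provenance`.
#' @export
gen_stability_dataset <- function(halflives = c(
                                    "CP-506H-(OH)2" = 2.5,
                                    "CP-506H" = 10.5,
                                    "CP-506M" = 7.6,
                                    "CP-506H-Cl2" = 141.3,
                                    "CP-506M-Cl2" = 271.1,
                                    "CP-506M-(OH)2" = 393.9,
                                    "CP-506" = Inf),
                                  C0 = 100, times = seq(0, 180, by = 15),
                                  noise = noise_model()) {
  stopifnot(!is.null(names(halflives)), all(halflives > 0))
  clean <- do.call(rbind, lapply(names(halflives), function(cmp) {
    data.frame(time_min = times, compound = cmp,
               concentration_uM = C0 * 2^(-times / halflives[[cmp]]),
               stringsAsFactors = FALSE)
  }))
  out <- .with_seed(noise$seed, .noisify(clean, noise))
  structure(out, provenance = .provenance(
    "media_stability", as.list(halflives), noise, list(C0 = C0)))
}

#' Estimate a half-life from decay data
#'
#' Log-linear least squares on the uncensored points of a
#' mono-exponential decay.
#'
#' @param time_min Times, minutes.
#' @param concentration_uM Concentrations, µM.
#' @param censored Optional logical censoring flags.
#' @return List with `halflife_min`, `k_loss_per_min`, `r_squared`.
#' @export
fit_halflife <- function(time_min, concentration_uM, censored = NULL) {
  keep <- concentration_uM > 0
  if (!is.null(censored)) keep <- keep & !as.logical(censored)
  if (sum(keep) < 3L) stop("need at least 3 uncensored points")
  fit <- stats::lm(log(concentration_uM[keep]) ~ time_min[keep])
  slope <- unname(coef(fit)[2L])
  list(halflife_min = if (slope < 0) -log(2) / slope else Inf,
       k_loss_per_min = max(-slope, 0),
       r_squared = summary(fit)$r.squared)
}

#' Generate a synthetic diffusion-chamber flux dataset
#'
#' Forward-solves the donor/MCL/support/receiver model with the given
#' generating truth and emits noisy donor/receiver concentration-time
#' records per chamber, together with a radiolabelled-urea internal
#' standard channel (no uptake, no instability, its own diffusivities).
#'
#' @param geometry Generating [chamber_geometry()] (`mcl_thickness = 0`
#'   for a bare-membrane scenario).
#' @param params Generating [transport_params()].
#' @param C0 Donor prodrug concentration, µM.
#' @param condition `"supraoxic"` or `"anoxic"`.
#' @param duration Minutes.
#' @param times Sampling times.
#' @param noise A [noise_model()] (`replicates` = chambers).
#' @param urea Include the urea internal standard channel?
#' @param urea_C0 Donor urea concentration (concentration units).
#' @param D_urea_mcl,D_urea_sup Urea diffusivities, cm^2/s.
#' @return Long-format data frame `time_min`, `compartment`, `compound`,
#'   `concentration_uM`, `chamber_id`, `condition`, `censored` with
#'   `provenance`.
#' @export
gen_flux_dataset <- function(geometry = chamber_geometry(),
                             params = transport_params(), C0 = 17.4,
                             condition = c("supraoxic", "anoxic"),
                             duration = 300,
                             times = seq(15, 300, by = 15),
                             noise = noise_model(),
                             urea = geometry$mcl_thickness > 0,
                             urea_C0 = 20, D_urea_mcl = 3.67e-7,
                             D_urea_sup = 3.0e-6) {
  condition <- match.arg(condition)
  sim <- solve_chamber(geometry, params, C0 = C0, duration = duration,
                       condition = condition, times = times)
  clean <- sim$reservoirs[sim$reservoirs$time_min > 0, ]
  if (urea) {
    cs_u <- compound_set(compound_params("urea"))
    p_u <- transport_params(D_sup = D_urea_sup, D_mcl = D_urea_mcl,
                            compounds = cs_u)
    sim_u <- solve_chamber(geometry, p_u, C0 = urea_C0,
                           duration = duration, condition = condition,
                           times = times)
    clean <- rbind(clean, sim_u$reservoirs[sim_u$reservoirs$time_min > 0, ])
  }
  out <- .with_seed(noise$seed, .noisify(clean, noise))
  names(out)[names(out) == "replicate"] <- "chamber_id"
  out$condition <- condition
  truth <- list(D_sup = params$D_sup, D_mcl = params$D_mcl,
                phi = params$phi, L_mcl = geometry$mcl_thickness,
                D_urea_mcl = D_urea_mcl, D_urea_sup = D_urea_sup)
  structure(out, provenance = .provenance("chamber_flux", truth, noise,
                                          list(C0 = C0,
                                               condition = condition)))
}

#' Expected clonogenic survival of monolayers under the kill model
#'
#' Monolayer companion of the spheroid kill model: simulates anoxic
#' exposure at each concentration, accumulates the intracellular AUC of
#' the cytotoxic metabolites, and converts exposure to survival as
#' `exp(-k_d * AUC)`.
#'
#' @param C0s Exposure concentrations, µM.
#' @param compounds A [compound_set()].
#' @param line A [cell_line_params()].
#' @param k_d Kill constant (default the line's monolayer value).
#' @param duration Exposure, minutes.
#' @param setup Template [monolayer_setup()] (C0 and duration are
#'   overridden).
#' @return Data frame `line`, `C0_uM`, `surviving_fraction`,
#'   `auc_uM_min`.
#' @export
monolayer_survival <- function(C0s, compounds = cp506_compounds(),
                               line = cp506_cell_lines()$activator,
                               k_d = line$k_d_monolayer, duration = 240,
                               setup = monolayer_setup()) {
  cyto <- names(compounds)[vapply(compounds, `[[`, TRUE, "is_cytotoxic")]
  out <- lapply(C0s, function(c0) {
    su <- setup
    su$C0 <- c0; su$duration <- duration; su$oxygen <- 0
    su$sample_times <- seq(0, duration, by = 2)
    sim <- simulate_monolayer(su, compounds, line)
    ci <- sim[sim$compartment == "intracellular" &
                sim$compound %in% cyto, ]
    tot <- tapply(ci$concentration_uM, ci$time_min, sum)
    tt <- as.numeric(names(tot))
    ord <- order(tt)
    auc <- sum(diff(tt[ord]) * (head(tot[ord], -1) + tail(tot[ord], -1)) / 2)
    data.frame(line = line$label, C0_uM = c0,
               surviving_fraction = exp(-k_d * auc), auc_uM_min = auc)
  })
  do.call(rbind, out)
}

#' Generate a synthetic clonogenic survival dataset
#'
#' Survival probabilities come from the kill model (monolayer exposure
#' or spheroid co-culture via the continuum surrogate); colony counts
#' are then drawn binomially given the cells plated and the plating
#' efficiency, and surviving fractions computed as the ratio of plating
#' efficiencies exactly as in the assay.
#'
#' @param C0s Exposure concentrations, µM.
#' @param mode `"monolayer"` or `"spheroid"`.
#' @param f_act Activator fraction (spheroid mode).
#' @param radius Spheroid radius, µm (spheroid mode).
#' @param compounds,lines Generating parameters.
#' @param k_d Kill constant override (default: context value per line).
#' @param cells_plated,plating_efficiency Colony-assay design.
#' @param noise A [noise_model()] (`replicates` = experiments; CV unused,
#'   counts are binomial).
#' @param duration Exposure, minutes.
#' @return Data frame `line`, `C0_uM`, `replicate`, `colonies`,
#'   `control_colonies`, `cells_plated`, `surviving_fraction`, with
#'   `provenance` (includes the generating true SF).
#' @export
gen_survival_dataset <- function(C0s, mode = c("monolayer", "spheroid"),
                                 f_act = 0.5, radius = 150,
                                 compounds = cp506_compounds(),
                                 lines = cp506_cell_lines(), k_d = NULL,
                                 cells_plated = 1000,
                                 plating_efficiency = 0.6,
                                 noise = noise_model(), duration = 240) {
  mode <- match.arg(mode)
  truth <- if (mode == "monolayer") {
    do.call(rbind, lapply(c("activator", "target"), function(ln) {
      li <- lines[[ln]]
      kd <- if (is.null(k_d)) li$k_d_monolayer else k_d
      monolayer_survival(C0s, compounds, li, k_d = kd,
                         duration = duration)
    }))
  } else {
    do.call(rbind, lapply(C0s, function(c0) {
      g <- simulate_spheroid_gradients(radius = radius, f_act = f_act,
                                       C0 = c0, duration = duration,
                                       compounds = compounds,
                                       lines = lines, dr = 10)
      sf <- surrogate_survival(g, k_d = k_d)
      data.frame(line = sf$line, C0_uM = c0,
                 surviving_fraction = sf$surviving_fraction)
    }))
  }
  out <- .with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(noise$replicates), function(r) {
      d <- truth[, c("line", "C0_uM")]
      d$replicate <- r
      p <- pmin(pmax(truth$surviving_fraction, 0), 1)
      d$colonies <- rbinom(nrow(d), cells_plated, plating_efficiency * p)
      d$control_colonies <- rbinom(nrow(d), cells_plated,
                                   plating_efficiency)
      d$cells_plated <- cells_plated
      d$surviving_fraction <- surviving_fraction(
        d$colonies, d$control_colonies, cells_plated)
      d
    }))
  })
  rownames(out) <- NULL
  structure(out, provenance = .provenance(
    paste0("clonogenic_", mode),
    list(true_sf = truth, k_d = k_d, f_act = f_act, radius = radius),
    noise,
    list(cells_plated = cells_plated,
         plating_efficiency = plating_efficiency)))
}

#' Write / read a synthetic dataset with its provenance header
#'
#' CSV files start with a single comment line
#' `# provenance: <json>` recording the generating parameters and seed,
#' so a round trip can always compare estimates against truth.
#'
#' @param x Data frame with a `provenance` attribute.
#' @param path File path.
#' @return `write_hap_csv()` returns `path` invisibly; `read_hap_csv()`
#'   the data frame with `provenance` restored.
#' @export
write_hap_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    writeLines(paste0("# provenance: ",
                      jsonlite::toJSON(prov, auto_unbox = TRUE,
                                       digits = NA, null = "null")), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hap_csv
#' @export
read_hap_csv <- function(path) {
  first <- readLines(path, n = 1L)
  prov <- NULL
  if (startsWith(first, "# provenance: "))
    prov <- jsonlite::fromJSON(sub("^# provenance: ", "", first),
                               simplifyVector = FALSE)
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(out, provenance = prov)
}
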