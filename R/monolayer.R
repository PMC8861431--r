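#' Monolayer experiment setup
#'
#' Describes a monolayer uptake/metabolism experiment: cells attached in a
#' well under a known medium volume, drug added at `C0`, sampled at
#' `sample_times`. The intracellular-to-extracellular volume ratio
#' `Vi/Ve = cell_count * cell_volume / medium_volume` couples the two
#' compartments; it is small (~0.3%) in the standard protocol
#' (5e5 cells, 2.5 pL, 400 µl), so the medium is only slowly depleted by
#' uptake.
#'
#' @param cell_count Number of cells per well.
#' @param cell_volume Single-cell volume in picolitres.
#' @param medium_volume Medium volume in microlitres.
#' @param C0 Initial extracellular prodrug concentration, µM.
#' @param duration Exposure duration, minutes.
#' @param oxygen Oxygen concentration, µM (0 = anoxia).
#' @param sample_times Sampling times, minutes (strictly increasing).
#' @param lloq Lower limit of quantification, µM.
#' @return An object of class `monolayer_setup`.
#' @export
monolayer_setup <- function(cell_count = 5e5, cell_volume = 2.5,
                            medium_volume = 400, C0 = 100,
                            duration = 180, oxygen = 200,
                            sample_times = c(5, 10, 15, 30, 60, 90, 120, 180),
                            lloq = 0.01) {
  stopifnot(cell_count > 0, cell_volume > 0, medium_volume > 0,
            C0 >= 0, duration > 0, oxygen >= 0, lloq >= 0,
            all(diff(sample_times) > 0), all(sample_times >= 0),
            max(sample_times) <= duration)
  structure(list(cell_count = cell_count, cell_volume = cell_volume,
                 medium_volume = medium_volume, C0 = C0,
                 duration = duration, oxygen = oxygen,
                 sample_times = sample_times, lloq = lloq,
                 ## pL -> µl is 1e-6
                 volume_ratio = cell_count * cell_volume * 1e-6 / medium_volume),
            class = "monolayer_setup")
}

## Right-hand side of the monolayer ODE system. State layout:
## [Ce_1..Ce_n, Ci_1..Ci_n, sink_ext, sink_term] where sink_ext collects
## extracellular degradation (µM on the Ve scale) and sink_term collects
## terminal intracellular metabolism (µM on the Vi scale).
.monolayer_rhs <- function(t, y, p) {
  n <- p$n
  Ce <- y[seq_len(n)]
  Ci <- y[n + seq_len(n)]
  exch <- p$k_in * Ce - p$k_out * Ci      # µM/min on the Vi scale
  met <- p$kmet * Ci
  prod <- c(0, met[-n])                   # chain: compound j fed by j-1
  dCe <- -p$k_loss * Ce - p$f * exch
  dCi <- exch + prod - met
  list(c(dCe, dCi, sum(p$k_loss * Ce), met[n]))
}

#' Simulate prodrug uptake and metabolism in a monolayer culture
#'
#' Integrates the two-compartment first-order cellular PK model for a
#' metabolite chain: the extracellular pool of each compound exchanges
#' with the intracellular pool via `k_in`/`k_out`, degrades chemically at
#' `k_loss = ln2 / T1/2`, and the intracellular prodrug is metabolised at
#' `k_met0 * g(O2)` feeding the next compound in the chain (metabolite
#' conversion is not oxygen gated). Terminal metabolism and extracellular
#' degradation are routed to explicit sinks so that total mass is
#' conserved exactly.
#'
#' @param setup A [monolayer_setup()].
#' @param compounds A [compound_set()].
#' @param line A [cell_line_params()] (selects per-line `k_met0`).
#' @param times Output times (minutes); defaults to `setup$sample_times`
#'   with 0 prepended.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame with columns `time_min`, `compound`,
#'   `compartment` (`"extracellular"`/`"intracellular"`),
#'   `concentration_uM`, of class `monolayer_sim`, carrying the sink
#'   trajectories, setup and volume ratio as attributes.
#' @export
simulate_monolayer <- function(setup, compounds = cp506_compounds(),
                               line = cp506_cell_lines()$activator,
                               times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(setup, "monolayer_setup"),
            inherits(compounds, "compound_set"),
            inherits(line, "cell_line_params"))
  if (is.null(times)) times <- setup$sample_times
  times <- sort(unique(c(0, times)))
  n <- length(compounds)
  p <- list(
    n = n,
    k_in = vapply(compounds, `[[`, 0, "k_in"),
    k_out = vapply(compounds, `[[`, 0, "k_out"),
    k_loss = vapply(compounds, `[[`, 0, "k_loss"),
    kmet = .kmet_effective(compounds, line$label, setup$oxygen),
    f = setup$volume_ratio
  )
  y0 <- c(c(setup$C0, rep(0, n - 1L)), rep(0, n), 0, 0)
  sol <- deSolve::lsoda(y0, times, .monolayer_rhs, p,
                        rtol = rtol, atol = atol)
  if (min(sol[, -1L]) < -10 * atol)
    stop("integrator produced negative concentrations; tighten tolerances")
  nm <- names(compounds)
  out <- data.frame(
    time_min = rep(rep(sol[, "time"], times = n), 2L),
    compound = rep(rep(nm, each = nrow(sol)), 2L),
    compartment = rep(c("extracellular", "intracellular"),
                      each = nrow(sol) * n),
    concentration_uM = c(as.vector(sol[, 1L + seq_len(n)]),
                         as.vector(sol[, 1L + n + seq_len(n)])),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("monolayer_sim", "data.frame"),
            sinks = data.frame(time_min = sol[, "time"],
                               sink_extracellular = sol[, 2L * n + 2L],
                               sink_terminal = sol[, 2L * n + 3L]),
            setup = setup, volume_ratio = setup$volume_ratio,
            compounds = nm)
}

#' Mass balance of a monolayer simulation or measured profile set
#'
#' Totals `Ve * sum(Ce) + Vi * sum(Ci)` plus (when available) the explicit
#' degradation sinks, per time point, normalised to the initial amount.
#' For a closed simulated system the balance is identically 1 to within
#' integrator tolerance; measured profiles without sink tracking show the
#' loss of mass balance caused by degradation and terminal metabolism.
#'
#' @param profiles A `monolayer_sim` or a data frame with columns
#'   `time_min`, `compound`, `compartment`, `concentration_uM` on a common
#'   time grid.
#' @param setup The [monolayer_setup()] (taken from the simulation object
#'   if absent).
#' @return Data frame with `time_min` and `balance` (fraction of initial
#'   amount).
#' @export
mass_balance <- function(profiles, setup = attr(profiles, "setup")) {
  stopifnot(is.data.frame(profiles), !is.null(setup))
  f <- setup$volume_ratio
  ce <- profiles[profiles$compartment == "extracellular", ]
  ci <- profiles[profiles$compartment == "intracellular", ]
  te <- sort(unique(ce$time_min)); ti <- sort(unique(ci$time_min))
  if (length(te) != length(ti) || any(te != ti))
    stop("extracellular and intracellular profiles are on different time grids")
  tot_e <- tapply(ce$concentration_uM, ce$time_min, sum)
  tot_i <- tapply(ci$concentration_uM, ci$time_min, sum)
  bal <- (tot_e + f * tot_i)
  sinks <- attr(profiles, "sinks")
  if (!is.null(sinks)) {
    if (length(sinks$time_min) != length(te) || any(sinks$time_min != te))
      stop("sink trajectory on a different time grid")
    bal <- bal + sinks$sink_extracellular + f * sinks$sink_terminal
  }
  C0_total <- bal[[1L]]
  data.frame(time_min = te, balance = as.vector(bal) / C0_total,
             row.names = NULL)
}
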