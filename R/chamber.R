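#' Diffusion-chamber geometry
#'
#' Layout of the stirred donor / multicellular layer (MCL) / support
#' membrane / stirred receiver diffusion apparatus. Set
#' `mcl_thickness = 0` for a bare-membrane (no cells) chamber.
#'
#' @param donor_volume,receiver_volume Reservoir volumes, ml.
#' @param exposed_area Membrane area exposed to flux, cm^2.
#' @param support_thickness Support membrane thickness, µm.
#' @param mcl_thickness MCL thickness, µm (0 = bare membrane).
#' @param grid_nodes_per_layer Spatial nodes per layer (>= 20) for the
#'   method-of-lines discretisation.
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(donor_volume = 8.5, receiver_volume = 8.5,
                             exposed_area = 0.6, support_thickness = 130,
                             mcl_thickness = 101.7,
                             grid_nodes_per_layer = 50L) {
  stopifnot(donor_volume > 0, receiver_volume > 0, exposed_area > 0,
            support_thickness > 0, mcl_thickness >= 0)
  if (grid_nodes_per_layer < 20L)
    stop("grid too coarse: need at least 20 nodes per layer")
  structure(list(donor_volume = donor_volume,
                 receiver_volume = receiver_volume,
                 exposed_area = exposed_area,
                 support_thickness = support_thickness,
                 mcl_thickness = mcl_thickness,
                 grid_nodes_per_layer = as.integer(grid_nodes_per_layer)),
            class = "chamber_geometry")
}

#' Transport parameters for the chamber model
#'
#' @param D_sup Diffusion coefficient across the bare support membrane,
#'   cm^2/s.
#' @param D_mcl Diffusion coefficient in the MCL extracellular space,
#'   cm^2/s.
#' @param phi Metabolic scaling factor in (0, 1]: multiplies the
#'   transmembrane exchange terms of both the extracellular and
#'   intracellular equations at tissue density.
#' @param compounds A [compound_set()].
#' @param line Cell line of the MCL (selects `k_met0`).
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D_sup = 1.32e-6, D_mcl = 1.93e-7, phi = 0.3,
                             compounds = cp506_compounds(),
                             line = cp506_cell_lines()$activator) {
  stopifnot(D_sup > 0, D_mcl > 0, phi > 0, phi <= 1,
            inherits(compounds, "compound_set"))
  structure(list(D_sup = D_sup, D_mcl = D_mcl, phi = phi,
                 compounds = compounds, line = line),
            class = "transport_params")
}

## Assemble the method-of-lines right-hand side for the chamber.
## State per compound: [donor, receiver, Ce(n1+n2), Ci(n1)] concatenated
## over compounds, then 2 sink states (extracellular loss, terminal
## intracellular metabolism), as amounts normalised to donor volume (µM
## donor-equivalents).
.chamber_rhs_factory <- function(geometry, params, condition,
                                 D_sup_cmp = NULL, D_mcl_cmp = NULL) {
  g <- geometry
  n1 <- if (g$mcl_thickness > 0) g$grid_nodes_per_layer else 0L
  n2 <- g$grid_nodes_per_layer
  nn <- n1 + n2
  dx1 <- if (n1 > 0) g$mcl_thickness / n1 else NA_real_
  dx2 <- g$support_thickness / n2
  A <- .cm2_to_um2(g$exposed_area)
  Vd <- .ml_to_um3(g$donor_volume)
  Vr <- .ml_to_um3(g$receiver_volume)
  cset <- params$compounds
  ncmp <- length(cset)
  o2 <- if (condition == "anoxic") 0 else 200
  kmet <- .kmet_effective(cset, params$line$label, o2)
  k_in <- vapply(cset, `[[`, 0, "k_in")
  k_out <- vapply(cset, `[[`, 0, "k_out")
  k_loss <- vapply(cset, `[[`, 0, "k_loss")
  phi <- params$phi
  ## per-compound diffusivities (µm^2/min); urea-style overrides allowed
  Dm <- rep(.cm2s_to_um2min(params$D_mcl), ncmp)
  Ds <- rep(.cm2s_to_um2min(params$D_sup), ncmp)
  if (!is.null(D_mcl_cmp)) Dm <- .cm2s_to_um2min(D_mcl_cmp)
  if (!is.null(D_sup_cmp)) Ds <- .cm2s_to_um2min(D_sup_cmp)
  ## node widths and face "conductances" (flux = cond * (C_right - C_left),
  ## in µm^3 µM / min when multiplied by area)
  widths <- c(rep(dx1, n1), rep(dx2, n2))
  per_cmp <- 2L + nn + n1
  function(t, y, ...) {
    dy <- numeric(length(y))
    s_ext <- 0; s_term <- 0
    for (j in seq_len(ncmp)) {
      off <- (j - 1L) * per_cmp
      Cd <- y[off + 1L]; Cr <- y[off + 2L]
      Ce <- y[off + 2L + seq_len(nn)]
      Dnode <- c(rep(Dm[j], n1), rep(Ds[j], n2))
      ## face fluxes (positive = toward receiver), length nn+1
      Call <- c(Cd, Ce, Cr)
      half <- widths / (2 * Dnode)
      resist <- c(half[1L], half[-nn] + half[-1L], half[nn])
      flux <- -(Call[-1L] - Call[-(nn + 2L)]) / resist * A
      dCe <- (flux[seq_len(nn)] - flux[-1L]) / (A * widths) - k_loss[j] * Ce
      dCd <- -flux[1L] / Vd - k_loss[j] * Cd
      dCr <- flux[nn + 1L] / Vr - k_loss[j] * Cr
      s_ext <- s_ext + k_loss[j] *
        (Cd * Vd + Cr * Vr + sum(Ce * widths) * A)
      if (n1 > 0) {
        Ci <- y[off + 2L + nn + seq_len(n1)]
        exch <- phi * (k_in[j] * Ce[seq_len(n1)] - k_out[j] * Ci)
        met <- kmet[j] * Ci
        dCe[seq_len(n1)] <- dCe[seq_len(n1)] - exch
        prod <- if (j > 1L) kmet[j - 1L] * y[(j - 2L) * per_cmp + 2L + nn + seq_len(n1)]
                else 0
        dCi <- exch + prod - met
        dy[off + 2L + nn + seq_len(n1)] <- dCi
        if (j == ncmp) s_term <- s_term + sum(met * dx1) * A
      }
      dy[off + 1L] <- dCd
      dy[off + 2L] <- dCr
      dy[off + 2L + seq_len(nn)] <- dCe
    }
    dy[ncmp * per_cmp + 1L] <- s_ext / Vd
    dy[ncmp * per_cmp + 2L] <- s_term / Vd
    list(dy)
  }
}

#' Solve the donor/MCL/support/receiver reaction-diffusion model
#'
#' Integrates one-dimensional Fickian diffusion with reaction across the
#' four chamber compartments: the stirred donor and receiver are
#' well-mixed reservoirs coupled by boundary flux to the MCL (diffusion
#' `D_mcl` plus cellular exchange scaled by `phi` and oxygen-gated
#' metabolism) and the acellular support membrane (diffusion `D_sup`).
#' Concentration and flux are continuous at the layer interface.
#' Metabolites formed intracellularly exchange with the extracellular
#' space and appear in both reservoirs. Degradation and terminal
#' metabolism accumulate in explicit sinks, so the audited mass balance
#' is exact.
#'
#' @param geometry A [chamber_geometry()].
#' @param params A [transport_params()].
#' @param C0 Initial donor concentration of the chain root, µM.
#' @param duration Minutes.
#' @param condition `"supraoxic"` (gate closed) or `"anoxic"` (gate open).
#' @param times Output times, minutes.
#' @param D_sup_cmp,D_mcl_cmp Optional per-compound diffusivity vectors
#'   (cm^2/s) overriding the scalar `params` values (used for the urea
#'   internal standard).
#' @param rtol,atol Integrator tolerances.
#' @return A list of class `chamber_sim`: `reservoirs` (long data frame
#'   `time_min`, `compartment`, `compound`, `concentration_uM`),
#'   `profiles` (in-layer extracellular/intracellular fields at the final
#'   time), `balance` (per-time normalised mass balance), plus the inputs.
#' @export
solve_chamber <- function(geometry, params, C0 = 20, duration = 300,
                          condition = c("supraoxic", "anoxic"),
                          times = seq(0, duration, by = 15),
                          D_sup_cmp = NULL, D_mcl_cmp = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  condition <- match.arg(condition)
  stopifnot(inherits(geometry, "chamber_geometry"),
            inherits(params, "transport_params"), C0 > 0)
  g <- geometry
  n1 <- if (g$mcl_thickness > 0) g$grid_nodes_per_layer else 0L
  n2 <- g$grid_nodes_per_layer
  nn <- n1 + n2
  per_cmp <- 2L + nn + n1
  cset <- params$compounds
  ncmp <- length(cset)
  rhs <- .chamber_rhs_factory(geometry, params, condition,
                              D_sup_cmp, D_mcl_cmp)
  y0 <- numeric(ncmp * per_cmp + 2L)
  y0[1L] <- C0
  times <- sort(unique(c(0, times)))
  sol <- deSolve::lsodes(y0, times, rhs, parms = NULL,
                         rtol = rtol, atol = atol)
  nm <- names(cset)
  res <- do.call(rbind, lapply(seq_len(ncmp), function(j) {
    off <- (j - 1L) * per_cmp
    data.frame(time_min = rep(sol[, "time"], 2L),
               compartment = rep(c("donor", "receiver"),
                                 each = nrow(sol)),
               compound = nm[j],
               concentration_uM = c(sol[, off + 2L], sol[, off + 3L]),
               stringsAsFactors = FALSE)
  }))
  ## mass balance (normalised to initial donor amount)
  A <- .cm2_to_um2(g$exposed_area)
  Vd <- .ml_to_um3(g$donor_volume); Vr <- .ml_to_um3(g$receiver_volume)
  dx1 <- if (n1 > 0) g$mcl_thickness / n1 else 0
  dx2 <- g$support_thickness / n2
  widths <- c(rep(dx1, n1), rep(dx2, n2))
  tot <- numeric(nrow(sol))
  for (j in seq_len(ncmp)) {
    off <- (j - 1L) * per_cmp
    tot <- tot + sol[, off + 2L] * Vd + sol[, off + 3L] * Vr +
      (sol[, off + 3L + seq_len(nn), drop = FALSE] %*% widths) * A
    if (n1 > 0)
      tot <- tot + (sol[, off + 3L + nn + seq_len(n1), drop = FALSE] %*%
                      rep(dx1, n1)) * A
  }
  tot <- tot + (sol[, ncmp * per_cmp + 2L] + sol[, ncmp * per_cmp + 3L]) * Vd
  xmid <- cumsum(widths) - widths / 2
  last <- nrow(sol)
  prof <- do.call(rbind, lapply(seq_len(ncmp), function(j) {
    off <- (j - 1L) * per_cmp
    d <- data.frame(x_um = xmid, compound = nm[j],
                    Ce_uM = as.vector(sol[last, off + 3L + seq_len(nn)]),
                    Ci_uM = NA_real_, stringsAsFactors = FALSE)
    if (n1 > 0)
      d$Ci_uM[seq_len(n1)] <- as.vector(sol[last, off + 3L + nn + seq_len(n1)])
    d
  }))
  structure(list(reservoirs = res, profiles = prof,
                 balance = data.frame(time_min = sol[, "time"],
                                      balance = as.vector(tot) / (C0 * Vd)),
                 geometry = geometry, params = params, C0 = C0,
                 condition = condition),
            class = "chamber_sim")
}

#' @export
print.chamber_sim <- function(x, ...) {
  fin <- x$reservoirs[x$reservoirs$time_min == max(x$reservoirs$time_min), ]
  cat(sprintf("<chamber_sim> %s, C0 = %g uM, %g min\n", x$condition, x$C0,
              max(x$reservoirs$time_min)))
  print(stats::reshape(fin, direction = "wide", idvar = "compound",
                       timevar = "compartment",
                       drop = "time_min"), row.names = FALSE)
  invisible(x)
}
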