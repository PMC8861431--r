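## Spherically-symmetric continuum surrogate of the lattice spheroid
## model. Each radial shell carries one extracellular pool per compound
## (per unit extracellular volume; tissue diffusivity D_s acts within the
## extracellular phase) and one intracellular pool per compound per cell
## line (activator/target), coupled by the monolayer exchange
## constants scaled by the line-to-extracellular volume ratio. The
## surrounding medium is a finite well-mixed compartment (or a constant
## boundary). Used for fast, low-variance radial-gradient and
## expected-value survival runs; the lattice model must agree with it.

#' Simulate drug/metabolite gradients in a spheroid (continuum surrogate)
#'
#' Exposes a spheroid of the given radius and activator/target
#' composition to the prodrug and integrates the radial
#' reaction-diffusion system: extracellular diffusion inward from the
#' medium, per-line cellular exchange, oxygen-gated prodrug activation,
#' metabolite chain kinetics, extracellular instability, and per-cell
#' cytotoxic-metabolite exposure (AUC).
#'
#' @param radius Spheroid radius, µm.
#' @param f_act Activator cell fraction in \[0, 1\].
#' @param C0 Initial medium prodrug concentration, µM.
#' @param duration Exposure duration, minutes.
#' @param anoxic If `TRUE` the oxygen field is clamped to 0 (the
#'   experimental design for bystander assays); otherwise the gate closes
#'   prodrug metabolism.
#' @param compounds A [compound_set()].
#' @param lines List with `activator` and `target` [cell_line_params()].
#' @param dr Shell width, µm.
#' @param cell_fraction Cellular volume fraction of spheroid tissue.
#' @param medium_volume Medium volume, µl (finite-well boundary).
#' @param constant_boundary If `TRUE` the medium concentration is held at
#'   `C0` for the prodrug (and 0 for metabolites).
#' @param times Output times, minutes.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `spheroid_grad`: list with `radial`
#'   (data frame `depth_um`, `r_um`, `compound`, `Ce_uM`, `mean_Ci_uM`,
#'   `Ci_act_uM`, `Ci_targ_uM` at end of exposure), `auc` (per shell/line
#'   cytotoxic AUC, µM min), `medium` (concentration-time), `balance`,
#'   and the configuration.
#' @export
simulate_spheroid_gradients <- function(radius = 300, f_act = 0.5, C0 = 20,
                                        duration = 240, anoxic = TRUE,
                                        compounds = cp506_compounds(),
                                        lines = cp506_cell_lines(),
                                        dr = 5, cell_fraction = 0.5,
                                        medium_volume = 100,
                                        constant_boundary = FALSE,
                                        times = seq(0, duration, by = 10),
                                        rtol = 1e-7, atol = 1e-9) {
  stopifnot(radius > 0, f_act >= 0, f_act <= 1, C0 >= 0,
            cell_fraction > 0, cell_fraction < 1)
  nr <- ceiling(radius / dr)
  redge <- seq_len(nr) * dr
  rcent <- redge - dr / 2
  Vk <- 4 / 3 * pi * (redge^3 - c(0, redge[-nr])^3)   # µm^3 per shell
  Aface <- 4 * pi * redge^2                            # outward face areas
  eps_e <- 1 - cell_fraction
  eps_line <- c(activator = cell_fraction * f_act,
                target = cell_fraction * (1 - f_act))
  ncmp <- length(compounds)
  nm <- names(compounds)
  o2 <- if (anoxic) 0 else 200
  kmetA <- .kmet_effective(compounds, lines$activator$label, o2)
  kmetT <- .kmet_effective(compounds, lines$target$label, o2)
  k_in <- vapply(compounds, `[[`, 0, "k_in")
  k_out <- vapply(compounds, `[[`, 0, "k_out")
  k_loss <- vapply(compounds, `[[`, 0, "k_loss")
  Ds <- .cm2s_to_um2min(vapply(compounds, `[[`, 0, "D_s"))
  cyto <- which(vapply(compounds, `[[`, TRUE, "is_cytotoxic"))
  Vmed <- .ul_to_um3(medium_volume)
  ## state: per compound [Ce(nr), CiA(nr), CiT(nr)] then medium (ncmp),
  ## AUC blocks (length 2*nr per cytotoxic compound), sinks (2)
  blk <- 3L * nr
  i_med <- ncmp * blk
  i_auc <- i_med + ncmp
  i_sink <- i_auc + 2L * nr * length(cyto)
  y0 <- numeric(i_sink + 2L)
  y0[i_med + 1L] <- C0
  rhs <- function(t, y, ...) {
    dy <- numeric(length(y))
    s_ext <- 0; s_term <- 0
    CiA_prev <- NULL; CiT_prev <- NULL
    kA_prev <- 0; kT_prev <- 0
    for (j in seq_len(ncmp)) {
      off <- (j - 1L) * blk
      Ce <- y[off + seq_len(nr)]
      CiA <- y[off + nr + seq_len(nr)]
      CiT <- y[off + 2L * nr + seq_len(nr)]
      Cmed <- if (constant_boundary) (if (j == 1L) C0 else 0) else y[i_med + j]
      ## diffusive fluxes through the extracellular phase (µm^3 µM / min)
      Fint <- eps_e * Ds[j] * Aface[-nr] * (Ce[-1L] - Ce[-nr]) / dr
      Fout <- eps_e * Ds[j] * Aface[nr] * (Cmed - Ce[nr]) / (dr / 2)
      divF <- (c(Fint, Fout) - c(0, Fint)) / (eps_e * Vk)
      exchA <- k_in[j] * Ce - k_out[j] * CiA
      exchT <- k_in[j] * Ce - k_out[j] * CiT
      dCe <- divF - k_loss[j] * Ce -
        (eps_line[["activator"]] * exchA +
           eps_line[["target"]] * exchT) / eps_e
      prodA <- if (j > 1L) kA_prev * CiA_prev else 0
      prodT <- if (j > 1L) kT_prev * CiT_prev else 0
      dCiA <- exchA + prodA - kmetA[j] * CiA
      dCiT <- exchT + prodT - kmetT[j] * CiT
      dy[off + seq_len(nr)] <- dCe
      dy[off + nr + seq_len(nr)] <- dCiA
      dy[off + 2L * nr + seq_len(nr)] <- dCiT
      if (!constant_boundary)
        dy[i_med + j] <- -Fout / Vmed - k_loss[j] * Cmed
      s_ext <- s_ext + k_loss[j] *
        (sum(Ce * eps_e * Vk) + Cmed * Vmed)
      if (j == ncmp)
        s_term <- s_term +
          sum((eps_line[["activator"]] * kmetA[j] * CiA +
                 eps_line[["target"]] * kmetT[j] * CiT) * Vk)
      CiA_prev <- CiA; CiT_prev <- CiT
      kA_prev <- kmetA[j]; kT_prev <- kmetT[j]
    }
    for (ci in seq_along(cyto)) {
      off <- (cyto[ci] - 1L) * blk
      a0 <- i_auc + (ci - 1L) * 2L * nr
      dy[a0 + seq_len(nr)] <- y[off + nr + seq_len(nr)]
      dy[a0 + nr + seq_len(nr)] <- y[off + 2L * nr + seq_len(nr)]
    }
    dy[i_sink + 1L] <- s_ext
    dy[i_sink + 2L] <- s_term
    list(dy)
  }
  times <- sort(unique(c(0, times)))
  sol <- deSolve::lsodes(y0, times, rhs, parms = NULL,
                         rtol = rtol, atol = atol)
  last <- nrow(sol)
  radial <- do.call(rbind, lapply(seq_len(ncmp), function(j) {
    off <- (j - 1L) * blk
    CiA <- as.vector(sol[last, 1L + off + nr + seq_len(nr)])
    CiT <- as.vector(sol[last, 1L + off + 2L * nr + seq_len(nr)])
    data.frame(r_um = rcent, depth_um = radius - rcent, compound = nm[j],
               Ce_uM = as.vector(sol[last, 1L + off + seq_len(nr)]),
               Ci_act_uM = CiA, Ci_targ_uM = CiT,
               mean_Ci_uM = f_act * CiA + (1 - f_act) * CiT,
               stringsAsFactors = FALSE)
  }))
  auc <- do.call(rbind, lapply(seq_along(cyto), function(ci) {
    a0 <- i_auc + (ci - 1L) * 2L * nr
    data.frame(r_um = rep(rcent, 2L),
               line = rep(c("activator", "target"), each = nr),
               compound = nm[cyto[ci]],
               auc_uM_min = c(as.vector(sol[last, 1L + a0 + seq_len(nr)]),
                              as.vector(sol[last, 1L + a0 + nr + seq_len(nr)])),
               stringsAsFactors = FALSE)
  }))
  medium <- data.frame(time_min = rep(sol[, "time"], ncmp),
                       compound = rep(nm, each = last),
                       concentration_uM =
                         as.vector(sol[, 1L + i_med + seq_len(ncmp)]))
  ## mass audit (skipped for the constant-concentration boundary, which
  ## is an open system by construction)
  balance <- NULL
  if (!constant_boundary) {
    tot <- numeric(last)
    for (j in seq_len(ncmp)) {
      off <- (j - 1L) * blk
      tot <- tot + (sol[, 1L + off + seq_len(nr), drop = FALSE] %*%
                      (eps_e * Vk)) +
        (sol[, 1L + off + nr + seq_len(nr), drop = FALSE] %*%
           (eps_line[["activator"]] * Vk)) +
        (sol[, 1L + off + 2L * nr + seq_len(nr), drop = FALSE] %*%
           (eps_line[["target"]] * Vk)) +
        sol[, 1L + i_med + j] * Vmed
    }
    tot <- tot + sol[, 1L + i_sink + 1L] + sol[, 1L + i_sink + 2L]
    balance <- data.frame(time_min = sol[, "time"],
                          balance = as.vector(tot) / (C0 * Vmed))
  }
  structure(list(radial = radial, auc = auc, medium = medium,
                 balance = balance, radius = radius, f_act = f_act,
                 C0 = C0, duration = duration, anoxic = anoxic,
                 cell_fraction = cell_fraction, dr = dr,
                 compounds = compounds, lines = lines),
            class = "spheroid_grad")
}

#' @export
print.spheroid_grad <- function(x, ...) {
  cat(sprintf("<spheroid_grad> R = %g um, %g%% activators, %g uM x %g min, %s\n",
              x$radius, 100 * x$f_act, x$C0, x$duration,
              if (x$anoxic) "anoxic" else "oxic"))
  for (cmp in unique(x$radial$compound)) {
    pr <- periphery_centre_ratio(x, cmp)
    cat(sprintf("  %-12s periphery/centre Ci ratio %.3g\n", cmp, pr))
  }
  invisible(x)
}

## Shared helpers on radial profiles ------------------------------------

.radial_of <- function(x) {
  if (inherits(x, "spheroid_grad")) x$radial
  else if (is.data.frame(x)) x
  else stop("expected a radial profile or spheroid_grad")
}

#' Periphery-to-centre intracellular concentration ratio
#'
#' Ratio of the mean intracellular concentration in the outermost radial
#' bin to the innermost (central) bin.
#'
#' @param x A `spheroid_grad`, lattice radial profile, or radial data
#'   frame with `depth_um`, `compound`, `mean_Ci_uM`.
#' @param compound Compound name.
#' @return Fold ratio (outermost / innermost).
#' @export
periphery_centre_ratio <- function(x, compound) {
  rad <- .radial_of(x)
  rad <- rad[rad$compound == compound, ]
  if (nrow(rad) == 0L) stop("compound not present in profile")
  rad <- rad[order(rad$depth_um), ]
  rad$mean_Ci_uM[1L] / rad$mean_Ci_uM[nrow(rad)]
}

#' Penetration depth at which intracellular concentration becomes negligible
#'
#' Depth from the spheroid surface where the intracellular concentration
#' first falls below `fraction` (default 1%) of the peripheral
#' (outermost-bin) value, found by log-linear interpolation between bins.
#'
#' @inheritParams periphery_centre_ratio
#' @param fraction Threshold as a fraction of the peripheral value.
#' @return Depth in µm, or `Inf` if the profile never falls below the
#'   threshold.
#' @export
penetration_depth <- function(x, compound, fraction = 0.01) {
  rad <- .radial_of(x)
  rad <- rad[rad$compound == compound, ]
  if (nrow(rad) == 0L) stop("compound not present in profile")
  rad <- rad[order(rad$depth_um), ]
  rel <- rad$mean_Ci_uM / rad$mean_Ci_uM[1L]
  below <- which(rel < fraction)
  if (length(below) == 0L) return(Inf)
  i <- below[1L]
  if (i == 1L) return(rad$depth_um[1L])
  ## log-linear interpolation between bins i-1 and i
  l1 <- log(rel[i - 1L]); l2 <- log(rel[i])
  w <- (log(fraction) - l1) / (l2 - l1)
  rad$depth_um[i - 1L] + w * (rad$depth_um[i] - rad$depth_um[i - 1L])
}

#' Expected-value clonogenic survival from a surrogate exposure
#'
#' Per-line surviving fraction computed as the cell-number-weighted mean
#' of `exp(-k_d * AUC)` over shells, where AUC sums the intracellular
#' exposure to every cytotoxic metabolite.
#'
#' @param x A `spheroid_grad` from [simulate_spheroid_gradients()].
#' @param k_d Kill-probability rate constant (per µM per min); defaults
#'   to each line's spheroid value.
#' @return Data frame `line`, `surviving_fraction`.
#' @export
surrogate_survival <- function(x, k_d = NULL) {
  stopifnot(inherits(x, "spheroid_grad"))
  nr <- length(unique(x$auc$r_um))
  redge <- sort(unique(x$auc$r_um)) + x$dr / 2
  Vk <- 4 / 3 * pi * (redge^3 - c(0, redge[-nr])^3)
  out <- lapply(c("activator", "target"), function(ln) {
    kd <- if (is.null(k_d)) x$lines[[ln]]$k_d_spheroid else k_d
    a <- x$auc[x$auc$line == ln, ]
    tot <- tapply(a$auc_uM_min, a$r_um, sum)   # sum over compounds
    tot <- tot[order(as.numeric(names(tot)))]
    data.frame(line = ln,
               surviving_fraction = sum(Vk * exp(-kd * tot)) / sum(Vk))
  })
  do.call(rbind, out)
}
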