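#' Convert an extracellular half-life to a first-order loss rate constant
#'
#' Chemical instability of a compound in culture medium is summarised by a
#' half-life; the reaction-diffusion models consume the corresponding
#' first-order rate constant \eqn{k_{loss} = \ln 2 / T_{1/2}}.
#'
#' @param halflife Half-life in minutes. `Inf` is allowed and denotes a
#'   chemically stable compound (rate 0).
#' @return First-order loss rate constant in min^-1.
#' @examples
#' halflife_to_rate(1800)   # a 30 h half-life
#' halflife_to_rate(Inf)    # stable
#' @export
halflife_to_rate <- function(halflife) {
  if (!is.numeric(halflife) || length(halflife) != 1L || is.na(halflife))
    stop("`halflife` must be a single number (minutes)")
  if (is.infinite(halflife)) {
    if (halflife < 0) stop("`halflife` must be positive")
    return(0)
  }
  if (halflife <= 0) stop("`halflife` must be positive")
  log(2) / halflife
}

#' Kinetic and transport constants for one compound
#'
#' Bundles the per-compound constants of the cellular PK and tissue
#' transport models: membrane transfer rate constants, the maximum anoxic
#' intracellular metabolism rate per cell line, extracellular stability,
#' and diffusion coefficients.
#'
#' @param name Compound identifier.
#' @param parent Identifier of the compound this one is produced from by
#'   intracellular metabolism, or `NULL` for the prodrug (chain root).
#' @param k_in,k_out Membrane transfer rate constants (min^-1), extracellular
#'   to intracellular and back.
#' @param k_met0 Named numeric vector: maximum anoxic intracellular
#'   metabolism/instability rate constant (min^-1) per cell line, e.g.
#'   `c(activator = 0.12, target = 0.0019)`. A single unnamed value applies
#'   to every line.
#' @param halflife_extracellular Extracellular (medium) half-life in
#'   minutes; `Inf` for a stable compound.
#' @param oxygen_gated Logical; `TRUE` only for the prodrug, whose
#'   intracellular metabolism is inhibited by oxygen. Metabolite
#'   instability is treated as purely chemical (not gated).
#' @param is_cytotoxic Logical; does intracellular exposure to this
#'   compound contribute to the kill probability?
#' @param D_s,D_m Diffusion coefficients (cm^2/s) in tissue (spheroid/MCL
#'   extracellular space) and in free medium.
#' @return An object of class `compound_params`.
#' @export
compound_params <- function(name, parent = NULL,
                            k_in = 0, k_out = 0,
                            k_met0 = 0,
                            halflife_extracellular = Inf,
                            oxygen_gated = FALSE,
                            is_cytotoxic = FALSE,
                            D_s = 1.93e-7, D_m = 1.32e-6) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(parent)) stopifnot(is.character(parent), length(parent) == 1L)
  if (any(c(k_in, k_out, k_met0) < 0)) stop("rate constants must be >= 0")
  if (!(is.infinite(halflife_extracellular) || halflife_extracellular > 0))
    stop("halflife_extracellular must be > 0 (minutes) or Inf")
  if (oxygen_gated && !is.null(parent))
    stop("only the chain root (prodrug) can be oxygen gated")
  if (is.null(names(k_met0)) && length(k_met0) != 1L)
    stop("`k_met0` must be a single value or a named per-line vector")
  structure(list(
    name = name, parent = parent,
    k_in = k_in, k_out = k_out, k_met0 = k_met0,
    halflife_extracellular = halflife_extracellular,
    k_loss = halflife_to_rate(halflife_extracellular),
    oxygen_gated = isTRUE(oxygen_gated),
    is_cytotoxic = isTRUE(is_cytotoxic),
    D_s = D_s, D_m = D_m
  ), class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf("<compound_params> %s%s\n", x$name,
              if (is.null(x$parent)) " (chain root)"
              else paste0(" <- ", x$parent)))
  cat(sprintf("  k_in %.4g  k_out %.4g  min^-1 | T1/2(ext) %.4g min | %s%s\n",
              x$k_in, x$k_out, x$halflife_extracellular,
              if (x$oxygen_gated) "O2-gated " else "",
              if (x$is_cytotoxic) "cytotoxic" else ""))
  invisible(x)
}

## Resolve per-line k_met0 for a compound.
.kmet0_for_line <- function(cmp, line) {
  k <- cmp$k_met0
  if (is.null(names(k))) return(unname(k[1L]))
  if (line %in% names(k)) return(unname(k[[line]]))
  if ("default" %in% names(k)) return(unname(k[["default"]]))
  stop(sprintf("compound '%s' has no k_met0 for line '%s'", cmp$name, line))
}

#' Assemble and validate a metabolite chain
#'
#' A compound set is an ordered list of [compound_params()] whose `parent`
#' links form a single acyclic chain rooted at the prodrug. The terminal
#' compound's metabolism routes to an explicit sink so that mass balance
#' can be audited.
#'
#' @param ... `compound_params` objects (or a single list of them).
#' @return An object of class `compound_set`, ordered root first.
#' @export
compound_set <- function(...) {
  cl <- list(...)
  if (length(cl) == 1L && !inherits(cl[[1L]], "compound_params")) cl <- cl[[1L]]
  stopifnot(all(vapply(cl, inherits, TRUE, "compound_params")))
  nm <- vapply(cl, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate compound names")
  names(cl) <- nm
  roots <- nm[vapply(cl, function(x) is.null(x$parent), TRUE)]
  if (length(roots) != 1L)
    stop("compound chain must have exactly one root (the prodrug)")
  ## order root-first by walking parent links; detects cycles/bad links
  order <- roots
  repeat {
    nxt <- nm[vapply(cl, function(x)
      !is.null(x$parent) && x$parent == order[length(order)], TRUE)]
    if (length(nxt) == 0L) break
    if (length(nxt) > 1L)
      stop("chain must be linear: compound '", order[length(order)],
           "' has multiple products")
    if (nxt %in% order) stop("cycle in compound chain")
    order <- c(order, nxt)
  }
  if (length(order) != length(cl))
    stop("compound chain is disconnected: check `parent` links")
  structure(cl[order], class = "compound_set")
}

#' @export
print.compound_set <- function(x, ...) {
  cat("<compound_set> ", paste(names(x), collapse = " -> "), " -> sink\n")
  invisible(x)
}

#' Reference compound set for CP-506 and its reduced metabolites
#'
#' The published kinetic/transport constants for the prodrug CP-506 and its
#' sequential reduction products: hydroxylamine CP-506H, amine CP-506M and
#' dichloro-amine CP-506M-Cl2 (terminal; its metabolism routes to the sink).
#' Membrane transfer constants are in min^-1, half-lives are stored in
#' minutes (30 h, 0.18 h, 0.13 h, 4.52 h), diffusion coefficients in cm^2/s
#' (1.93e-7 in tissue, 1.32e-6 in medium for all four compounds).
#' Prodrug metabolism is oxygen gated and line dependent (activator
#' 0.12 min^-1, target 0.0019 min^-1); metabolite conversion is treated as
#' line-independent chemical instability.
#'
#' @return A [compound_set()] of four compounds, prodrug first.
#' @export
cp506_compounds <- function() {
  compound_set(
    compound_params("CP-506",
      k_in = 3.7, k_out = 0.06,
      k_met0 = c(activator = 0.12, target = 0.0019, default = 0.0019),
      halflife_extracellular = 30 * 60,
      oxygen_gated = TRUE, is_cytotoxic = FALSE),
    compound_params("CP-506H", parent = "CP-506",
      k_in = 0.9, k_out = 0.25, k_met0 = 0.09,
      halflife_extracellular = 0.18 * 60, is_cytotoxic = TRUE),
    compound_params("CP-506M", parent = "CP-506H",
      k_in = 0.9, k_out = 0.4, k_met0 = 0.1,
      halflife_extracellular = 0.13 * 60, is_cytotoxic = TRUE),
    compound_params("CP-506M-Cl2", parent = "CP-506M",
      k_in = 0.9, k_out = 0.3, k_met0 = 0.1,
      halflife_extracellular = 4.52 * 60, is_cytotoxic = TRUE)
  )
}

#' Cell-line parameters
#'
#' @param name Line identifier.
#' @param doubling_time Population doubling time in hours.
#' @param k_d_monolayer,k_d_spheroid Kill-probability rate constants
#'   (per µM per minute of intracellular cytotoxic-metabolite exposure) in
#'   monolayer and spheroid contexts.
#' @param label One of `"activator"`, `"target"`, `"wildtype"`; selects the
#'   per-line `k_met0` entry of each compound.
#' @return An object of class `cell_line_params`.
#' @export
cell_line_params <- function(name, doubling_time,
                             k_d_monolayer = 0.01, k_d_spheroid = 0.0256,
                             label = c("activator", "target", "wildtype")) {
  label <- match.arg(label)
  stopifnot(doubling_time > 0, k_d_monolayer >= 0, k_d_spheroid >= 0)
  structure(list(name = name, doubling_time = doubling_time,
                 k_d_monolayer = k_d_monolayer, k_d_spheroid = k_d_spheroid,
                 label = label),
            class = "cell_line_params")
}

#' Reference cell-line panel
#'
#' The reductase-overexpressing "activator" line, reductase-null "target"
#' line and parental wildtype, with their doubling times (21.7 h activator,
#' 22.95 h target) and the kill-probability constants estimated from
#' clonogenic assays (0.01 in monolayers, 0.0256 in spheroids; the prodrug
#' itself does not kill).
#'
#' @return Named list of [cell_line_params()].
#' @export
cp506_cell_lines <- function() {
  list(
    activator = cell_line_params("POR-overexpressing", 21.7,
                                 label = "activator"),
    target = cell_line_params("POR-knockout", 22.95, label = "target"),
    wildtype = cell_line_params("parental", 22.95, label = "wildtype")
  )
}

#' Oxygen gating of prodrug metabolism
#'
#' Prodrug activation proceeds via a nitro radical anion that is
#' back-oxidised by molecular oxygen, so the effective metabolism rate is
#' \eqn{k_{met0} \cdot g(O_2)} with a hyperbolic inhibition factor
#' \eqn{g(C) = 1 / (1 + (C/K)^h)}. The default gate (`K = 0.1` µM,
#' `h = 2`) gives \eqn{g(0)=1} and at least 99% inhibition above 1 µM O2,
#' matching the observed complete suppression of activation through the
#' physiological oxygen range. Metabolite instability is not gated.
#'
#' @param o2 Oxygen concentration(s), µM.
#' @param K Gate constant, µM.
#' @param hill Gate steepness.
#' @return Gating factor in \[0, 1\].
#' @export
oxygen_gate <- function(o2, K = 0.1, hill = 2) {
  stopifnot(all(o2 >= 0), K > 0, hill > 0)
  1 / (1 + (o2 / K)^hill)
}

## Effective intracellular metabolism rates for a compound set at a given
## oxygen level and cell line label: named vector, min^-1.
.kmet_effective <- function(compounds, line_label, o2) {
  g <- oxygen_gate(o2)
  vapply(compounds, function(cmp) {
    k <- .kmet0_for_line(cmp, line_label)
    if (cmp$oxygen_gated) k * g else k
  }, numeric(1L))
}

#' Read / write compound parameter sets as JSON
#'
#' The on-disk schema mirrors the published parameter table:
#' `k_in_per_min`, `k_out_per_min`, `k_met0_per_min` (named by line),
#' `halflife_h`, `parent`, `oxygen_gated`, `is_cytotoxic`,
#' `D_s_cm2_s`, `D_m_cm2_s`.
#'
#' @param x A `compound_set`.
#' @param path File path.
#' @return `write_compound_json()` returns `path` invisibly;
#'   `read_compound_json()` returns a `compound_set`.
#' @export
write_compound_json <- function(x, path) {
  stopifnot(inherits(x, "compound_set"))
  out <- lapply(unclass(x), function(cmp) list(
    parent = cmp$parent,
    k_in_per_min = cmp$k_in, k_out_per_min = cmp$k_out,
    k_met0_per_min = as.list(cmp$k_met0),
    halflife_h = if (is.infinite(cmp$halflife_extracellular)) NULL
                 else cmp$halflife_extracellular / 60,
    oxygen_gated = cmp$oxygen_gated, is_cytotoxic = cmp$is_cytotoxic,
    D_s_cm2_s = cmp$D_s, D_m_cm2_s = cmp$D_m))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_compound_json
#' @export
read_compound_json <- function(path) {
  raw <- jsonlite::read_json(path)
  cl <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    km <- unlist(r$k_met0_per_min)
    compound_params(nm, parent = r$parent,
                    k_in = r$k_in_per_min, k_out = r$k_out_per_min,
                    k_met0 = km,
                    halflife_extracellular =
                      if (is.null(r$halflife_h)) Inf else r$halflife_h * 60,
                    oxygen_gated = isTRUE(r$oxygen_gated),
                    is_cytotoxic = isTRUE(r$is_cytotoxic),
                    D_s = r$D_s_cm2_s, D_m = r$D_m_cm2_s)
  })
  compound_set(cl)
}
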