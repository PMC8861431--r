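#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + (top - bottom) / (1 + (x / ec50)^{hill})}
#' to fraction-of-control responses, on a log-concentration axis.
#' Zero-concentration (control) points are excluded from the fit but may
#' be used upstream for normalisation.
#'
#' @param concentrations Concentrations, µM (>= 0; at least 4 distinct
#'   positive values spanning the transition).
#' @param responses Fraction-of-control responses (same length).
#' @return An object of class `curve_4pl` with fields `top`, `bottom`,
#'   `ec50`, `hill`, `r_squared`.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations >= 0), all(is.finite(responses)))
  keep <- concentrations > 0
  x <- concentrations[keep]; y <- responses[keep]
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct positive concentrations for a 4PL fit")
  ymax <- max(y); ymin <- min(y)
  if (ymax - ymin < 1e-8)
    stop("non-convergence: responses show no transition across the range")
  ## starting values: midpoint response concentration by interpolation
  ymid <- (ymax + ymin) / 2
  ord <- order(x)
  ec0 <- exp(approx(y[ord], log(x[ord]), xout = ymid, ties = mean)$y)
  if (!is.finite(ec0)) ec0 <- exp(mean(log(x)))
  fn <- function(p) {
    pred <- p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + (x / exp(p[["lec50"]]))^exp(p[["lhill"]]))
    pred - y
  }
  fit <- minpack.lm::nls.lm(
    par = c(top = ymax, bottom = ymin, lec50 = log(ec0), lhill = 0),
    fn = fn, control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  if (p[["top"]] < p[["bottom"]]) {   # enforce top > bottom orientation
    tmp <- p[["top"]]; p[["top"]] <- p[["bottom"]]; p[["bottom"]] <- tmp
    p[["lhill"]] <- log(max(exp(p[["lhill"]]), 1e-6))  # degenerate; rare
  }
  pred <- p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + (x / exp(p[["lec50"]]))^exp(p[["lhill"]]))
  out <- structure(list(top = unname(p[["top"]]),
                        bottom = unname(p[["bottom"]]),
                        ec50 = unname(exp(p[["lec50"]])),
                        hill = unname(exp(p[["lhill"]])),
                        r_squared = .r_squared(y, pred)),
                   class = "curve_4pl")
  if (!is.finite(out$ec50) || out$ec50 <= 0)
    stop("non-convergence: no interpretable EC50 in range")
  out
}

#' @export
print.curve_4pl <- function(x, ...) {
  cat(sprintf(
    "<curve_4pl> top %.4g, bottom %.4g, ec50 %.4g uM, hill %.4g (R^2 %.4f)\n",
    x$top, x$bottom, x$ec50, x$hill, x$r_squared))
  invisible(x)
}

#' Evaluate a fitted 4PL curve
#'
#' @param object A `curve_4pl`.
#' @param newdata Concentrations, µM.
#' @param ... Unused.
#' @return Predicted fraction-of-control responses.
#' @export
predict.curve_4pl <- function(object, newdata, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (newdata / object$ec50)^object$hill)
}

#' Interpolate the IC50 from a fitted curve
#'
#' The IC50 is defined as the concentration at which the fitted response
#' equals 50% of the control level — not the 4PL midpoint `ec50`, which
#' coincides with it only when `bottom = 0` and `top = control_level`.
#' When the curve never reaches 50% of control within `range`, the
#' greater-than-range sentinel `Inf` is returned with attribute
#' `"censored" = ">max"` (mirroring ">40 µM"-style reporting).
#'
#' @param curve A `curve_4pl`.
#' @param control_level Response of the untreated control (default 1).
#' @param range Concentration search interval, µM.
#' @return IC50 in µM, or `Inf` (attribute `censored`) if no crossing.
#' @export
interpolate_ic50 <- function(curve, control_level = 1,
                             range = c(1e-4, 1e4)) {
  stopifnot(inherits(curve, "curve_4pl"), control_level > 0)
  target <- control_level / 2
  f <- function(x) predict(curve, x) - target
  if (f(range[2L]) > 0)
    return(structure(Inf, censored = ">max"))
  if (f(range[1L]) < 0)
    return(structure(range[1L], censored = "<min"))
  uniroot(f, range, tol = 1e-10)$root
}

#' Clonogenic surviving fraction
#'
#' Ratio of the plating efficiency of treated cells to that of controls.
#'
#' @param treated_colonies,control_colonies Colony counts (>= 0).
#' @param treated_plated,control_plated Cells plated (> 0).
#' @return Surviving fraction.
#' @export
surviving_fraction <- function(treated_colonies, control_colonies,
                               treated_plated, control_plated = treated_plated) {
  stopifnot(all(treated_colonies >= 0), all(control_colonies >= 0),
            all(treated_plated > 0), all(control_plated > 0))
  if (any(control_colonies == 0))
    stop("undefined control: zero colonies in the control plating")
  (treated_colonies / treated_plated) / (control_colonies / control_plated)
}

#' Fold ratio between two concentrations
#'
#' @param a,b Concentrations (same units); `b > 0`.
#' @param digits Significant digits for reporting (default 3).
#' @return `a / b` rounded to `digits` significant figures.
#' @export
fold_ratio <- function(a, b, digits = 3) {
  stopifnot(all(b > 0))
  signif(a / b, digits)
}
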