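## Shared least-squares machinery.
##
## All stage fits minimise proportionally weighted residuals
## (model - obs) / max(obs, lloq) with censored observations excluded,
## via Levenberg-Marquardt (minpack.lm::nls.lm) on log-transformed
## parameters (which enforces positivity and makes scale-free steps).
## A small number of seeded multi-starts guards against local minima.

.hap_objective <- function(pred, obs, lloq) {
  (pred - obs) / pmax(obs, lloq)
}

## residual_fn(pars_natural) -> weighted residual vector.
## start: named vector of natural-scale starting values.
.hap_ls_fit <- function(residual_fn, start, lower = NULL, upper = NULL,
                        multistart = 5L, seed = 1L, spread = 0.5,
                        maxiter = 200L) {
  pn <- names(start)
  if (is.null(pn)) stop("start values must be named")
  log_lower <- if (is.null(lower)) rep(-Inf, length(start)) else log(lower)
  log_upper <- if (is.null(upper)) rep(Inf, length(start)) else log(upper)
  fn_log <- function(lp) {
    r <- residual_fn(as.list(setNames(exp(lp), pn)))
    r[!is.finite(r)] <- 1e6
    r
  }
  starts <- list(log(start))
  if (multistart > 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (i in seq_len(multistart - 1L)) {
      lp <- log(start) + rnorm(length(start), sd = spread)
      starts[[i + 1L]] <- pmin(pmax(lp, log_lower), log_upper)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  best <- NULL
  for (s in starts) {
    ## epsfcn keeps finite-difference Jacobian steps (~1% of each
    ## log-parameter) well above the forward solvers' integration noise
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = fn_log, lower = log_lower, upper = log_upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           epsfcn = 1e-4)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("least-squares fit failed from every start")
  best
}

## Build a `hap_fit` result from an nls.lm fit on log-scale parameters.
## obs is the vector of (uncensored) observations entering the objective.
.hap_fit_result <- function(fit, obs, fixed = list(), extra = list()) {
  lp <- fit$par
  est <- exp(lp)
  ## delta method: sd(exp(lp)) = exp(lp) * sd(lp)
  se <- rep(NA_real_, length(est))
  dof <- length(fit$fvec) - length(lp)
  if (dof > 0 && !is.null(fit$hessian)) {
    vc <- try(solve(fit$hessian) * fit$deviance / dof, silent = TRUE)
    if (!inherits(vc, "try-error") && all(is.finite(diag(vc))))
      se <- est * sqrt(pmax(diag(vc), 0))
  }
  names(se) <- names(est)
  structure(c(list(estimates = as.list(est), stderr = as.list(se),
                   residuals = fit$fvec, deviance = fit$deviance,
                   fixed = fixed,
                   r_squared = NA_real_, n_obs = length(obs)),
              extra),
            class = "hap_fit")
}

## R^2 = 1 - SSR/SST computed on untransformed concentrations.
.r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' @export
print.hap_fit <- function(x, ...) {
  cat("<hap_fit>\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %-14s %.6g (se %.3g)\n", nm, x$estimates[[nm]],
                x$stderr[[nm]]))
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed),
                          signif(unlist(x$fixed), 4), sep = "=",
                          collapse = ", "), "\n")
  if (is.finite(x$r_squared))
    cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, x$n_obs))
  invisible(x)
}

#' Extract estimated parameters from a model fit
#'
#' @param object A `hap_fit`.
#' @param ... Unused.
#' @return Named numeric vector of estimates.
#' @export
coef.hap_fit <- function(object, ...) unlist(object$estimates)
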