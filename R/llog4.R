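#' Four-parameter log-logistic concentration-response model
#'
#' `fit_llog4()` fits the log(inhibitor) vs. response, variable-slope
#' model
#' \deqn{Y = Bottom + \frac{Top - Bottom}{1 + 10^{(\log EC_{50} - X)\,
#'   Hillslope}}}
#' where \eqn{X = \log_{10}} concentration (mg/L) and \eqn{Y} is percent
#' growth inhibition. The basal response `Bottom` is fixed at 0, as is
#' standard for inhibition data normalised against untreated controls;
#' `Top`, `logEC50` and `Hillslope` are estimated by Levenberg-Marquardt
#' least squares with box constraints.
#'
#' Zero-concentration (control) records must not appear among the fitted
#' points: controls are used upstream to normalise responses (see
#' [compute_inhibition()]) and have no position on the log-concentration
#' axis. Inhibition values outside \[0, 100\] (e.g. mild hormesis) are
#' clipped to that range for fitting only.
#'
#' @param formula model formula, `inhibition ~ concentration`. The
#'   response may be on the percent (0-100) or fraction (0-1) scale,
#'   controlled by `scale`.
#' @param data a data frame containing the variables of `formula`, one
#'   row per replicate measurement at a positive concentration (mg/L).
#' @param top_policy `"free"` (default) estimates `Top` within
#'   `(0, 120]`; `"fixed_100"` pins it at 100 for data already expressed
#'   as percent inhibition of a full effect.
#' @param scale `"auto"` (default) treats the response as fractions when
#'   every value is at most 1.5 in absolute value and as percent
#'   otherwise; `"percent"` and `"fraction"` force the interpretation.
#' @param control a list from [llog4_control()].
#' @return An object of class `"llog4"`: a list with components
#'   `coefficients` (named vector `bottom`, `top`, `log_ec50`,
#'   `hillslope`), `r.squared`, `n`, `converged`, `fitted.values`,
#'   `residuals`, `data` (the clipped percent-scale points used),
#'   `top_policy` and `call`.
#' @examples
#' d <- data.frame(concentration = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.2),
#'                 inhibition    = c(4, 23, 42, 55, 65, 76))
#' fit <- fit_llog4(inhibition ~ concentration, d)
#' coef(fit)
#' ecx(fit, 50)
#' @seealso [ecx()], [effect_at()], [predict.llog4()]
#' @export
fit_llog4 <- function(formula, data,
                      top_policy = c("free", "fixed_100"),
                      scale = c("auto", "percent", "fraction"),
                      control = llog4_control()) {
  top_policy <- match.arg(top_policy)
  scale <- match.arg(scale)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  conc <- mf[[2L]]

  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all concentrations must be finite and > 0; ",
         "controls (concentration 0) are for normalisation only")
  }
  if (scale == "auto") {
    scale <- if (all(abs(y) <= 1.5)) "fraction" else "percent"
  }
  if (scale == "fraction") y <- 100 * y

  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct positive concentrations to fit ",
         "a three-parameter constrained curve")
  }
  if (length(unique(y)) < 2L) {
    stop("all responses are identical; concentration-response curve ",
         "is undefined")
  }

  # hormesis / overshoot: clip to the valid model range for fitting only
  yfit <- pmin(pmax(y, 0), 100)
  lx <- log10(conc)

  resid_fun <- function(p) {
    yfit - llog4_curve(conc, top = p[["top"]], log_ec50 = p[["log_ec50"]],
                       hillslope = p[["hillslope"]])
  }

  start <- c(top = max(yfit), log_ec50 = stats::median(lx), hillslope = 1)
  if (top_policy == "fixed_100") start[["top"]] <- 100
  lower <- c(top = 1e-3, log_ec50 = min(lx) - 3, hillslope = 1e-3)
  upper <- c(top = 120,  log_ec50 = max(lx) + 3, hillslope = 50)
  if (top_policy == "fixed_100") {
    lower[["top"]] <- 100
    upper[["top"]] <- 100
  }

  # deterministic jittered restarts around the heuristic start
  jitters <- rbind(c(0, 0, 0),
                   c(5, 0.3, 0.5), c(-5, -0.3, 0.5),
                   c(10, 0.6, 2),  c(-10, -0.6, -0.5),
                   c(0, 0, 3))
  best <- NULL
  for (k in seq_len(min(nrow(jitters), control$restarts + 1L))) {
    st <- pmin(pmax(start + jitters[k, ], lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = control$maxit,
                           ftol = control$ftol, ptol = control$ptol)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && res$deviance < best$fit$deviance - 1e-12)) {
      best <- list(fit = res, ok = ok)
    }
    if (!is.null(best) && best$ok && k == 1L &&
        best$fit$deviance < control$ftol) break
  }
  if (is.null(best)) {
    stop("log-logistic fit failed: optimiser did not return a solution")
  }

  p <- stats::coef(best$fit)
  fitted <- llog4_curve(conc, top = p[["top"]], log_ec50 = p[["log_ec50"]],
                        hillslope = p[["hillslope"]])
  ss_res <- sum((yfit - fitted)^2)
  ss_tot <- sum((yfit - mean(yfit))^2)

  structure(list(
    coefficients = c(bottom = 0, top = unname(p[["top"]]),
                     log_ec50 = unname(p[["log_ec50"]]),
                     hillslope = unname(p[["hillslope"]])),
    r.squared = 1 - ss_res / ss_tot,
    n = length(yfit),
    converged = best$ok,
    fitted.values = fitted,
    residuals = yfit - fitted,
    data = data.frame(concentration = conc, inhibition = yfit),
    top_policy = top_policy,
    call = match.call()), class = "llog4")
}

#' Optimiser settings for [fit_llog4()]
#'
#' @param maxit maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol convergence tolerances on the cost and parameters.
#' @param restarts number of deterministic jittered restarts tried when
#'   the first start does not converge (or to escape a poor local
#'   optimum).
#' @return a list of settings.
#' @export
llog4_control <- function(maxit = 1024L, ftol = 1e-12, ptol = 1e-12,
                          restarts = 5L) {
  stopifnot(maxit >= 1, ftol > 0, ptol > 0, restarts >= 0)
  list(maxit = as.integer(maxit), ftol = ftol, ptol = ptol,
       restarts = as.integer(restarts))
}

#' Construct a fitted-curve object from known parameters
#'
#' Builds an `"llog4"` object directly from curve parameters, e.g. for
#' literature EC50s or the true curves of a synthetic dataset. All
#' downstream prediction ([effect_at()], [ecx()], mixture models) works
#' on such objects exactly as on fitted ones.
#'
#' @param top upper asymptote, percent effect in `(0, 120]`.
#' @param ec50 half-maximal effective concentration, mg/L (> 0).
#' @param hillslope steepness of the curve (> 0 for inhibition data).
#' @param bottom basal response; must be 0 for this constrained model.
#' @return an object of class `"llog4"` with `NA` fit diagnostics.
#' @examples
#' smx <- llog4(top = 100, ec50 = 0.612, hillslope = 2)
#' effect_at(smx, 0.612)
#' @export
llog4 <- function(top = 100, ec50, hillslope, bottom = 0) {
  stopifnot(is.numeric(top), length(top) == 1L, top > 0, top <= 120,
            is.numeric(ec50), length(ec50) == 1L, ec50 > 0,
            is.numeric(hillslope), length(hillslope) == 1L, hillslope > 0)
  if (!identical(as.numeric(bottom), 0)) {
    stop("bottom is fixed at 0 in this constrained model")
  }
  structure(list(
    coefficients = c(bottom = 0, top = top, log_ec50 = log10(ec50),
                     hillslope = hillslope),
    r.squared = NA_real_, n = 0L, converged = NA,
    fitted.values = numeric(0), residuals = numeric(0),
    data = NULL, top_policy = "free", call = match.call()),
    class = "llog4")
}

# core curve evaluation on the percent scale (vectorised, unchecked)
llog4_curve <- function(conc, top, log_ec50, hillslope, bottom = 0) {
  bottom + (top - bottom) / (1 + 10^((log_ec50 - log10(conc)) * hillslope))
}

#' Evaluate a concentration-response curve
#'
#' Percent effect predicted by a fitted (or constructed) log-logistic
#' curve at given concentrations. Strictly increasing in concentration
#' for positive hill slopes, tending to `bottom` as the concentration
#' approaches 0 and to `top` at high concentration.
#'
#' @param curve an `"llog4"` object.
#' @param concentration numeric vector of concentrations, mg/L (> 0).
#' @return percent effect, same length as `concentration`.
#' @export
effect_at <- function(curve, concentration) {
  stopifnot(inherits(curve, "llog4"))
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration must be finite and > 0 ",
         "(the log-scale model is undefined at 0)")
  }
  p <- curve$coefficients
  llog4_curve(concentration, top = p[["top"]], log_ec50 = p[["log_ec50"]],
              hillslope = p[["hillslope"]], bottom = p[["bottom"]])
}

#' Effective concentration for an x% effect level
#'
#' Inverts the fitted curve in closed form:
#' \deqn{\log EC_x = \log EC_{50} + \frac{1}{Hillslope}
#'   \log_{10}\frac{x}{100 - x}}
#' `x` is expressed on the bottom-top span, so `ecx(curve, 50)` is
#' exactly `10^log_ec50` regardless of the fitted `Top`, and
#' `effect_at(curve, ecx(curve, x))` equals
#' `bottom + x * (top - bottom) / 100`.
#'
#' @param curve an `"llog4"` object.
#' @param x numeric vector of effect levels, percent, each in (0, 100).
#' @return effective concentrations, mg/L.
#' @examples
#' crv <- llog4(top = 100, ec50 = 2, hillslope = 1)
#' ecx(crv, c(10, 50, 90))
#' @export
ecx <- function(curve, x) {
  stopifnot(inherits(curve, "llog4"))
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 100)) {
    stop("effect level x must lie strictly inside (0, 100)")
  }
  p <- curve$coefficients
  10^(p[["log_ec50"]] + log10(x / (100 - x)) / p[["hillslope"]])
}

#' @export
coef.llog4 <- function(object, ...) object$coefficients

#' Predicted percent effect at new concentrations
#'
#' @param object an `"llog4"` object.
#' @param newdata data frame with a `concentration` column, or `NULL`
#'   to predict at the fitted concentrations.
#' @param ... unused.
#' @return numeric vector of percent effects.
#' @export
predict.llog4 <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    if (is.null(object$data)) stop("no fitted data; supply newdata")
    object$data$concentration
  } else if (is.data.frame(newdata)) {
    newdata$concentration
  } else {
    as.numeric(newdata)
  }
  effect_at(object, conc)
}

#' @export
residuals.llog4 <- function(object, ...) object$residuals

#' @export
fitted.llog4 <- function(object, ...) object$fitted.values

#' @export
print.llog4 <- function(x, digits = 4, ...) {
  p <- x$coefficients
  cat("Four-parameter log-logistic curve (Bottom fixed at 0)\n")
  cat(sprintf("  Top       : %.*g %%\n", digits, p[["top"]]))
  cat(sprintf("  EC50      : %.*g mg/L  (logEC50 = %.*g)\n",
              digits, 10^p[["log_ec50"]], digits, p[["log_ec50"]]))
  cat(sprintf("  Hillslope : %.*g\n", digits, p[["hillslope"]]))
  if (!is.na(x$r.squared)) {
    cat(sprintf("  R-squared : %.*g on %d points; converged: %s\n",
                digits, x$r.squared, x$n, x$converged))
  }
  invisible(x)
}

#' @export
summary.llog4 <- function(object, levels = c(10, 30, 50, 70, 90), ...) {
  out <- list(curve = object,
              ecx = data.frame(effect_level = levels,
                               ecx_mg_L = ecx(object, levels)))
  class(out) <- "summary.llog4"
  out
}

#' @export
print.summary.llog4 <- function(x, ...) {
  print(x$curve)
  cat("\nEffective concentrations:\n")
  print(x$ecx, row.names = FALSE)
  invisible(x)
}

#' Plot a fitted concentration-response curve
#'
#' Observed points (if the object was fitted) and the predicted curve on
#' a log10 concentration axis.
#'
#' @param x an `"llog4"` object.
#' @param xlim concentration range, mg/L; defaults to the data range or
#'   EC1-EC99.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.llog4 <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) {
    xlim <- if (!is.null(x$data)) range(x$data$concentration)
            else ecx(x, c(1, 99))
  }
  cgrid <- 10^seq(log10(xlim[1]), log10(xlim[2]), length.out = 200)
  graphics::plot(cgrid, effect_at(x, cgrid), type = "l", log = "x",
                 xlab = "concentration (mg/L)",
                 ylab = "growth inhibition (%)", ylim = c(0, 105), ...)
  if (!is.null(x$data)) {
    graphics::points(x$data$concentration, x$data$inhibition, pch = 19)
  }
  invisible(x)
}

#' Simulate replicate assay datasets from a fitted curve
#'
#' Uses the fitted parameters as the generating truth for
#' [gen_single()]; see that function for the noise model.
#'
#' @param object an `"llog4"` object.
#' @param nsim number of datasets.
#' @param seed integer seed; consecutive datasets use `seed`, `seed+1`,
#'   ...
#' @param concentrations concentration series including the 0 control.
#' @param ... passed on to [gen_single()] (noise level, replicates, ...).
#' @return a list of `nsim` response-record data frames.
#' @export
simulate.llog4 <- function(object, nsim = 1, seed = 1,
                           concentrations = NULL, ...) {
  p <- object$coefficients
  if (is.null(concentrations)) {
    concentrations <- c(0, ecx(object, c(5, 15, 30, 50, 70, 90)))
  }
  truth <- synthetic_truth(
    curves = list(sim = list(top = p[["top"]], ec50 = 10^p[["log_ec50"]],
                             hillslope = p[["hillslope"]])),
    seed = seed, ...)
  lapply(seq_len(nsim), function(i) {
    truth$seed <- seed + i - 1L
    gen_single(truth, concentrations)
  })
}
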