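#' Binary (or n-ary) mixture design
#'
#' Fixes the identities and mixing proportions of the components of a
#' mixture. Proportions `P_i` are fractions of the *total* mixture
#' concentration and must sum to 1. Instead of explicit proportions a
#' `ratio_rule` may be given:
#' \describe{
#'   \item{`ec50_proportional`}{`P_i = EC50_i / sum(EC50)` - the
#'     components are blended in the ratio of their individual EC50s
#'     (the default, standard for equitoxic binary designs); resolved
#'     against the component curves at prediction time.}
#'   \item{`fixed_equal`}{equal proportions `1/n` (a 1:1 mixture for two
#'     components).}
#'   \item{`custom`}{explicit `proportions` supplied by the user.}
#' }
#'
#' @param component_ids character vector of component labels (n >= 2,
#'   except for degenerate single-component designs used in model
#'   consistency checks).
#' @param proportions numeric proportions summing to 1 (implies
#'   `ratio_rule = "custom"`), or `NULL`.
#' @param ratio_rule one of `"ec50_proportional"`, `"fixed_equal"`,
#'   `"custom"`.
#' @return an object of class `"mixture_design"`.
#' @examples
#' mixture_design(c("SMX", "SMZ"))                      # EC50-ratio blend
#' mixture_design(c("SMX", "ERY"), ratio_rule = "fixed_equal")
#' mixture_design(c("A", "B"), proportions = c(0.3, 0.7))
#' @export
mixture_design <- function(component_ids, proportions = NULL,
                           ratio_rule = c("ec50_proportional",
                                          "fixed_equal", "custom")) {
  if (!is.null(proportions) && length(ratio_rule) == 3L) {
    ratio_rule <- "custom"
  }
  ratio_rule <- match.arg(ratio_rule)
  component_ids <- as.character(component_ids)
  if (length(component_ids) < 1L || anyDuplicated(component_ids)) {
    stop("component_ids must be a non-empty set of distinct labels")
  }
  if (ratio_rule == "custom") {
    if (is.null(proportions)) {
      stop("ratio_rule 'custom' requires explicit proportions")
    }
    if (length(proportions) != length(component_ids)) {
      stop("proportions must match component_ids in length")
    }
    if (any(!is.finite(proportions)) || any(proportions <= 0)) {
      stop("all proportions must be finite and > 0")
    }
    if (abs(sum(proportions) - 1) > 1e-12) {
      stop("proportions must sum to 1 (got ", format(sum(proportions)),
           ")")
    }
    proportions <- stats::setNames(as.numeric(proportions), component_ids)
  } else {
    proportions <- NULL
  }
  structure(list(component_ids = component_ids,
                 proportions = proportions,
                 ratio_rule = ratio_rule),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("Mixture design:", paste(x$component_ids, collapse = " + "),
      sprintf("(rule: %s)\n", x$ratio_rule))
  if (!is.null(x$proportions)) {
    cat("  proportions:",
        paste(sprintf("%s = %.4g", names(x$proportions), x$proportions),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# resolve proportions against the component curves; curves is a named
# list of llog4 objects covering design$component_ids
resolve_proportions <- function(design, curves) {
  stopifnot(inherits(design, "mixture_design"))
  ids <- design$component_ids
  missing_ids <- setdiff(ids, names(curves))
  if (length(missing_ids)) {
    stop("no fitted curve supplied for component(s): ",
         paste(missing_ids, collapse = ", "))
  }
  switch(design$ratio_rule,
    custom = design$proportions[ids],
    fixed_equal = stats::setNames(rep(1 / length(ids), length(ids)), ids),
    ec50_proportional = {
      ec50 <- vapply(curves[ids],
                     function(crv) 10^crv$coefficients[["log_ec50"]],
                     numeric(1))
      ec50 / sum(ec50)
    })
}

#' Concentration-addition (Loewe) mixture ECx
#'
#' Under concentration addition the components act as dilutions of one
#' another, and the total mixture concentration producing an x% effect
#' is the proportion-weighted harmonic combination of the single
#' compound effective concentrations:
#' \deqn{EC_{x,mix} = \left( \sum_i \frac{P_i}{EC_{x,i}} \right)^{-1}}
#'
#' @param curves named list of `"llog4"` component curves.
#' @param design a [mixture_design()] over (a subset of) the curve
#'   names.
#' @param x effect level(s), percent, each in (0, 100).
#' @return predicted mixture ECx, mg/L (vectorised over `x`).
#' @examples
#' crvs <- list(A = llog4(ec50 = 1, hillslope = 1),
#'              B = llog4(ec50 = 3, hillslope = 1))
#' ca_ecx(crvs, mixture_design(c("A", "B"), proportions = c(.5, .5)), 50)
#' @export
ca_ecx <- function(curves, design, x) {
  p <- resolve_proportions(design, curves)
  ids <- design$component_ids
  vapply(x, function(xi) {
    ecx_i <- vapply(ids, function(id) ecx(curves[[id]], xi), numeric(1))
    bad <- !is.finite(ecx_i) | ecx_i <= 0
    if (any(bad)) {
      stop("non-finite single-compound EC", xi, " for component(s): ",
           paste(ids[bad], collapse = ", "))
    }
    1 / sum(p / ecx_i)
  }, numeric(1))
}

#' Independent-action (Bliss) mixture effect
#'
#' Under independent action the components act through unrelated
#' pathways and their non-effects multiply: at total mixture
#' concentration `c` with proportions `P_i`,
#' \deqn{E_{mix}(c) = 1 - \prod_i \left(1 - E_i(P_i\, c)\right)}
#' where `E_i` is component i's single-compound fractional effect at
#' its partial concentration. The result is a fraction in \[0, 1\],
#' non-decreasing in `c`, and at least the largest individual
#' component effect.
#'
#' @inheritParams ca_ecx
#' @param total_concentration total mixture concentration(s), mg/L
#'   (> 0).
#' @return fractional mixture effect(s) in \[0, 1\].
#' @export
ia_effect <- function(curves, design, total_concentration) {
  p <- resolve_proportions(design, curves)
  ids <- design$component_ids
  if (any(!is.finite(total_concentration)) ||
      any(total_concentration <= 0)) {
    stop("total_concentration must be finite and > 0")
  }
  vapply(total_concentration, function(ct) {
    e <- vapply(ids,
                function(id) effect_at(curves[[id]], p[[id]] * ct) / 100,
                numeric(1))
    if (any(e > 1 + 1e-9)) {
      stop("component fractional effect exceeds 1 (Top > 100 at this ",
           "concentration); the independent-action product is undefined")
    }
    e <- pmin(pmax(e, 0), 1)
    1 - prod(1 - e)
  }, numeric(1))
}

#' Independent-action mixture ECx by numerical inversion
#'
#' Solves `ia_effect(curves, design, c) = x/100` for the total mixture
#' concentration `c` by bisection on the log10 concentration scale
#' (relative tolerance 1e-10). The attainable ceiling is
#' `1 - prod(1 - top_i/100)`; requesting an effect level at or above it
#' is an error that reports the ceiling.
#'
#' @inheritParams ca_ecx
#' @return predicted mixture ECx, mg/L (vectorised over `x`).
#' @export
ia_ecx <- function(curves, design, x) {
  p <- resolve_proportions(design, curves)
  ids <- design$component_ids
  tops <- vapply(curves[ids],
                 function(crv) min(crv$coefficients[["top"]], 100),
                 numeric(1))
  ceiling_frac <- 1 - prod(1 - tops / 100)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("effect level x must be > 0")
  }
  vapply(x, function(xi) {
    target <- xi / 100
    if (target >= ceiling_frac - 1e-12) {
      stop(sprintf(paste0("effect level %.4g%% is not attainable: the ",
                          "mixture effect is bounded above by %.6g%%"),
                   xi, 100 * ceiling_frac))
    }
    # bracket on the log scale starting from the component EC50 range
    ec50s <- vapply(curves[ids],
                    function(crv) 10^crv$coefficients[["log_ec50"]],
                    numeric(1))
    lo <- log10(min(ec50s)) - 9
    hi <- log10(max(ec50s)) + 3
    while (ia_effect(curves, design, 10^hi) < target) {
      hi <- hi + 3
      if (hi > 60) stop("failed to bracket the IA ECx from above")
    }
    while (ia_effect(curves, design, 10^lo) > target) lo <- lo - 3
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (ia_effect(curves, design, 10^mid) < target) lo <- mid
      else hi <- mid
      if (hi - lo < 4e-11) break  # ~1e-10 relative in concentration
    }
    10^((lo + hi) / 2)
  }, numeric(1))
}

#' Mixture concentration-response predictions over a grid
#'
#' Convenience wrapper computing predicted ECx values at a set of effect
#' levels under one or both mixture models.
#'
#' @inheritParams ca_ecx
#' @param models character subset of `c("CA", "IA")`.
#' @param effect_levels percent effect levels.
#' @return a data frame with columns `model`, `effect_level`,
#'   `predicted_ecx_mg_L`.
#' @export
predict_mixture <- function(curves, design, models = c("CA", "IA"),
                            effect_levels = c(10, 30, 50, 70, 90)) {
  models <- match.arg(toupper(models), c("CA", "IA"), several.ok = TRUE)
  out <- do.call(rbind, lapply(models, function(m) {
    pred <- if (m == "CA") ca_ecx(curves, design, effect_levels)
            else ia_ecx(curves, design, effect_levels)
    data.frame(model = m, effect_level = effect_levels,
               predicted_ecx_mg_L = pred)
  }))
  rownames(out) <- NULL
  out
}
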