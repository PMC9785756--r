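#' Concentration unit conversion
#'
#' Normalises environmental concentrations to mg/L. Recognised units:
#' `"ng/L"`, `"ug/L"` (also `"µg/L"` / `"μg/L"`), `"mg/L"`.
#'
#' @param value numeric concentrations.
#' @param unit character unit string (scalar or per-value).
#' @return concentrations in mg/L.
#' @export
to_mg_per_L <- function(value, unit) {
  factor_of <- function(u) {
    u <- gsub("µ|μ", "u", trimws(u))
    switch(tolower(u),
           "ng/l" = 1e-6, "ug/l" = 1e-3, "mg/l" = 1,
           stop("unrecognised concentration unit: '", u,
                "' (expected ng/L, ug/L or mg/L)"))
  }
  value * vapply(as.character(unit), factor_of, numeric(1),
                 USE.NAMES = FALSE)
}

#' Predicted no-effect concentration
#'
#' `PNEC = EC50 / AF`, with the assessment factor defaulting to 1000 as
#' appropriate when only acute EC50 data are available.
#'
#' @param ec50 acute EC50, mg/L (> 0).
#' @param assessment_factor dimensionless safety factor (> 0).
#' @return PNEC in mg/L.
#' @examples
#' pnec(0.612)  # 0.000612 mg/L
#' @export
pnec <- function(ec50, assessment_factor = 1000) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop("ec50 must be finite and > 0")
  }
  if (!is.finite(assessment_factor) || assessment_factor <= 0) {
    stop("assessment_factor must be > 0")
  }
  ec50 / assessment_factor
}

#' Risk grade from a risk quotient
#'
#' Four-band grading of risk quotients with boundary values belonging to
#' the upper band: `rq < 0.01` insignificant; `0.01 <= rq < 0.1` low;
#' `0.1 <= rq < 1` medium; `rq >= 1` high.
#'
#' @param rq numeric risk quotient(s), each >= 0.
#' @return character vector of grades.
#' @export
classify_risk <- function(rq) {
  if (any(!is.finite(rq)) || any(rq < 0)) {
    stop("risk quotient must be finite and >= 0")
  }
  ifelse(rq >= 1, "high",
         ifelse(rq >= 0.1, "medium",
                ifelse(rq >= 0.01, "low", "insignificant")))
}

#' Intrinsic-toxicity band from an acute EC50
#'
#' EU Directive 93/67/EEC hazard bands by acute EC50: below 1 mg/L
#' "very toxic", 1-10 mg/L "toxic", 10-100 mg/L "harmful". Boundaries
#' are closed on the left (an EC50 of exactly 10 mg/L is "harmful");
#' above 100 mg/L no band is defined and `"unclassified_low_concern"`
#' is reported.
#'
#' @param ec50 acute EC50(s), mg/L (> 0).
#' @return character vector of bands.
#' @examples
#' classify_toxicity(c(0.612, 3.235, 15))
#' @export
classify_toxicity <- function(ec50) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop("ec50 must be finite and > 0")
  }
  ifelse(ec50 > 100, "unclassified_low_concern",
         ifelse(ec50 >= 10, "harmful",
                ifelse(ec50 >= 1, "toxic", "very_toxic")))
}

# normalise and validate an exposure table to mg/L
normalise_exposures <- function(exposures) {
  required <- c("compound_id", "mec", "mec_unit")
  miss <- setdiff(required, names(exposures))
  if (length(miss)) {
    stop("exposure table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(!is.finite(exposures$mec)) || any(exposures$mec < 0)) {
    stop("mec must be finite and >= 0")
  }
  exposures$mec_mg_L <- to_mg_per_L(exposures$mec, exposures$mec_unit)
  exposures
}

validate_toxicity <- function(toxicities) {
  required <- c("compound_id", "trophic_level", "ec50_mg_L")
  miss <- setdiff(required, names(toxicities))
  if (length(miss)) {
    stop("toxicity table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(!is.finite(toxicities$ec50_mg_L)) ||
      any(toxicities$ec50_mg_L <= 0)) {
    stop("ec50_mg_L must be finite and > 0")
  }
  ok_levels <- c("algae", "daphnia", "fish")
  bad <- setdiff(unique(toxicities$trophic_level), ok_levels)
  if (length(bad)) {
    stop("unknown trophic level(s): ", paste(bad, collapse = ", "))
  }
  toxicities
}

#' Mixture risk quotient by the MEC/PNEC method
#'
#' Per compound, `RQ_i = MEC_i / PNEC_i` with `PNEC_i = EC50_i / AF`
#' using the algal EC50; the mixture risk quotient is the sum of the
#' component quotients, so it is always at least the largest component
#' quotient.
#'
#' @param exposures data frame with columns `compound_id`, `mec`,
#'   `mec_unit` (and optionally `environment`); the highest detected
#'   concentration per compound should be supplied.
#' @param toxicities data frame with columns `compound_id`,
#'   `trophic_level`, `ec50_mg_L` (and optionally `source`); an `algae`
#'   record is required per exposed compound.
#' @param af assessment factor, default 1000.
#' @return an object of class `"rq_result"`: a list with `method`,
#'   `rq`, `grade`, `driver` (component with the largest quotient),
#'   `af` and a `per_compound` breakdown data frame.
#' @export
rq_mec_pnec <- function(exposures, toxicities, af = 1000) {
  exposures <- normalise_exposures(exposures)
  toxicities <- validate_toxicity(toxicities)
  algae <- toxicities[toxicities$trophic_level == "algae", ]
  miss <- setdiff(exposures$compound_id, algae$compound_id)
  if (length(miss)) {
    stop("no algal EC50 available for compound(s): ",
         paste(miss, collapse = ", "))
  }
  ec50 <- algae$ec50_mg_L[match(exposures$compound_id,
                                algae$compound_id)]
  rq_i <- exposures$mec_mg_L / pnec(ec50, af)
  per_compound <- data.frame(compound_id = exposures$compound_id,
                             mec_mg_L = exposures$mec_mg_L,
                             ec50_mg_L = ec50,
                             pnec_mg_L = pnec(ec50, af),
                             rq = rq_i,
                             grade = classify_risk(rq_i))
  total <- sum(rq_i)
  structure(list(method = "mec_pnec", rq = total,
                 grade = classify_risk(total),
                 driver = per_compound$compound_id[which.max(rq_i)],
                 af = af, per_compound = per_compound),
            class = "rq_result")
}

#' Mixture risk quotient by toxic-unit summation
#'
#' For each trophic level with complete EC50 coverage of the mixture
#' components, the sum of toxic units is
#' `STU_level = sum_i MEC_i / EC50_{i,level}`; the risk quotient is the
#' maximum STU across algae, daphnia and fish multiplied by the
#' assessment factor. A trophic level with only partial EC50 coverage
#' is skipped with a warning rather than summed over a subset. With
#' algae-only data and the same AF this reduces exactly to
#' [rq_mec_pnec()].
#'
#' @inheritParams rq_mec_pnec
#' @return an `"rq_result"` whose `driver` is the trophic level
#'   attaining the maximum STU and whose `per_level` element tabulates
#'   the STU per covered level.
#' @export
rq_stu <- function(exposures, toxicities, af = 1000) {
  exposures <- normalise_exposures(exposures)
  toxicities <- validate_toxicity(toxicities)
  levels_present <- intersect(c("algae", "daphnia", "fish"),
                              unique(toxicities$trophic_level))
  stu <- numeric(0)
  for (lv in levels_present) {
    tox_lv <- toxicities[toxicities$trophic_level == lv, ]
    miss <- setdiff(exposures$compound_id, tox_lv$compound_id)
    if (length(miss)) {
      warning("trophic level '", lv, "' skipped: no EC50 for ",
              paste(miss, collapse = ", "))
      next
    }
    ec50 <- tox_lv$ec50_mg_L[match(exposures$compound_id,
                                   tox_lv$compound_id)]
    stu[lv] <- sum(exposures$mec_mg_L / ec50)
  }
  if (!length(stu)) {
    stop("no trophic level has complete EC50 coverage of the mixture")
  }
  total <- max(stu) * af
  structure(list(method = "stu", rq = total,
                 grade = classify_risk(total),
                 driver = names(stu)[which.max(stu)],
                 af = af,
                 per_level = data.frame(trophic_level = names(stu),
                                        stu = unname(stu))),
            class = "rq_result")
}

#' @export
print.rq_result <- function(x, ...) {
  cat(sprintf("Risk quotient (%s method): RQ = %.4g -> %s risk",
              x$method, x$rq, sub("_", " ", x$grade)))
  if (!is.null(x$driver)) cat(sprintf("  [driver: %s]", x$driver))
  cat("\n")
  if (!is.null(x$per_compound)) {
    print(x$per_compound, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$per_level)) {
    print(x$per_level, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
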