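#' Validate a response-record table
#'
#' Response records are the tidy raw-assay format consumed by the whole
#' pipeline: one row per replicate reading, with columns
#' `id` (compound or mixture label), `concentration_mg_L` (nominal
#' concentration, mg/L, >= 0), `replicate` (index), `response` (OD680,
#' cells/mL or percent inhibition, per `response_type`) and
#' `is_control` (logical, must agree with concentration == 0).
#'
#' @param records a data frame.
#' @return the validated data frame, invisibly (with `is_control`
#'   coerced to logical).
#' @export
validate_response_records <- function(records) {
  required <- c("id", "concentration_mg_L", "replicate", "response",
                "is_control")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("response records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  conc <- records$concentration_mg_L
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentration_mg_L must be finite and >= 0")
  }
  ctrl <- as.logical(records$is_control)
  if (any(is.na(ctrl))) stop("is_control must be TRUE/FALSE")
  if (any(ctrl != (conc == 0))) {
    stop("is_control must hold exactly for concentration_mg_L == 0 rows")
  }
  for (g in unique(records$id)) {
    if (!any(ctrl[records$id == g])) {
      stop("dataset '", g, "' has no control (concentration 0) record")
    }
  }
  records$is_control <- ctrl
  invisible(records)
}

#' Derive growth-inhibition fractions from raw responses
#'
#' Normalises replicate responses against the control mean. Two
#' endpoints are supported:
#' \describe{
#'   \item{`yield`}{`inhibition(c) = 1 - mean_response(c) /
#'     mean_response(control)` - single-timepoint biomass yield, the
#'     default for 96-h OD/cell-count readings.}
#'   \item{`growth_rate`}{`inhibition(c) = 1 - mu(c) / mu(control)` with
#'     specific growth rate `mu = ln(N_end / N_0) / t`; requires strictly
#'     positive responses and a known inoculum density.}
#' }
#' The control mean maps to inhibition exactly 0 by construction.
#' Negative inhibition (responses above the control, e.g. hormesis) is
#' kept unclipped in `inhibition`; `inhibition_clipped` restricts to
#' \[0, 1\] for fitting.
#'
#' @param records a response-record data frame for a single `id`
#'   (see [validate_response_records()]).
#' @param endpoint `"yield"` (default) or `"growth_rate"`.
#' @param n0 inoculum density, cells/mL (growth-rate endpoint only).
#' @param duration_h exposure duration in hours (growth-rate endpoint
#'   only).
#' @return a data frame with columns `concentration` (mg/L, > 0),
#'   `inhibition` (fraction, unclipped) and `inhibition_clipped`
#'   (fraction in \[0, 1\]), one row per positive concentration.
#' @examples
#' rec <- data.frame(id = "x", concentration_mg_L = c(0, 0, 1, 1),
#'                   replicate = c(1, 2, 1, 2),
#'                   response = c(1000, 1000, 500, 500),
#'                   is_control = c(TRUE, TRUE, FALSE, FALSE))
#' compute_inhibition(rec)
#' @export
compute_inhibition <- function(records,
                               endpoint = c("yield", "growth_rate"),
                               n0 = 1e4, duration_h = 96) {
  endpoint <- match.arg(endpoint)
  records <- validate_response_records(records)
  if (length(unique(records$id)) != 1L) {
    stop("compute_inhibition expects records for a single id; got: ",
         paste(unique(records$id), collapse = ", "))
  }
  ctrl <- records$is_control

  if (endpoint == "yield") {
    ctrl_mean <- mean(records$response[ctrl])
    if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
      stop("control mean response must be positive")
    }
    agg <- stats::aggregate(response ~ concentration_mg_L,
                            data = records[!ctrl, ], FUN = mean)
    inh <- 1 - agg$response / ctrl_mean
  } else {
    if (any(records$response <= 0)) {
      stop("growth_rate endpoint requires strictly positive responses")
    }
    stopifnot(n0 > 0, duration_h > 0)
    mu <- function(n_end) log(n_end / n0) / duration_h
    mu_ctrl <- mean(mu(records$response[ctrl]))
    if (!is.finite(mu_ctrl) || mu_ctrl <= 0) {
      stop("control growth rate must be positive")
    }
    agg <- stats::aggregate(response ~ concentration_mg_L,
                            data = records[!ctrl, ],
                            FUN = function(r) mean(mu(r)))
    inh <- 1 - agg$response / mu_ctrl
  }

  data.frame(concentration = agg$concentration_mg_L,
             inhibition = inh,
             inhibition_clipped = pmin(pmax(inh, 0), 1))
}
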