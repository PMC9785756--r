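#' Read a response-record CSV
#'
#' Reads a tidy assay CSV (UTF-8, comma separated, header, decimal
#' point) with columns `id`, `concentration_mg_L`, `replicate`,
#' `response`, `response_type` (`od680` | `cells_per_ml` |
#' `percent_inhibition`) and `is_control`, and validates it. OD680
#' responses can be converted downstream with [od_to_cells()].
#'
#' @param path file path.
#' @return a validated response-record data frame.
#' @export
read_response_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"response_type" %in% names(records)) {
    records$response_type <- "cells_per_ml"
  }
  ok_types <- c("od680", "cells_per_ml", "percent_inhibition")
  bad <- setdiff(unique(records$response_type), ok_types)
  if (length(bad)) {
    stop("unknown response_type value(s): ", paste(bad, collapse = ", "))
  }
  validate_response_records(records)
  records
}

#' Write / read a fitted curve as a JSON record
#'
#' The JSON record carries the four curve parameters, the fit
#' diagnostics (R^2, n, convergence) and a metadata block (package
#' version, compound id). `read_curve_json()` reconstructs an
#' `"llog4"` object usable in all downstream prediction.
#'
#' @param curve an `"llog4"` object.
#' @param path output / input file path.
#' @param id compound or mixture label stored in the record.
#' @param meta optional named list merged into the metadata block.
#' @return `write_curve_json()` returns `path` invisibly;
#'   `read_curve_json()` returns an `"llog4"` object with an `id`
#'   attribute.
#' @export
write_curve_json <- function(curve, path, id = "curve", meta = list()) {
  stopifnot(inherits(curve, "llog4"))
  p <- curve$coefficients
  rec <- list(id = id,
              bottom = p[["bottom"]], top = p[["top"]],
              log_ec50 = p[["log_ec50"]], ec50 = 10^p[["log_ec50"]],
              hillslope = p[["hillslope"]],
              r_squared = curve$r.squared, n_points = curve$n,
              converged = curve$converged,
              metadata = c(list(package = "toxmix",
                                version = as.character(
                                  utils::packageVersion("toxmix"))),
                           meta))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  crv <- llog4(top = rec$top, ec50 = rec$ec50,
               hillslope = rec$hillslope)
  crv$r.squared <- rec$r_squared %||% NA_real_
  crv$n <- rec$n_points %||% 0L
  crv$converged <- rec$converged %||% NA
  attr(crv, "id") <- rec$id %||% "curve"
  crv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tidy ECx table for a fitted curve
#'
#' @param curve an `"llog4"` object.
#' @param path output CSV path.
#' @param effect_levels percent effect levels.
#' @param id label written in the `id` column.
#' @return `path`, invisibly.
#' @export
write_ecx_csv <- function(curve, path,
                          effect_levels = c(10, 30, 50, 70, 90),
                          id = "curve") {
  out <- data.frame(id = id, effect_level = effect_levels,
                    ecx_mg_L = ecx(curve, effect_levels))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a mixture design from a CSV or YAML file
#'
#' CSV files need columns `component_id` and, for custom blends,
#' `proportion`; YAML files need a `components` list and either a
#' `proportions` list or a `ratio_rule`. When no proportions are given
#' the EC50-proportional rule is assumed.
#'
#' @param path file path ending in `.csv`, `.yaml` or `.yml`.
#' @return a [mixture_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    spec_list <- yaml::read_yaml(path)
    ids <- unlist(spec_list$components)
    if (is.null(ids)) stop("design YAML must list 'components'")
    if (!is.null(spec_list$proportions)) {
      mixture_design(ids, proportions = unlist(spec_list$proportions))
    } else {
      mixture_design(ids, ratio_rule = spec_list$ratio_rule %||%
                            "ec50_proportional")
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"component_id" %in% names(df)) {
      stop("design CSV must have a component_id column")
    }
    if ("proportion" %in% names(df)) {
      mixture_design(df$component_id, proportions = df$proportion)
    } else {
      mixture_design(df$component_id)
    }
  }
}

#' Read an observed mixture ECx table
#'
#' CSV with columns `effect_level` (percent) and `ecx_mg_L`.
#'
#' @param path file path.
#' @return named numeric vector of observed ECx keyed by effect level.
#' @export
read_observed_ecx <- function(path) {
  if (!file.exists(path)) stop("observed ECx file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("effect_level", "ecx_mg_L")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("observed ECx CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  stats::setNames(df$ecx_mg_L, df$effect_level)
}
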