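#' Optical-density to cell-count calibration line
#'
#' Linear standard curve relating absorbance at 680 nm to algal cell
#' density, `cells/mL = slope * OD680 + intercept`, with predictions
#' clipped at zero. The packaged default, [od_calibration_default()],
#' carries the coefficients 2614.2 and -87.75 (R^2 = 0.992) determined
#' by haemocytometer counting for *Raphidocelis subcapitata*.
#'
#' @param slope cells/mL per OD unit; must be positive.
#' @param intercept cells/mL at zero absorbance.
#' @param r_squared coefficient of determination of the standard curve.
#' @return an object of class `"calibration_line"`.
#' @export
calibration_line <- function(slope, intercept, r_squared = NA_real_) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  if (slope <= 0) stop("calibration slope must be > 0")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared),
            class = "calibration_line")
}

#' @rdname calibration_line
#' @export
od_calibration_default <- function() {
  calibration_line(slope = 2614.2, intercept = -87.75, r_squared = 0.992)
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("OD680 calibration: cells/mL = %g * OD680 %+g (R^2 = %s)\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", format(x$r_squared))))
  invisible(x)
}

#' Convert OD680 readings to cell counts
#'
#' Applies a linear calibration line and clips negative predictions to
#' zero (a blank reading below the line's zero-crossing cannot imply a
#' negative cell density).
#'
#' @param od680 numeric vector of absorbance readings, each >= 0.
#' @param calibration a [calibration_line()]; default the packaged
#'   *R. subcapitata* line.
#' @return cell densities, cells/mL (>= 0).
#' @examples
#' od_to_cells(0.5)  # 1219.35 with the default line
#' @export
od_to_cells <- function(od680, calibration = od_calibration_default()) {
  stopifnot(inherits(calibration, "calibration_line"))
  if (any(!is.finite(od680)) || any(od680 < 0)) {
    stop("od680 readings must be finite and >= 0")
  }
  pmax(0, calibration$slope * od680 + calibration$intercept)
}

#' Fit a calibration line from paired counts and absorbances
#'
#' Ordinary least squares of cell density on OD680, returned as a
#' [calibration_line()].
#'
#' @param od680 absorbance readings.
#' @param cells haemocytometer cell densities, cells/mL.
#' @return a `"calibration_line"`.
#' @export
fit_calibration <- function(od680, cells) {
  stopifnot(length(od680) == length(cells), length(od680) >= 3L)
  fit <- stats::lm(cells ~ od680)
  calibration_line(slope = unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]),
                   r_squared = summary(fit)$r.squared)
}
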