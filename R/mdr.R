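#' Model deviation ratio
#'
#' The model deviation ratio (MDR) scores a mixture-toxicity prediction
#' as the ratio of the experimentally observed effective concentration
#' to the model-predicted one at the same effect level:
#' `MDR = observed ECx / predicted ECx`. An MDR of 1 is a perfect fit;
#' MDR < 1 means the model under-estimated the effective concentration
#' (over-predicted toxicity is the converse reading); MDR > 1 the
#' opposite. Predictions with MDR between 0.5 and 2 are conventionally
#' deemed reliable.
#'
#' @param observed_ecx experimentally determined ECx, mg/L (> 0).
#' @param predicted_ecx model-predicted ECx, mg/L (> 0).
#' @param effect_level optional percent effect level, carried through
#'   for reporting.
#' @param model optional model label (`"CA"`, `"IA"`, ...).
#' @param tie_tol half-width of the band around 1 counted as
#'   `perfect_fit`; ratios are floating point, so exact equality is not
#'   meaningful.
#' @return an object of class `"mdr_result"`: a one-row data frame with
#'   columns `model`, `effect_level`, `observed_ecx`, `predicted_ecx`,
#'   `mdr`, `classification` (`perfect_fit` / `underestimation` /
#'   `overestimation`) and `reliable` (`0.5 <= mdr <= 2`).
#' @examples
#' mdr(2.146, 1.864)   # 1.151, overestimation, reliable
#' mdr(2.146, 3.253)   # 0.6597, underestimation, reliable
#' @export
mdr <- function(observed_ecx, predicted_ecx, effect_level = NA_real_,
                model = NA_character_, tie_tol = 1e-9) {
  if (!is.finite(observed_ecx) || observed_ecx <= 0 ||
      !is.finite(predicted_ecx) || predicted_ecx <= 0) {
    stop("observed and predicted ECx must both be finite and > 0")
  }
  ratio <- observed_ecx / predicted_ecx
  classification <- if (abs(ratio - 1) < tie_tol) "perfect_fit"
                    else if (ratio < 1) "underestimation"
                    else "overestimation"
  out <- data.frame(model = model, effect_level = effect_level,
                    observed_ecx = observed_ecx,
                    predicted_ecx = predicted_ecx,
                    mdr = ratio, classification = classification,
                    reliable = ratio >= 0.5 & ratio <= 2)
  class(out) <- c("mdr_result", "data.frame")
  out
}

#' MDR table over effect levels and models
#'
#' Computes one [mdr()] row per (model, effect level) pair from an
#' observed ECx profile and per-model predicted profiles, along with the
#' table-wide minimum and maximum ratio.
#'
#' @param observed named numeric vector of observed ECx values, names
#'   the percent effect levels (e.g. `c("10" = 1.283, "50" = 2.146)`).
#' @param predictions named list of such vectors, one per model; every
#'   model must cover all the observed effect levels.
#' @param ... passed to [mdr()].
#' @return an object of class `"mdr_table"`: a data frame of
#'   `mdr_result` rows with attributes `mdr_min` and `mdr_max`.
#' @export
mdr_table <- function(observed, predictions, ...) {
  stopifnot(is.numeric(observed), !is.null(names(observed)),
            is.list(predictions), !is.null(names(predictions)))
  levels_obs <- names(observed)
  rows <- lapply(names(predictions), function(m) {
    pred <- predictions[[m]]
    missing_lv <- setdiff(levels_obs, names(pred))
    if (length(missing_lv)) {
      stop("model '", m, "' is missing predictions at effect level(s): ",
           paste(missing_lv, collapse = ", "))
    }
    do.call(rbind, lapply(levels_obs, function(lv) {
      mdr(observed[[lv]], pred[[lv]], effect_level = as.numeric(lv),
          model = m, ...)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mdr_min") <- min(out$mdr)
  attr(out, "mdr_max") <- max(out$mdr)
  class(out) <- c("mdr_table", "data.frame")
  out
}

#' @export
print.mdr_table <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df$mdr <- signif(df$mdr, digits)
  print(df, row.names = FALSE)
  cat(sprintf("MDR range: %.4g - %.4g\n",
              attr(x, "mdr_min"), attr(x, "mdr_max")))
  invisible(x)
}
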