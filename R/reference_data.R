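#' Reference 96-h EC50s of the three study antibiotics
#'
#' Acute 96-h EC50 values for sulfamethoxazole (SMX), sulfamethazine
#' (SMZ) and erythromycin (ERY) against the green alga *Raphidocelis
#' subcapitata*, determined by constrained four-parameter log-logistic
#' fits to growth-inhibition assays. Useful as realistic defaults for
#' examples, simulations and risk calculations.
#'
#' @return data frame with columns `compound_id`, `ec50_mg_L`,
#'   `r_squared`, `duration_h`.
#' @export
study_ec50 <- function() {
  data.frame(compound_id = c("SMX", "SMZ", "ERY"),
             ec50_mg_L = c(0.6120, 3.235, 0.056),
             r_squared = c(0.9856, 0.9992, 0.9757),
             duration_h = 96,
             stringsAsFactors = FALSE)
}

#' Literature EC50s of SMX, SMZ and ERY against green algae
#'
#' Published acute EC50 values for the three antibiotics against
#' *R. subcapitata* and *Chlorella vulgaris*, for comparison with the
#' study values in [study_ec50()].
#'
#' @return data frame with columns `compound_id`, `species`,
#'   `ec50_mg_L`, `duration_h`, `source`.
#' @export
literature_ec50 <- function() {
  data.frame(
    compound_id = c("SMX", "SMX", "SMX", "SMX",
                    "SMZ", "SMZ", "SMZ", "SMZ",
                    "ERY", "ERY", "ERY", "ERY", "ERY"),
    species = c("R. subcapitata", "R. subcapitata", "C. vulgaris",
                "R. subcapitata",
                "R. subcapitata", "R. subcapitata", "C. vulgaris",
                "R. subcapitata",
                "R. subcapitata", "R. subcapitata", "R. subcapitata",
                "C. vulgaris", "R. subcapitata"),
    ec50_mg_L = c(4.74, 0.52, 1.51, 0.612,
                  7.8, 8.7, 31.35, 3.235,
                  0.0246, 0.038, 0.044, 0.36, 0.056),
    duration_h = c(96, 72, 72, 96, 72, 72, 96, 96, 96, 72, 96, 96, 96),
    source = c(rep("literature", 3), "this_study",
               rep("literature", 3), "this_study",
               rep("literature", 4), "this_study"),
    stringsAsFactors = FALSE)
}

#' Reference binary-mixture ECx table (observed and model-predicted)
#'
#' Observed ("experimental data", ED) and CA/IA-model-predicted
#' effective concentrations (mg/L) of the SMX+SMZ and SMX+ERY binary
#' mixtures against *R. subcapitata* at the 10/30/50/70/90% growth
#' inhibition levels. This is the worked dataset on which the model
#' deviation ratios of the study system are computed; feed it to
#' [mdr_table()] to reproduce them.
#'
#' @return data frame with columns `mixture`, `effect_level`,
#'   `observed_ecx`, `ca_ecx`, `ia_ecx` (all ECx in mg/L).
#' @examples
#' ref <- reference_mixture_ecx()
#' smx_smz <- ref[ref$mixture == "SMX+SMZ", ]
#' mdr(smx_smz$observed_ecx[3], smx_smz$ca_ecx[3])
#' @export
reference_mixture_ecx <- function() {
  data.frame(
    mixture = rep(c("SMX+SMZ", "SMX+ERY"), each = 5),
    effect_level = rep(c(10, 30, 50, 70, 90), 2),
    observed_ecx = c(1.283, 1.760, 2.146, 2.617, 3.589,
                     0.2534, 0.2907, 0.3716, 0.4308, 0.5451),
    ca_ecx = c(1.185, 1.572, 1.864, 2.226, 2.932,
               0.1561, 0.2807, 0.4077, 0.4921, 0.669),
    ia_ecx = c(1.711, 2.539, 3.253, 4.168, 6.186,
               0.3260, 0.3206, 0.4267, 0.4734, 0.5585),
    stringsAsFactors = FALSE)
}

#' MDR table for the reference binary mixtures
#'
#' Runs [mdr_table()] on [reference_mixture_ecx()] for one or both
#' mixtures, reproducing the study system's CA and IA model deviation
#' ratios.
#'
#' @param mixtures subset of `c("SMX+SMZ", "SMX+ERY")`.
#' @return an `"mdr_table"` with a `mixture` column prepended.
#' @export
reference_mdr_table <- function(mixtures = c("SMX+SMZ", "SMX+ERY")) {
  ref <- reference_mixture_ecx()
  mixtures <- match.arg(mixtures, several.ok = TRUE)
  tabs <- lapply(mixtures, function(m) {
    sub <- ref[ref$mixture == m, ]
    obs <- stats::setNames(sub$observed_ecx, sub$effect_level)
    tab <- mdr_table(obs, list(
      CA = stats::setNames(sub$ca_ecx, sub$effect_level),
      IA = stats::setNames(sub$ia_ecx, sub$effect_level)))
    cbind(mixture = m, as.data.frame(tab))
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "mdr_min") <- min(out$mdr)
  attr(out, "mdr_max") <- max(out$mdr)
  class(out) <- c("mdr_table", "data.frame")
  out
}
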