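#' Generating truth for synthetic assay datasets
#'
#' Bundles everything needed to generate concentration-response data
#' with a known answer: the true curves, the joint-action model for
#' mixtures, the noise model, the replicate count and the seed. The
#' defaults emulate the standard 96-h algal growth-inhibition design:
#' 3 replicates, 6-7 concentrations spanning the 0-100% effect range,
#' additive Gaussian noise of 3% effect on each reading, and a control
#' culture density of 5e5 cells/mL grown from a 1e4 cells/mL inoculum.
#'
#' @param curves named list of per-compound parameter lists, each with
#'   elements `top` (percent), `ec50` (mg/L) and `hillslope`.
#' @param mixture_model `"none"`, `"CA"` or `"IA"`; the joint behaviour
#'   obeyed by mixture data generated from this truth.
#' @param design a [mixture_design()] over the curve names (required
#'   when `mixture_model` is not `"none"`).
#' @param additive_sd standard deviation of Gaussian noise added on the
#'   percent-effect scale (>= 0).
#' @param multiplicative_cv coefficient of variation of optional
#'   lognormal noise applied to the raw responses (>= 0; 0 disables).
#' @param replicates replicate cultures per concentration (>= 1).
#' @param control_response mean untreated-control response, cells/mL.
#' @param seed integer seed; identical truth + seed reproduces the
#'   dataset exactly.
#' @return an object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(curves, mixture_model = c("none", "CA", "IA"),
                            design = NULL, additive_sd = 3,
                            multiplicative_cv = 0, replicates = 3,
                            control_response = 5e5, seed = 1) {
  mixture_model <- match.arg(mixture_model)
  stopifnot(is.list(curves), length(curves) >= 1L, !is.null(names(curves)),
            additive_sd >= 0, multiplicative_cv >= 0, replicates >= 1,
            control_response > 0)
  for (id in names(curves)) {
    crv <- curves[[id]]
    if (!all(c("top", "ec50", "hillslope") %in% names(crv))) {
      stop("curve '", id, "' must define top, ec50 and hillslope")
    }
  }
  if (mixture_model != "none" && !inherits(design, "mixture_design")) {
    stop("a mixture_design is required when mixture_model is '",
         mixture_model, "'")
  }
  structure(list(curves = curves, mixture_model = mixture_model,
                 design = design, additive_sd = additive_sd,
                 multiplicative_cv = multiplicative_cv,
                 replicates = as.integer(replicates),
                 control_response = control_response,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

truth_curve_objects <- function(truth) {
  lapply(truth$curves, function(crv) {
    llog4(top = crv$top, ec50 = crv$ec50, hillslope = crv$hillslope)
  })
}

# run expr with a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# shared record generator: true percent effect from effect_fun(conc>0)
gen_records <- function(id, concentrations, effect_fun, truth) {
  if (!length(concentrations)) stop("concentration list must be non-empty")
  if (!any(concentrations == 0)) {
    stop("the concentration series must include 0 (the control)")
  }
  conc <- rep(sort(unique(concentrations)), each = truth$replicates)
  true_eff <- ifelse(conc > 0,
                     vapply(conc, function(ci) {
                       if (ci > 0) effect_fun(ci) else 0
                     }, numeric(1)), 0)
  n <- length(conc)
  eff_obs <- true_eff + stats::rnorm(n, 0, truth$additive_sd)
  response <- truth$control_response * (1 - eff_obs / 100)
  if (truth$multiplicative_cv > 0) {
    sdlog <- sqrt(log(1 + truth$multiplicative_cv^2))
    response <- response * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  response <- pmax(response, 0)
  data.frame(id = id,
             concentration_mg_L = conc,
             replicate = rep(seq_len(truth$replicates),
                             times = n / truth$replicates),
             response = response,
             response_type = "cells_per_ml",
             is_control = conc == 0,
             stringsAsFactors = FALSE)
}

#' Generate single-compound assay data with known truth
#'
#' Produces tidy replicate response records (cells/mL) from the true
#' curves of a [synthetic_truth()]: the expected response at
#' concentration `c` is `control_response * (1 - E(c)/100)` with `E`
#' the true percent inhibition, perturbed by the truth's noise model.
#' The output validates under [validate_response_records()] and is
#' byte-identical across calls with the same truth and seed.
#'
#' @param truth a [synthetic_truth()].
#' @param concentrations concentration series in mg/L, including 0 (the
#'   control); defaults to seven points spanning EC5-EC95 of each
#'   compound.
#' @return a response-record data frame covering every compound in
#'   `truth$curves`.
#' @export
gen_single <- function(truth, concentrations = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  curves <- truth_curve_objects(truth)
  with_local_seed(truth$seed, {
    do.call(rbind, lapply(names(curves), function(id) {
      crv <- curves[[id]]
      concs <- if (is.null(concentrations)) {
        c(0, ecx(crv, c(5, 15, 30, 50, 70, 90, 95)))
      } else concentrations
      gen_records(id, concs, function(ci) effect_at(crv, ci), truth)
    }))
  })
}

#' Effect of a concentration-addition mixture at a total concentration
#'
#' The CA model defines the mixture through its ECx profile; the
#' forward curve is obtained by inverting that profile, solving
#' `ca_ecx(x) = c` for the effect level `x` by bisection. Used both for
#' plotting predicted CA curves and as the generating truth of
#' CA-behaved synthetic mixtures.
#'
#' @inheritParams ca_ecx
#' @param total_concentration total mixture concentration(s), mg/L
#'   (> 0).
#' @return fractional mixture effect(s) in (0, 1).
#' @export
ca_effect <- function(curves, design, total_concentration) {
  if (any(!is.finite(total_concentration)) ||
      any(total_concentration <= 0)) {
    stop("total_concentration must be finite and > 0")
  }
  vapply(total_concentration, function(ct) {
    lo <- 1e-9
    hi <- 100 - 1e-9
    if (ca_ecx(curves, design, lo) >= ct) return(0)
    if (ca_ecx(curves, design, hi) <= ct) return(1)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (ca_ecx(curves, design, mid) < ct) lo <- mid else hi <- mid
    }
    (lo + hi) / 200
  }, numeric(1))
}

#' Generate binary-mixture assay data with known joint behaviour
#'
#' As [gen_single()], but the true effect at total concentration `c` is
#' the prediction of the truth's declared `mixture_model` (CA via
#' [ca_effect()], IA via [ia_effect()]) from the true component curves
#' and design.
#'
#' @param truth a [synthetic_truth()] with `mixture_model` `"CA"` or
#'   `"IA"` and a valid design.
#' @param total_concentrations total mixture concentration series,
#'   mg/L, including 0 (the control).
#' @return a response-record data frame with a single mixture id of the
#'   form `"A+B"`.
#' @export
gen_mixture <- function(truth, total_concentrations = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (truth$mixture_model == "none") {
    stop("truth declares no mixture model; use gen_single()")
  }
  curves <- truth_curve_objects(truth)
  design <- truth$design
  eff_fun <- if (truth$mixture_model == "CA") {
    function(ci) 100 * ca_effect(curves, design, ci)
  } else {
    function(ci) 100 * ia_effect(curves, design, ci)
  }
  mix_id <- paste(design$component_ids, collapse = "+")
  with_local_seed(truth$seed + 1L, {
    concs <- if (is.null(total_concentrations)) {
      ec <- if (truth$mixture_model == "CA") {
        ca_ecx(curves, design, c(5, 15, 30, 50, 70, 90, 95))
      } else {
        ia_ecx(curves, design, c(5, 15, 30, 50, 70, 90, 95))
      }
      c(0, ec)
    } else total_concentrations
    gen_records(mix_id, concs, eff_fun, truth)
  })
}

#' Generate a matched exposure / toxicity fixture for risk assessment
#'
#' Builds a small plausible pair of tables exercising every method and
#' every risk grade: four compounds whose MEC/PNEC quotients fall in
#' the insignificant, low, medium and high bands, with EC50s on all
#' three trophic levels (algae always the most sensitive, so it drives
#' the toxic-unit maximum). Deterministic per seed.
#'
#' @param seed integer seed.
#' @return a list with elements `exposures` (compound_id, environment,
#'   mec, mec_unit) and `toxicity` (compound_id, trophic_level,
#'   ec50_mg_L, source).
#' @export
gen_risk_fixture <- function(seed = 1) {
  with_local_seed(seed, {
    ids <- c("cmpA", "cmpB", "cmpC", "cmpD")
    ec50_algae <- stats::runif(4, 0.5, 5)           # mg/L
    ec50_daphnia <- ec50_algae * stats::runif(4, 5, 50)
    ec50_fish <- ec50_algae * stats::runif(4, 20, 200)
    target_rq <- c(0.005, 0.05, 0.5, 5) * stats::runif(4, 0.85, 1.15)
    mec_mg_L <- target_rq * ec50_algae / 1000       # AF 1000
    exposures <- data.frame(compound_id = ids,
                            environment = "surface_water",
                            mec = mec_mg_L * 1000,  # report in ug/L
                            mec_unit = "ug/L",
                            stringsAsFactors = FALSE)
    toxicity <- data.frame(
      compound_id = rep(ids, 3),
      trophic_level = rep(c("algae", "daphnia", "fish"), each = 4),
      ec50_mg_L = c(ec50_algae, ec50_daphnia, ec50_fish),
      source = "experimental",
      stringsAsFactors = FALSE)
    list(exposures = exposures, toxicity = toxicity)
  })
}

#' Regenerate a cell-count vs OD680 calibration fixture
#'
#' Simulates a haemocytometer standard-curve experiment: absorbances on
#' a grid with cell densities from the packaged calibration line plus
#' Gaussian counting error, suitable for checking that [fit_calibration()]
#' recovers the line's coefficients with R^2 >= 0.99.
#'
#' @param seed integer seed.
#' @param n number of standards.
#' @param count_sd counting-error standard deviation, cells/mL.
#' @return data frame with columns `od680`, `cells`.
#' @export
gen_calibration_fixture <- function(seed = 1, n = 10, count_sd = 30) {
  cal <- od_calibration_default()
  with_local_seed(seed, {
    od <- seq(0.05, 0.9, length.out = n)
    cells <- cal$slope * od + cal$intercept + stats::rnorm(n, 0, count_sd)
    data.frame(od680 = od, cells = pmax(cells, 0))
  })
}
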