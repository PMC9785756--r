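---
title: "Methods: concentration-response curves, mixture models and risk quotients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentration-response curves, mixture models and risk quotients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmix)
```

This vignette documents the models implemented in `toxmix`, the
assumptions behind them, the numerical choices made where the methods
literature leaves latitude, and what the synthetic-data experiments in
the test suite do and do not demonstrate about real assay data.

## The assay and its endpoint

The unit of raw data is the 96-h algal growth-inhibition test: replicate
cultures exposed to a nominal concentration series (including untreated
controls), read out as OD680 absorbance or haemocytometer cell counts.
`od_to_cells()` applies a linear standard curve (packaged default:
2614.2 cells/mL per OD unit, intercept −87.75, R² = 0.992) with
predictions clipped at zero, since a blank below the line's
zero-crossing cannot mean negative biomass.

`compute_inhibition()` supports two endpoints:

* **yield** (default): `1 − mean response / control mean` at the final
  timepoint. This is the natural endpoint for single-timepoint OD/count
  data and is what the package's reference system used.
* **growth rate**: `1 − µ/µ_control` with `µ = ln(N_end/N_0)/t`,
  requiring the inoculum density (default 1 × 10⁴ cells/mL) and
  duration (default 96 h). OECD-style rate endpoints are less sensitive
  to the exposure duration but need the extra inputs, so yield is the
  default rather than a guess at unavailable time-series data.

Responses above the control mean (mild hormesis or simple noise) give
negative inhibition. These are preserved unclipped in the `inhibition`
column and clipped to [0, 1] in `inhibition_clipped`; only the clipped
values enter curve fitting, because the constrained model below cannot
represent negative effects. A dedicated hormesis model (Brain–Cousens)
is out of scope.

## The constrained four-parameter log-logistic curve

`fit_llog4()` fits

$$Y = Bottom + \frac{Top - Bottom}{1 + 10^{(\log EC_{50} - X)\,h}},
  \qquad X = \log_{10} c,$$

with `Bottom` fixed at 0 — the standard constraint for
control-normalised inhibition, which by construction is zero at zero
dose. Three parameters are estimated: `Top` (percent effect, bounded to
(0, 120] so that modest overshoot above 100% can be represented without
letting the asymptote run away), `logEC50`, and the hill slope `h > 0`.
A `fixed_100` top policy is available for data already expressed as
percent of a full effect; the default leaves `Top` free, which mirrors
the common "variable slope" practice for algal data whose maximal
inhibition may genuinely fall short of 100% over the tested range.

Numerical choices:

* **Optimiser**: Levenberg-Marquardt least squares with box constraints
  (`minpack.lm::nls.lm`), tolerances 1e−12 on cost and parameters,
  up to 1024 iterations.
* **Starting values**: `Top` = maximum observed effect, `logEC50` =
  median log10 concentration, `h` = 1, plus five *deterministic*
  jittered restarts; the best converged solution by residual sum of
  squares wins. No random numbers are used, so identical input always
  returns identical estimates.
* **Controls** never enter the fit: `log10(0)` is undefined, so
  zero-concentration records serve only to normalise. At least four
  distinct positive concentrations and two distinct response values are
  required; degenerate inputs are rejected with an explanatory error
  rather than a silent flat fit.
* **R²** is reported as `1 − SS_res/SS_tot` about the mean response —
  the convention nonlinear-regression GUIs print, kept for
  comparability even though R² lacks its linear-model interpretation
  here.

`ecx()` inverts the curve in closed form,
$\log EC_x = \log EC_{50} + h^{-1} \log_{10}\!\big(x/(100-x)\big)$,
where `x` is a percent of the bottom–top *span*. So `ecx(fit, 50)`
equals `10^logEC50` exactly whatever `Top` is, and the round trip
`effect_at(fit, ecx(fit, x))` reproduces `x·Top/100` to 1e−9 (verified
property-style in the tests).

## Mixture models

A `mixture_design()` fixes component identities and proportions
`P_i` of the **total** mixture concentration. The default
`ec50_proportional` rule blends the components in the ratio of their
EC50s — the equitoxic design standard for binary studies — resolved
against the component curves at prediction time; `fixed_equal` (1:1)
and explicit `custom` proportions are also supported because published
mixture ratios are often not recoverable exactly.

**Concentration addition** (Loewe additivity; shared mode of action)
treats components as dilutions of one another:

$$EC_{x,\text{mix}} = \Big( \sum_i \frac{P_i}{EC_{x,i}} \Big)^{-1}.$$

It satisfies the sham-combination identity (a compound "mixed" with
itself returns the single-compound curve exactly) and is homogeneous of
degree one in a joint rescaling of the component EC50s. With equal hill
slopes and EC50-proportional blending the algebra collapses to
$EC_{x,\text{mix}} = k(x)\,\overline{EC_{50}}$ with `k(50) = 1`, so the
CA EC50 is the arithmetic mean of the component EC50s — a useful
closed-form check.

**Independent action** (Bliss independence; dissimilar modes of action)
multiplies non-effects at the components' partial concentrations:

$$E_\text{mix}(c) = 1 - \prod_i \big(1 - E_i(P_i c)\big).$$

All IA algebra runs on effect *fractions* in [0, 1]; percent appears
only at IO boundaries, since the product form is meaningless on the
percent scale. The printed-equation form that equates a concentration
to a product of effects is dimensionally inconsistent and is not
implemented. The IA ECx has no closed form; `ia_ecx()` bisects the
forward curve on the log-concentration scale to 1e−10 relative
tolerance. The attainable ceiling is
$1 - \prod_i (1 - Top_i/100)$; requesting an effect above it errors
with the ceiling stated, rather than returning a spurious root.

### Which model predicts more toxicity?

CA is conventionally described as the conservative (worst-case) model.
That ordering is slope-dependent, not universal: for two identical
components at equal proportions the closed forms give CA ≤ IA at effect
level `x` exactly when

$$h \;\ge\; \log_2 \frac{x/(100-x)}{e/(1-e)},
  \qquad e = 1 - \sqrt{1 - x/100},$$

so at `h = 1` IA predicts the *lower* ECx (higher toxicity) at every
common effect level, and the reversal at `x = 90` persists up to
`h ≈ 2.06`. The test suite verifies the ordering against this boundary
rather than asserting a blanket inequality. For the steep curves
typical of the reference antibiotics (h ≈ 2) CA is conservative at the
EC50, matching the usual narrative.

### Model deviation ratios

`mdr()` scores a prediction as `observed ECx / predicted ECx`:
1 = perfect fit (within a 1e−9 floating-point tie band), < 1
underestimation, > 1 overestimation, with the 0.5–2 interval flagged
reliable. `mdr_table()` applies this over an effect-level grid and
reports the table-wide extremes. The packaged
`reference_mixture_ecx()` table carries the observed and
model-predicted ECx profiles of the SMX+SMZ and SMX+ERY reference
mixtures; the CA/IA columns are taken as given because the exact
mixture proportions behind them are not recoverable from the published
single-compound EC50s (the EC50-proportional closed form gives
1.92 mg/L for SMX+SMZ where the table prints 1.864).

## Risk quotients

* `rq_mec_pnec()`: per compound `RQ_i = MEC_i / (EC50_i / AF)` using
  the algal EC50 and AF = 1000 (the factor appropriate when only acute
  data are available; overridable); the mixture RQ is the component
  sum, hence additive, permutation-invariant and at least the largest
  component quotient. MECs should be the highest detected
  concentrations; units ng/L, µg/L, mg/L are normalised internally.
* `rq_stu()`: toxic units `STU_level = Σ MEC_i/EC50_{i,level}` per
  trophic level (algae, daphnia, fish), `RQ = max STU × AF`. A trophic
  level with incomplete EC50 coverage is *skipped with a warning* —
  summing a subset would silently understate the level. With
  algae-only data and the same AF this reduces exactly to the MEC/PNEC
  method, which the tests assert. QSAR-predicted EC50s participate by
  supplying toxicity records with `source = "qsar"`; no QSAR estimation
  is implemented.
* `classify_risk()` grades at 0.01/0.1/1 with boundary values in the
  upper band. `classify_toxicity()` applies the 93/67/EEC bands
  (< 1 very toxic, 1–10 toxic, 10–100 harmful); the directive does not
  state boundary semantics, so the closed-left convention is used
  (10 mg/L is "harmful") and EC50s above 100 mg/L are reported as
  `unclassified_low_concern` rather than forced into a band.

## The synthetic-data generator

`synthetic_truth()` + `gen_single()`/`gen_mixture()` emulate the
reference assay design: 3 replicates, 6–7 concentrations spanning the
0–100% effect range (the default series places points at EC5–EC95 of
the generating curve), a control culture density of 5 × 10⁵ cells/mL,
and additive Gaussian noise with sd 3% effect per reading — a level at
which fitted R² values typically land in the ≥ 0.97 range reported for
real assays of this kind. Optional multiplicative lognormal noise on
the raw responses is available; both mechanisms are standard
descriptions of algal count error. Each dataset draws from one seeded
generator and restores the caller's RNG state, so identical truth and
seed give byte-identical data.

Mixture data are generated so that the *true* effect at total
concentration `c` is the declared model's prediction: IA directly via
the forward formula, CA by inverting its ECx profile with `ca_effect()`
(bisection on the effect level). What the generator does **not**
emulate: nominal-vs-measured concentration drift, photodegradation,
solvent effects, between-day batch variation, or count censoring —
passing the recovery tests therefore demonstrates correctness of the
estimation chain under a clean error model, not robustness to every
field artefact of real assays.

## Self-consistency experiments and problem sizes

The deeper test-suite experiments, with the sizes chosen for them:

* **Noiseless recovery**: fits on exact 4PL points recover (Top, EC50,
  h) to 1e−6 relative over a grid of EC50 ∈ [1e−3, 10], h ∈ [0.5, 4],
  Top ∈ {80, 100}.
* **Noisy recovery**: at the default design (sd 3%, 3 replicates, 7
  concentrations, free Top) the EC50 of an SMX-like truth is recovered
  within 10% in ≥ 95 of seeds 1–100. Note the result is sensitive to
  the concentration design: a series reaching only ~80% effect roughly
  halves the number of seeds within tolerance, which is why the
  generator's default series spans EC5–EC95.
* **Grid-search cross-check**: the continuous optimiser is compared
  against an independent brute-force SSE grid search on noisy data and
  must match within the grid resolution (and never have a larger
  residual sum of squares).
* **IA inversion oracle**: `ia_ecx()` agrees with an independent
  recursive grid scan of the forward curve to 1e−6 relative on 100
  random curve pairs.
* **Pipeline self-consistency**: data simulated under CA (resp. IA)
  truth for an SMX+SMZ-like pair (EC50s 0.612 / 3.235 mg/L, hills
  2 / 1.5, EC50-proportional design, sd 3%), fitted and scored against
  the same model's prediction, give a mean MDR across effect levels
  10–90 and 8 seeds inside [0.9, 1.1]. For this experiment the observed
  mixture curve is fitted with `top_policy = "fixed_100"`: the
  generated inhibition data are normalised fractions whose true
  asymptote is exactly 100%, and a free Top on an IA-truth curve (which
  is not exactly log-logistic) drifts upward and inflates the fitted
  EC90, turning model misspecification into an apparent MDR bias. With
  the asymptote pinned, the noiseless means are 1.004 (CA) and 1.033
  (IA) — the residual IA offset is the irreducible misspecification of
  summarising an IA curve by a log-logistic fit, and is worth
  remembering when interpreting tail-level MDRs from real data too.

## Known limitations

* Single-timepoint yield endpoint by default; no time-series growth
  modelling.
* No hormesis-capable curve; negative inhibition is preserved in the
  data but clipped for fitting.
* No interaction models (combination index, isobole deviation
  surfaces) — CA and IA are reference models, not fitted interaction
  hypotheses.
* Risk quotients are deterministic ratios; no probabilistic species
  sensitivity distributions, dilution modelling, or chronic
  extrapolation beyond the assessment factor.
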