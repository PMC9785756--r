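# toxmix

Concentration-response analysis, binary-mixture toxicity prediction and
environmental risk assessment for algal growth-inhibition assays.

Antibiotics reach surface waters at ng/L-µg/L levels and rarely occur
alone, yet regulatory toxicity testing is mostly single-compound. This
package implements the standard desk analysis used to bridge that gap
for the 96-h growth-inhibition assay with green algae (e.g.
*Raphidocelis subcapitata* exposed to sulfamethoxazole, sulfamethazine
and erythromycin, the worked system shipped as reference data):

1. **Single-compound curves.** OD680 readings are converted to cell
   densities through a linear standard curve
   (`cells/mL = 2614.2·OD680 − 87.75`, clipped at 0), normalised
   against controls into inhibition fractions, and fitted with the
   log(inhibitor) vs. response, variable-slope model with the basal
   response pinned at zero:

   `Y = Top / (1 + 10^((logEC50 − X)·Hillslope))`, `X = log10 c`.

   `ecx()` inverts the curve in closed form:
   `log ECx = logEC50 + (1/Hillslope)·log10(x/(100−x))`.

2. **Mixture prediction.** For a mixture with proportions `P_i` of the
   total concentration, concentration addition (Loewe) predicts
   `ECx_mix = (Σ P_i / ECx_i)^−1`, and independent action (Bliss)
   predicts `E_mix(c) = 1 − Π (1 − E_i(P_i·c))`, inverted numerically
   for the IA ECx. Predictions are scored with the model deviation
   ratio `MDR = observed ECx / predicted ECx` (1 = perfect fit; 0.5-2
   deemed reliable).

3. **Risk assessment.** Risk quotients by the MEC/PNEC method
   (`RQ = Σ MEC_i / (EC50_i / AF)`, AF = 1000) and by toxic-unit
   summation (`RQ_STU = max_level Σ MEC_i/EC50_i,level × AF` over
   algae, daphnia and fish), graded insignificant/low/medium/high at
   0.01/0.1/1, plus EU 93/67/EEC intrinsic-toxicity bands.

A synthetic-data generator (`synthetic_truth()`, `gen_single()`,
`gen_mixture()`, `gen_risk_fixture()`) produces assay datasets with
known truth so the whole pipeline is testable without laboratory data.

## Worked example

Simulate a sulfamethoxazole-like assay (EC50 0.612 mg/L, hill 2, 3
replicates, 3% effect noise), fit the curve, and report ECx values:

```r
library(toxmix)

truth <- synthetic_truth(
  curves = list(SMX = list(top = 100, ec50 = 0.612, hillslope = 2)),
  additive_sd = 3, replicates = 3, seed = 7)
records <- gen_single(truth)
inh <- compute_inhibition(records)          # 1 - response/control mean
fit <- fit_llog4(inhibition_clipped ~ concentration, inh,
                 scale = "fraction")
summary(fit)
#> Four-parameter log-logistic curve (Bottom fixed at 0)
#>   Top       : 99.71 %
#>   EC50      : 0.5751 mg/L  (logEC50 = -0.2402)
#>   Hillslope : 2.002
#>   R-squared : 0.996 on 7 points; converged: TRUE
#>
#> Effective concentrations:
#>  effect_level  ecx_mg_L
#>            10 0.1919726
#>            30 0.3767094
#>            50 0.5751292
#>            70 0.8780601
#>            90 1.7230245
```

The fitted EC50 (0.575 mg/L) recovers the generating 0.612 mg/L within
the noise of a single simulated assay. Predict a binary mixture blended
in the ratio of the component EC50s, and score a prediction against an
observed EC50:

```r
crvs <- list(SMX = llog4(ec50 = 0.6120, hillslope = 2),
             SMZ = llog4(ec50 = 3.235,  hillslope = 2))
des <- mixture_design(c("SMX", "SMZ"))     # EC50-proportional blend
predict_mixture(crvs, des, effect_levels = c(10, 50, 90))
#>   model effect_level predicted_ecx_mg_L
#> 1    CA           10          0.6411667
#> 2    CA           50          1.9235000
#> 3    CA           90          5.7705000
#> 4    IA           10          0.8947278
#> 5    IA           50          2.4759071
#> 6    IA           90          5.6568924

mdr(2.146, 1.864)$mdr                      # observed vs CA-predicted EC50
#> [1] 1.151288  -> "overestimation", reliable (0.5 <= MDR <= 2)
```

With equal hill slopes the CA EC50 is exactly the mean of the component
EC50s ((0.612 + 3.235)/2 = 1.92 mg/L). Finally, risk quotients on the
packaged demonstration exposure/toxicity tables:

```r
expo <- read.csv(system.file("extdata", "exposures_synthetic.csv",
                             package = "toxmix"))
tox  <- read.csv(system.file("extdata", "toxicity_synthetic.csv",
                             package = "toxmix"))
rq_stu(expo[expo$environment == "surface_water", ], tox)
#> Risk quotient (stu method): RQ = 33.66 -> high risk  [driver: algae]
#>  trophic_level       stu
#>          algae 3.366e-02
#>        daphnia 2.653e-04
#>           fish 1.452e-05
```

The algal toxic units dominate, and an RQ of 33.7 (≥ 1) grades as high
risk. A command-line front end wrapping the same pipeline lives at
`system.file("cli", "toxmix.R", package = "toxmix")` with `fit`,
`mixture`, `risk` and `simulate` subcommands.

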