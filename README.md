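# barngas

Ammonia (NH₃) and methane (CH₄) are the two gases that dominate the
environmental footprint of dairy housing: NH₃ volatilises from manure on
the barn floor, CH₄ is exhaled from enteric fermentation. In naturally
ventilated barns neither can be measured as a flux directly, because the
air-exchange rate of the building is itself unknown. `barngas` implements
the standard indirect solution — the **CO₂ mass-balance method** — together
with a multilayer-perceptron (MLP) modelling layer that predicts gas
concentrations and emission rates from climatic, behavioural and dietary
variables and ranks those input groups by an ablation study. It is aimed
at researchers in livestock environmental monitoring and precision
livestock farming who want a tested, scriptable version of this workflow.

## The method

**Emission estimation.** The herd's metabolic CO₂ production is computed
from heat-production equations (per cow, in W):

    qt   = 5.6 m^0.75 + 1.6e-5 p³ + 22 y
    CF   = 4e-5 (20 − Ti)³ + 1
    qcor = qt · CF
    P_CO2 = 0.299 · qcor            [g CO₂ cow⁻¹ h⁻¹]

with `m` the animal mass (kg), `p` days after insemination, `y` milk
yield (kg d⁻¹) and `Ti` indoor temperature (°C). Dividing the herd's CO₂
production by the indoor–outdoor CO₂ concentration difference gives the
ventilation rate, and multiplying that by the target-gas gradient gives
the emission rate, optionally per livestock unit (LU = 500 kg):

    Q  = P_CO2 · N / (C_CO2,in − C_CO2,out)     [m³ h⁻¹]
    Et = Q · (C_in − C_out)                     [g h⁻¹]
    E  = Et · 500 / (N · m)                     [g LU⁻¹ h⁻¹]

**Prediction.** A from-scratch MLP (tansig hidden units, linear output,
default 20–10 hidden structure) is trained with Levenberg–Marquardt and
validation-based early stopping on min/max-normalised features, after a
70:15:15 random partition. `run_ablation()` retrains the same model on
defined subsets of the input groups — climatic variables, animal activity
(cow lying/activity indices from 15-min scan sampling), diet, gas
concentrations — and reports R, R², MSE, RMSE, MAE and SD per subset;
models are satisfactory when R > 0.80 and R² > 0.70.

**Synthetic campaigns.** Because field campaigns of this kind are rarely
public, `gen_study()` generates a seeded synthetic month of barn data
(718 hourly records, 56 cows, diurnal Mediterranean November climate,
15-min behaviour scans, the published step-wise diet schedule) whose
concentrations satisfy the mass-balance relation by construction, with
the latent truth returned alongside. Every stage of the pipeline is
testable against that truth.

## Worked example

```r
library(barngas)

study <- gen_study(generator_config(seed = 42))   # 718 hourly records
herd  <- herd_state(n_cows = 56, mean_mass = 620,
                    days_insemination = 120, milk_yield = 28)

est <- estimate_emissions_series(study$records, herd, gas = "NH3")
head(est[c("Q", "Et", "E", "flag")], 3)
#>          Q     Et     E flag
#> 1 31206.68 35.063 0.505   ok
#> 2 33663.69 29.414 0.424   ok
#> 3 31902.12 31.101 0.448   ok
```

`Q` is the hourly ventilation rate (m³ h⁻¹) recovered from the CO₂
balance — around 33 600 m³ h⁻¹ on average here, i.e. the barn air turns
over many times per hour, as expected for an open-sided building. `Et`
is the NH₃ emission rate (g h⁻¹) and `E` the same per 500-kg livestock
unit (mean 0.50 g LU⁻¹ h⁻¹ in this simulation). Hours whose CO₂
gradient collapses are flagged `invalid_gradient` instead of failing.

```r
full <- feature_sets("NH3_concentration")[[7]]  # climatic + activity + diet
fit  <- fit_prediction_model(study$records, full, seed = 1)
fit$metrics_test
#> <metrics_report> test (n = 108): R 0.926, R2 0.857, MSE 0.01282,
#>                  RMSE 0.1132, MAE 0.0764, SD 0.1121
```

The full-input 20–10 model predicts the held-out NH₃ concentration with
R = 0.93 and R² = 0.86 (RMSE 0.11 ppm) — a satisfactory model under the
R > 0.80 / R² > 0.70 rule. The ablation table ranks input groups:

```r
run_ablation(study, "NH3_concentration", seed = 1,
             configs = c("Climatic variables", "Animal activity", "Diet"))
#>           variables structure     R     R2    MSE  RMSE    MAE    SD satisfied
#>  Climatic variables     20 10 0.922 0.8500 0.0137 0.117 0.0897 0.114      TRUE
#>     Animal activity     20 10 0.187 0.0348 0.0864 0.294 0.2210 0.292     FALSE
#>                Diet     20 10 0.221 0.0487 0.0834 0.289 0.2010 0.286     FALSE
```

Climatic variables dominate this synthetic campaign (temperature drives
NH₃ volatilisation and wind drives ventilation), so the climatic-only
model is the only satisfactory single-group model — activity and diet
alone carry little signal.

A thin command-line wrapper with `simulate`, `estimate-emissions` and
`ablate` subcommands is installed at `inst/cli/barngas.R`.

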