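# thinlayer

Thin-layer drying-kinetics analysis for slab-shaped plant material, built
around the workflow of hot-air drying studies on tomato peels: moisture
accounting, effective-diffusivity and activation-energy estimation,
empirical drying-model selection, drying-energy calculation, and
carotenoid thermal-degradation modeling.

## Who it is for

Food-process and drying-kinetics researchers who weigh a thin bed of
material at intervals while it dries at a set of air temperatures, and
need the standard chain of analyses that follows:

1. **Moisture ratio** — masses m(t) → dry-basis moisture
   M = (m − m_s)/m_s → dimensionless MR = (M − M_e)/(M_0 − M_e), with the
   equilibrium moisture M_e ≈ 0 for high-moisture material.
2. **Fick slab diffusion** — the thickness-averaged series solution
   MR = (8/π²) Σ (2j+1)⁻² exp(−(2j+1)²π²·D_eff·t/(4(L/2)²)); for Fourier
   numbers above 0.2 only the first term matters, so ln(MR) is linear in t
   with intercept ln(8/π²) and D_eff comes from the regression slope.
   A finite-difference solver of the same boundary-value problem serves as
   an independent numerical cross-check.
3. **Arrhenius activation energy** — ln(D_eff) against 1/T gives
   E_a = −slope·R and the pre-exponential factor D_0.
4. **Thin-layer model selection** — ten classical forms (Newton, Page,
   Modified Page, Henderson–Pabis and its modified form, Midilli,
   Logarithmic, Two-term, Two-term exponential, first-term Fick) fitted by
   bounded multi-start Levenberg–Marquardt and ranked by RMSE with
   reduced χ² and R² reported alongside.
5. **Specific drying energy** — E = A·w·ρ·Cp·ΔT·t/m in kWh per kg of
   sample, across a temperature/run-length schedule.
6. **Carotenoid degradation** — lycopene and β-carotene concentrations
   versus drying temperature modeled as a fitted baseline times a
   logistic or exponential retention curve, with degradation percentages
   and flagged extrapolation.

Seeded synthetic-data generators emulate the whole study design (hourly
weighings of 30 g slabs at 50–75 °C tied together by an Arrhenius law), so
every estimator is validated by parameter-recovery round trips.

## Worked example

```r
library(thinlayer)

# a noise-free synthetic drying curve generated from the two-term model
curve <- gen_drying_curve("two_term",
                          c(a = 0.3408, k1 = 0.3562, b = 0.6593, k2 = 1.3215),
                          noise_sd = 0, temperature = 65)
rk <- fit_all_models(moisture_ratio_series(curve))
head(as.data.frame(rk)[, c("rank", "model", "r_squared", "rmse")], 5)
#>   rank                    model r_squared      rmse
#> 1    1                 two_term    1.0000 1.162e-17
#> 2    2 modified_henderson_pabis    1.0000 6.298e-11
#> 3    3                   midili    0.9998 3.854e-03
#> 4    4            modified_page    0.9997 5.442e-03
#> 5    5                     page    0.9997 5.442e-03
```

The generating model wins; the six-parameter Modified Henderson–Pabis also
reaches a near-zero RMSE because the two-term form nests inside it, and
the tie resolves toward the model with fewer parameters.

```r
# activation energy from the bundled study's six diffusivities
d <- read.csv(thinlayer_example("tomato_peel_deff.csv"))
fit_arrhenius(d$temperature_C, d$d_eff_m2_per_s)
#> Arrhenius fit (6 temperatures): Ea = 16.27 kJ/mol, D0 = 4.138e-07 m^2/s, R^2 = 0.9706
```

Diffusivity rises from 1.01×10⁻⁹ to 1.53×10⁻⁹ m²/s over 50–75 °C; the
16.27 kJ/mol activation energy quantifies that temperature sensitivity.

```r
# lycopene retention against drying temperature
caro <- read_carotenoid_csv(thinlayer_example("tomato_peel_carotenoids.csv"))
fit <- fit_degradation(caro$lycopene)
fit
#> logistic retention fit for lycopene: s = 0.1152, t_mid = 66.05, c_ref = 111.6
#> R^2 = 0.9941, RMSE = 0.0162 (retention scale)
predict(fit, c(50, 75))
#>   temperature_C concentration retention extrapolated
#> 1            50         96.47    0.8641        FALSE
#> 2            75         29.35    0.2629        FALSE
```

Retention falls from 86 % of the fitted baseline at 50 °C to 26 % at
75 °C — the quantitative version of "dry cool to keep the lycopene".

`run_pipeline()` strings all stages together from a YAML config and a
drying CSV, writing per-temperature model tables, the diffusivity and
Arrhenius fits, the energy schedule, degradation fits and a run log. See
the vignette (`vignettes/thin-layer-drying.Rmd`) for the models,
assumptions and numerical choices.

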