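# berryflux

Process-based simulation of blueberry fruit growth driven by carbon and
water fluxes under abscisic acid (ABA) control.

## What it models, and for whom

Biophysical fruit-growth models of the Fishman–Génard family treat the
fruit as one large cell behind a composite membrane: dry mass grows by
sugar uptake minus respiration, water mass by xylem/phloem uptake minus
skin transpiration, and volume by turgor-driven (Lockhart) wall
yielding. These models capture the broad trend of fruit growth but have
no notion of *ripening*. `berryflux` adds the hormonal layer relevant to
non-climacteric fruit such as blueberry: endogenous ABA, accumulated as
a beta-growth function of cumulative growing degree hours (cGDH), acts
as a ripening signal that

* gates **active sugar uptake** (a beta-shaped response between two
  thresholds, on top of Michaelis–Menten transport and a logistic
  late-season inhibitor),
* adds a **ripening respiration** term to the classical growth +
  maintenance (Q10) split,
* reduces membrane **hydraulic conductivity**, and
* seals the fruit skin by lowering its **permeability**, limiting
  transpirational water loss.

The coupled state (dry mass *s*, water mass *w*, fresh = *s* + *w*) is
integrated hourly over a weather record:

    ds/dt = U_s − R_f          dw/dt = U_x + U_p − T_f

The package is aimed at plant physiologists and crop modellers who want
to explore hormone-modulated fruit growth, run climate what-if
experiments (uniform warming, shifted anthesis dates), or calibrate the
model to their own fruit time series. It ships a synthetic weather
generator so the entire system is testable without external data.
It is a simulation and analysis toolkit, not a fitted description of any
particular orchard; the packaged parameter values are documented,
plausible defaults to calibrate from.

## A worked example

```r
library(berryflux)

weather <- synthetic_season()          # 80-day season, anthesis 10 May
params  <- default_parameters()        # 39 parameters, 13 flagged calibrated
run     <- simulate_fruit(weather, params)
print(run)
#> <simulation_result> 1921 hourly rows, 0..80 DAA
#>   final: dry 221.5 mg, water 1194.3 mg, fresh 1415.8 mg
#>   ABA peak: 32.30 ug/g at 58 DAA
```

One row per hour: state (`s`, `w`, `fresh`, `cGDH`, `ABA_conc`,
`ABA_norm`), carbon fluxes (`U_a`, `U_mf`, `U_diff`, `U_s`, `R_f`),
water fluxes (`U_x`, `U_p`, `T_f`) and pressures (`P_f`, `pi_f`). The
printed summary says the fruit ends the season at 1.42 g fresh mass with
~16 % dry matter, and that the ABA signal peaked at 32.30 µg g⁻¹ dry
mass 58 days after anthesis — after which dry mass itself peaks (231 mg
at ~71 DAA) and declines as sugar uptake falls below respiration:

```r
str(peak_times(run))
#> List of 4
#>  $ t_peak_ABA: int 1409      # hours after anthesis (~58.7 DAA)
#>  $ ABA_peak  : num 32.3      # ug per g dry mass
#>  $ t_peak_dry: int 1715      # ~71.5 DAA
#>  $ dry_peak  : num 231       # mg
```

Warming scenarios and sensitivity:

```r
plus3 <- scenario_temperature_offset(weather, 3, params)   # +3 K, RH kept
sens  <- sensitivity_analysis(weather, params)             # 13 params, +10 %
subset(sens, parameter %in% c("v_m", "k_ABA", "q_r"))
```

Calibration against observations (CSV columns `daa, dry_mg, water_mg,
fresh_mg, aba_ug_per_g`) follows the two-stage protocol — ABA first,
then the full model on fresh mass with ABA frozen:

```r
obs  <- read_observations_csv("my_fruit.csv")
fit1 <- calibrate(calibration_spec("aba",  seed = 1), obs, weather, params)
fit2 <- calibrate(calibration_spec("full", seed = 1), obs, weather, fit1$params)
```

A thin command-line interface mirrors these operations
(`inst/cli/berryflux`): `simulate`, `scenario temp-offset`,
`scenario anthesis`, `fit`, `sensitivity`, `summary`, `params`.

See `vignettes/berryflux-methods.Rmd` for the model equations,
parameter provenance, numerical choices and known limitations —
including why `v_m` and `k_ABA` are only jointly identifiable from mass
data.

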