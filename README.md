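# wintercarb

Process-based modelling of winter carbohydrate dynamics and frost hardiness
in walnut branches.

## What it does

During the leafless period, walnut branches convert starch into soluble
sugars (glucose + fructose + sucrose, **GFS**) and back, driven by
temperature and dormancy stage. Because the sugar-to-water ratio controls
the freezing point of living tissue, this interconversion largely determines
**frost hardiness** (FH, the highest temperature inducing frost damage;
more negative = hardier). `wintercarb` is for tree ecophysiologists and
modellers who want to simulate these pools daily from nothing more than a
weather series, water-content observations and one initial carbohydrate
measurement, and to propagate the result into a frost-hardiness prediction.

The core model:

* **Phenology** — sequential dormancy: chilling units
  `CU(t+1) = CU(t) + max(min(T_high − θ, T_high − T_low), 0)` release
  endodormancy at `CU_crit`; forcing units
  `FU(t+1) = FU(t) + 1/(1 + exp(−slp·(θ − T50)))` then release ecodormancy at
  `FU_crit`. Stage index `PS = min(CU/CU_crit, 1) + min(FU/FU_crit, 1) ∈ [0, 2]`.
* **Kinetics** — each reaction rate (cold hydrolysis k₁c, mild hydrolysis
  k₁m, re-synthesis k₂) is
  `max[0, (a·PS + b)·exp(−(θ − μ)²/(σ·2π))]`, continuous at PS = 1 by
  construction; respiration is
  `R_max/(1 + exp(a₃(WC − b₃)))·Q₁₀^((θ−15)/10)`.
* **Daily update** — three variants: zero-order (*simple*),
  substrate-limited (*intermediate*, `H = (k₁c+k₁m)·Starch`, `S = k₂·GFS`),
  and Michaelis–Menten (*complete*); starch closes the balance so NSC
  declines by exactly the respired carbon each day.
* **Calibration** — multistart Nelder–Mead (Latin hypercube starts, smooth
  logit bound handling) minimising the pooled GFS + starch residual sum of
  squares; RMSE/RMSEP and Nash–Sutcliffe efficiency reporting.
* **Frost hardiness** — the osmo-hydric relation `FH = a·ln(GFS)/WC + b`
  (defaults a = −5.32, b = 1.71), calibrated by ordinary least squares.
* **Synthetic data** — generators for orchard weather (seasonal sinusoid +
  AR(1) noise), monthly field sampling around a known latent trajectory, and
  constant-temperature branch-storage experiments, so the whole pipeline is
  testable without any field download.

See `vignettes/wintercarb-methods.Rmd` for the full model description,
parameter meanings, and the package's numerical choices.

## Worked example

```r
library(wintercarb)

# one synthetic season of orchard weather and monthly branch sampling
weather <- generate_weather(weather_config(seed = 42))
field   <- generate_field_dataset(weather, field_config(seed = 42))
head(field$observations, 3)
#>         date      gfs   starch        wc        fh
#> 1 2008-08-31 31.85479 89.68643 0.7767860 -20.19954
#> 2 2008-09-30 32.72399 81.40460 0.8396034 -21.57618
#> 3 2008-10-30 43.57370 77.19333 0.7408008 -25.40155

# dormancy phenology over that window: budburst (PS = 2) at the end of April
range(field$pheno$date)
#> [1] "2008-08-31" "2009-04-30"

# calibrate the substrate-limited (intermediate) variant, small search
ds  <- prepare_calibration_data(weather, field$observations)
fit <- fit_carbon_model(ds, "intermediate", n_starts = 5, max_evals = 5000,
                       seed = 1)
fit
#> Carbon-metabolism model fit (intermediate variant)
#>   ss_res: 128.646 over 5 starts, 30038 evaluations
#>   GFS    RMSE  2.737  Eff  0.978
#>   Starch RMSE  2.608  Eff  0.988

# osmo-hydric frost hardiness from the fitted trajectory
fh_fit <- calibrate_fh(field$observations$fh, field$observations$gfs,
                       field$observations$wc)
c(a = fh_fit$params$a, b = fh_fit$params$b)
#>         a         b
#> -4.512575 -2.120440

traj <- simulate_carbon(weather, field$observations[, c("date", "wc")],
                        field$pheno,
                        c(gfs    = field$observations$gfs[1],
                          starch = field$observations$starch[1]),
                        fit$best_params)
idx  <- match(as.Date(field$observations$date), as.Date(traj$date))
pred <- predict_fh(traj$gfs[idx], traj$wc[idx], fh_fit$params)
round(rmse(field$observations$fh, pred), 2)
#> [1] 1.67
```

The fitted intermediate model reproduces the season (GFS RMSE
2.7 mg·g DM⁻¹, Eff 0.98). The osmo-hydric slope calibrated on nine noisy
observations (a ≈ −4.5 °C, generating value −5.32) is attenuated by the
observation noise on GFS, as errors-in-variables regression always is;
chained onto the fitted carbon trajectory it still predicts the measured
frost hardiness to about 1.7 °C.

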