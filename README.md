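# photodiurnal

Diurnal gas-exchange modelling for factorial drought × silicon
experiments in C₄ crops (developed with sugarcane trials in mind).

Agronomists screening silicon irrigation as a drought mitigant measure
leaf gas exchange — net photosynthesis *P*ₙ, stomatal conductance
*g*ₛ, transpiration *E* — every 2 h through the day, for every
combination of soil-moisture band (100–95, 80–75, 55–50, 35–30 % of
field capacity) and Si dose (0, 100, 300, 500 mg L⁻¹). This package
turns those diurnal series into comparable quantities: a fitted curve
per treatment cell, goodness-of-fit statistics, cumulative and daily
totals, percent gains against controls, and per-hour ANOVA screens.

## The model

Each response follows the empirical rate law
*dp/dt = p (ω/t + η/t²)*, whose closed-form solution is log-linear in
ln *t* and 1/*t*:

```
p(t) = exp(ω ln t − η/t + ψ),    t = clock hours since midnight
```

With ω < 0 and η > 0 the curve rises to an interior peak at
*t*\* = −η/ω (about 09:00 in the field) and declines through the
afternoon. Because ln *p* is exactly linear in (ln *t*, −1/*t*, 1),
the three constants are estimated by closed-form least squares on the
log scale; fit quality is reported on the original scale as Pearson
*r* and the residual standard error *S* = √(SSE/(n−3)). Daily totals
and the fraction of the day's response achieved by noon come from
composite Simpson quadrature of the fitted curve over the 07:00–17:00
photoperiod (the curve is singular at *t* = 0, so windows start after
midnight).

A synthetic-data module simulates the full factorial experiment —
4 bands × 4 doses × 3 responses × 5 replicates × 6 hours — from known
parameters with multiplicative lognormal noise, plus a matching
diurnal microclimate (PPFD, air temperature, RH, ambient CO₂, and
Tetens-derived VPD), so the entire pipeline runs and is tested with no
field data. See `vignette source in vignettes/` for the methods
account.

## Worked example

```r
library(photodiurnal)

cfg <- synthetic_config(seed = 1)      # the default factorial experiment
res <- run_pipeline(config = cfg)      # simulate -> fit -> integrate -> compare

subset(res$constants, water_band == "100-95" & si_dose_mg_per_L == 0 &
                      response_kind == "PN")
#>   water_band si_dose_mg_per_L response_kind  omega   eta   psi  n      r     S
#> 1     100-95                0            PN -6.082 54.84 22.87 30 0.9885 1.056

p <- with(subset(res$constants, water_band == "100-95" &
                 si_dose_mg_per_L == 0 & response_kind == "PN"),
          model_params(omega, eta, psi))
c(peak = peak_time(p), daily_total = daily_total(p),
  by_noon = fraction_achieved_by(p, 12))
#>        peak daily_total     by_noon
#>      9.0160    225.7337      0.6222
```

Reading the numbers: the well-watered, no-Si photosynthesis curve was
recovered with *r* = 0.99 and *S* ≈ 1.1 µmol m⁻² s⁻¹; its fitted peak
sits at 09:01; the photoperiod total is ≈ 226 µmol CO₂ m⁻² s⁻¹ · h,
and 62 % of it is assimilated before noon — the morning-loaded shape
typical of these curves. `res$percent_gain` holds per-hour gains of
each Si dose over the no-Si control (≈ +10 % for 300 mg L⁻¹ by
construction of the simulation), and `res$anova` the per-hour F tests
across doses:

```r
head(subset(res$anova, response_kind == "PN"), 3)
#>    water_band response_kind time_h    F       p significant
#> 13     100-95            PN      7 2.06 0.14664       FALSE
#> 14     100-95            PN      9 5.53 0.00844        TRUE
#> 15     100-95            PN     11 4.16 0.02345        TRUE
```

A command-line front end with `simulate`, `fit`, `integrate` and
`report` subcommands is installed under `exec/photodiurnal`.

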