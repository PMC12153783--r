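# bioclimzone

Bioclimatic zoning for dairy cattle from georeferenced climate data.

Heat stress is a leading constraint on tropical dairy production: when
the thermal load on a cow exceeds her capacity to dissipate heat, feed
intake and milk yield drop. `bioclimzone` turns gridded annual climate
data (mean air temperature, wind speed, precipitation) into maps and
tables that delineate where, and how severely, dairy herds are at risk —
the workflow used in regional livestock climate-vulnerability
assessments. It is aimed at agro-meteorologists and animal scientists
who need a reproducible, scriptable alternative to point-and-click GIS
workflows.

## What it computes

* **Temperature–Humidity Index (THI)** per point, from a pluggable
  formula registry. The default annual-scale parameterization is

  `THI = 6.3952 + 0.08964 · Tair + 0.01018 · Ws²`

  with `Tair` in °C and `Ws` in m·s⁻¹.
* **Decrease in milk production (DMP)**, a regression estimate of the
  daily loss per cow given her potential production `NP` (kg·day⁻¹,
  typically 10 or 25) under thermal comfort:

  `DMP = −1.075 − 1.736 · NP + 0.02474 · NP · THI`, clamped at 0.
* **Heat-stress classes**: the Livestock Weather Safety Index
  (normal ≤ 74 < alert < 79 ≤ danger < 84 ≤ emergency) and dairy-specific
  stress onsets (moderate 72, high 79, extreme 89).
* **Standardized Precipitation Index (SPI)** on annual totals, from a
  maximum-likelihood gamma fit; seven drought/wet classes from
  Extremely Dry (≤ −2) to Extremely Wet (≥ 2), per mesoregion and for
  the whole domain.
* **Geostatistical interpolation**: experimental semivariograms, WLS
  fitting of spherical / exponential / gaussian variogram models,
  ordinary kriging with standard errors, leave-one-out cross-validation
  (ME, MSE, ASE, RMSE, RMSSE), automatic model selection (RMSSE closest
  to 1), and the Cambardella degree-of-spatial-dependence diagnostic
  `100 · C0 / (C0 + C)`.
* **A synthetic climate-field generator** (Gaussian random fields by
  dense Cholesky factorization, gamma precipitation, injectable drought
  years) so the whole pipeline runs and is tested without any external
  data download.

## Worked example

```r
library(bioclimzone)

cfg <- synthetic_config(years = 2012:2015, seed = 42)
field <- generate_climate_series(cfg)           # ~300 points x 4 years
report <- run_zoning(field, thi_formula = "silva", cv_max_n = 120)
report
```

```
bioclimatic zoning report
  years: 2012, 2013, 2014, 2015 | THI formula: silva | metric: planar
  THI descriptive statistics:
 year   mean    min    max       sd     cv cv_class
 2012 8.8853 8.6537 9.1490 0.100820 1.1347      low
 2013 8.8889 8.6276 9.0829 0.102959 1.1583      low
 2014 8.8564 8.5539 9.0954 0.109217 1.2332      low
 2015 8.9000 8.6782 9.1344 0.098661 1.1085      low
  selected variogram per year:
 year    family  rmsse
 2012 spherical 1.0395
 2013 spherical 1.0007
 2014 spherical 0.8502
 2015 spherical 0.9859
```

The generator's covariance is spherical, and the cross-validated model
selection recovers that family in every year, with RMSSE ≈ 1 showing the
kriging standard errors are well calibrated. CV below 12 % classes the
interannual THI dispersion as "low".

Milk losses at the THI levels that bound the high-stress zones:

```r
milk_loss(c(25, 25, 10), c(80, 86.5, 81))
```

```
  np  thi dmp_raw     dmp
1 25 80.0 5.00500 5.00500
2 25 86.5 9.02525 9.02525
3 10 81.0 1.60440 1.60440
```

A 25 kg/day cow loses about 5 kg of milk per day at the danger-zone
boundary (THI 80) and about 9 kg/day at THI 86.5; a 10 kg/day cow loses
about 1.6 kg/day at THI 81.

Drought indexing on the default 12-year synthetic series (drought years
2012, 2015, 2016, 2023 are injected by the generator):

```r
spi_by_region(generate_climate_series(synthetic_config(seed = 42)))[["(all)"]]
```

```
   year precip    spi          class
1  2012   1073 -1.257       Very Dry
2  2013   1640  0.757 Moderately Wet
...
5  2015   1028 -1.444       Very Dry
6  2016   1008 -1.529       Very Dry
...
12 2023   1039 -1.399       Very Dry
```

Surfaces are written as plain-text georeferenced rasters (ESRI ASCII
grid, with a `*_se.asc` standard-error band) via `write_raster()`, and
reports as CSV/JSON via `write_report()`. A thin command-line wrapper
lives in `inst/scripts/zoning` (`synth`, `run`, `spi` subcommands).
Climate-projection scenarios (RCP4.5 / RCP8.5 over short/mid/long
horizons) go through the identical pathway via `scenario_spec()` and
`run_scenarios()`.

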