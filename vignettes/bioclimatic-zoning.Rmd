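---
title: "Methods: bioclimatic zoning for dairy cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioclimatic zoning for dairy cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioclimzone)
```

This vignette documents the models behind `bioclimzone`, the choices
made where the methodology is genuinely open, and what the package's
tests do and do not demonstrate.

## Thermal indices

The Temperature–Humidity Index condenses the meteorological drivers of
heat load on cattle into one number. The default registry entry
(`"silva"`) is an annual-scale form driven by mean air temperature and
wind speed,

$$\mathrm{THI} = 6.3952 + 0.08964\,T_{air} + 0.01018\,W_s^2,$$

with $T_{air}$ in °C and $W_s$ in m s$^{-1}$; the quadratic wind term is
part of the published coefficient set. THI parameterizations vary widely
across the literature (many are driven by temperature and relative
humidity and live on a 70–90 scale), and annual-mean inputs compress
the index further. The registry (`thi_register()`, `thi_formulas()`)
therefore makes the formula a first-class, recorded choice: every
`run_zoning()` report carries the `thi_formula` that produced it, and
classification thresholds (which come from the 70–90-scale tradition)
can be used with a formula on that scale. The default formula's outputs
on realistic annual means sit near 8–9, so on that default the
threshold-based classes act on the index as defined, not on a
re-scaled one — users comparing against 70–90-scale charts should
register the corresponding formula.

The decrease in milk production is the linear regression

$$\mathrm{DMP} = -1.075 - 1.736\,NP + 0.02474\,NP \cdot \mathrm{THI},$$

where $NP$ is the potential daily production under comfort (10 and 25
kg day$^{-1}$ cow$^{-1}$ are the conventional settings). A negative
regression value means "no loss", so the reported `dmp` is clamped at
zero while `dmp_raw` is preserved for diagnostics. Because the form is
linear in THI with slope $0.02474\,NP$, losses for a 25 kg cow grow
exactly 2.5 times faster with THI than for a 10 kg cow.

Classification schemes are implemented as exact partitions of the real
line: the Livestock Weather Safety Index (normal $\le 74$ < alert
$< 79 \le$ danger $< 84 \le$ emergency), dairy stress onsets treated as
inclusive lower bounds (moderate 72, high 79, extreme 89), coefficient
of variation (low $<12\%$, medium $12$–$24\%$ inclusive, high
$>24\%$), and spatial-dependence bands (strong $<25\%$, moderate
$25$–$75\%$, weak $>75\%$).

## Drought indexing (SPI)

Annual precipitation totals are modelled as gamma distributed. The MLE
solves the profile score $\log\alpha - \psi(\alpha) = \log\bar x -
\overline{\log x}$ by Newton iteration from Thom's closed-form
initializer, with tolerance $10^{-8}$; $\beta = \bar x / \alpha$.
Zero totals — rare on annual scales but possible — are handled with the
standard mixed distribution $H(x) = q_0 + (1 - q_0) F(x)$, where $q_0$
is the zero fraction and $F$ the fitted gamma CDF. The SPI is
$\Phi^{-1}(H(x))$. The printed seven-band classification leaves
micro-gaps between its band edges (e.g. between $-0.99$ and $-1.00$);
the implementation uses contiguous bands at the cut points $\pm 2$,
$\pm 1$, $\pm 0.5$, closed on the side the printed scale shows, so
every value classifies uniquely. Regional series are computed on
region-mean precipitation and then fitted per region; the whole-domain
series uses the global mean. The accumulation window is calendar-year
totals; multi-month SPI variants are out of scope.

## Geostatistics

The experimental semivariogram is the method-of-moments estimator
$\hat\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2$ over pairs binned
into `n_lags = 12` equal-width bins up to half the maximum pairwise
distance — conventional defaults, both configurable. Three model
families are fitted (spherical, exponential, gaussian; the latter two
use the practical-range convention with the factor 3 in the
exponent). The fitting criterion is least squares weighted by the pair
counts $N(h)$. Numerically, for a fixed range the model is linear in
(nugget, partial sill), so those are profiled out by constrained
weighted linear least squares and the range alone is optimized over a
grid refined by golden-section search; this makes noise-free recovery
exact to optimizer tolerance and keeps flat (pure-nugget) variograms
well defined rather than an optimizer failure mode. A fit whose partial
sill collapses to zero warns "no spatial structure".

Ordinary kriging solves the bordered semivariance system with a
Lagrange multiplier for the unbiasedness constraint $\sum\lambda_i = 1$.
Prediction is local by default (`n_neighbors = 16`, ties in neighbour
distance broken stably by sample index) for scalability; a global mode
(`n_neighbors = Inf`) factorizes the system once for all targets and is
used in the oracle tests. Two degenerate cases are handled explicitly:
a target coinciding with a sample under a zero-nugget model is returned
exactly (kriging exactness is an identity; extracting it from the
bordered system is needlessly ill-conditioned), and a zero-sill model
(a constant field) returns the neighbourhood mean with zero error.
Duplicate sample locations with no nugget give a deliberate, named
error.

Distance metric: input coordinates are lon/lat degrees, and the package
never hides the metric choice — `"planar"` (Euclidean on degrees, the
default and the units of the synthetic generator), `"equirectangular"`
(projection to metres about the mean latitude), or `"greatcircle"`
(haversine, via geosphere). Variogram ranges are expressed in the
metric chosen, and all stages (simulation, variogram, kriging) share
it. No attempt is made to reproduce any particular published range
values, whose units/CRS conventions are ambiguous at ~4 km grid
spacing.

## Validation

Leave-one-out cross-validation predicts each point from all others and
summarizes errors $e_i$ and kriging standard errors $s_i$ as ME
$=\overline{e}$, MSE $=\overline{e/s}$ (a *mean standardized error* —
the name "MSE" here follows the ArcGIS-style cross-validation output
this mirrors, not "mean squared error"), ASE $=\overline{s}$, RMSE
$=\sqrt{\overline{e^2}}$ and RMSSE $=\sqrt{\overline{(e/s)^2}}$. The
$s_i$ are the kriging standard errors of the held-out predictions.
Model selection formalizes the usual verbal rule: choose the family
with RMSSE closest to 1 (calibrated standard errors), break ties
(within $10^{-6}$) by the smaller |RMSE − ASE|, then smaller RMSE, then
the fixed order spherical, exponential, gaussian. Applied per dataset,
this rule can disagree with a global choice made across many years;
the full ranking table is attached to every selection. The degree of
spatial dependence is $100\,C_0/(C_0+C)$ with the *total* sill in the
denominator — the convention that reproduces published
nugget/sill/DSD triples — classed by the Cambardella bands. Residual
normality uses the Shapiro–Wilk test at $p < 0.05$.

## Synthetic data

The generator exists so that every downstream stage is testable without
external downloads, and its defaults are fixed to the statistical shape
of an annual tropical climate grid over a Maranhão-sized domain: base
mean temperature 27.3 °C; a north-positive latitudinal gradient of
0.35 °C per degree latitude (the observed warm-north pattern); a
spherical generating variogram (nugget 0.005, partial sill 0.35, range
2.5°) whose sill mirrors the 0.3–0.4 magnitudes seen in annual THI
variography; gamma precipitation with shape 8 and scale 202.875 mm
(mean 1623 mm, the state average; per-mesoregion magnitudes are not
published, so defaults centre on the state mean without claiming
sub-regional realism); drought years 2012, 2015, 2016 and 2023 with
precipitation multiplier 0.65 and a +0.3 °C temperature offset; wind
speed as $\exp(\text{GRF})$ rescaled into the reported 0.7–2.8 m s$^{-1}$
band, so positivity is structural.

Fields are simulated by dense Cholesky factorization of the covariance
$C(h) = (C_0 + C) - \gamma(h)$ with the total sill on the diagonal, the
nugget acting as independent white noise per location — exact, and
practical up to roughly 5000 points; a $10^{-10}$-scaled ridge is added
once if the matrix is numerically semi-definite, and a genuine
non-positive-definite configuration is an error. The factor is reused
across years and realizations, so multi-year generation costs one
factorization. All randomness flows from the single config seed and the
RNG state is restored on exit, giving bit-identical fields per config.

What the generator does *not* emulate: orography, coastlines, ENSO
teleconnections, temporally correlated drought persistence, or
measurement error structure of any real gridded product. Passing tests
on synthetic fields therefore demonstrate the *statistical* correctness
of the estimators (parameter recovery, calibration, classification),
not fidelity to any real region's climatology.

## Pipeline

`run_zoning()` processes each year independently: indices per point →
THI dispersion statistics → three variogram fits → leave-one-out
selection → kriging of THI and of each DMP level onto the output grid
(default: the input locations) → classed area fractions. The default
mode interpolates the per-point indices (index-then-krige), matching
how THI/DMP maps are usually presented; a `krige_mode = "variable"`
alternative interpolates $T_{air}$ and $W_s$ and applies the formulas
on the grid, since published workflows rarely state which order they
used. DMP surfaces are kriged with the family selected on THI but with
parameters refit to each DMP variable's own empirical variogram.
Cross-validation is capped at `cv_max_n = 400` points per year
(deterministic evenly spaced subsample) so that the family comparison
stays $O(\text{cv\_max\_n})$ small-system solves; kriging itself uses
all points. Scenario runs (`scenario_spec()`, pathways RCP4.5/RCP8.5,
horizons short/mid/long) reuse exactly the same layer computation, so
an identity scenario reproduces the historical surfaces bit for bit.
Every report records the formula, metric, lag design, neighbourhood and
selection rankings — precisely the knobs a methods section usually
leaves open.

Problem sizes in the shipped tests were chosen to exercise the
asymptotics that matter while staying desk-scale: 2000-point fields
(10 realizations per family) for variogram-recovery checks, 500 points
for the RMSSE-calibration check, 100 random small datasets for the
metric oracles, and a 15 × 7-point, multi-year grid for the pipeline
round trips.

## Known limitations

* Isotropic variograms only; no anisotropy, co-kriging or universal
  kriging (intrinsic stationarity is assumed throughout).
* The dense-Cholesky simulator and global kriging are $O(n^3)$; use the
  local neighbourhood (default) for large prediction tasks.
* SPI is annual-scale only; no 1/3/6-month accumulation variants and no
  SPEI.
* Raster output is the plain-text ESRI ASCII grid (one value band plus
  one standard-error band); no GeoTIFF/NetCDF writers, keeping the
  package free of compiled geospatial dependencies.
* The THI-threshold classes and the DMP regression are generalized
  dose-response summaries: they ignore breed, lactation stage,
  management (shade, cooling) and radiative load, so mapped classes are
  screening-level indicators, not farm-level predictions.
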