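# quakefatal

Rapid post-earthquake fatality estimation: from an earthquake source
description to an expected death toll, fatality-range probabilities and an
emergency-response level, fast enough to inform the first hours of relief
planning.

The package is aimed at hazard scientists and emergency-response analysts
working at regional scale. It implements the full chain:

1. **Ground motion** — a desk-scale 3-D velocity-stress elastic
   finite-difference solver (fourth-order Runge-Kutta in time, alternating
   one-sided MacCormack-type spatial operators, traction-image free surface,
   absorbing sponge boundaries, point and finite-fault moment-tensor
   sources, optional terrain-following vertical stretch), written in C++
   behind an R interface.
2. **Intensity** — peak ground velocity to macroseismic intensity through a
   configurable log-linear law `I = clamp(c0 + c1 log10 PGV, 1, 12)`.
3. **Exposure** — conservative nearest-neighbour overlay of the intensity
   raster with a gridded population raster, yielding persons exposed per
   intensity class V-XI.
4. **Fatalities** — a regionally stratified empirical model: log-linear
   fatality ratio `log10 r(I) = beta + theta I` (five sub-regions, each with
   its own parameters), a human-development-index correction
   `HDI_max-year / HDI_event-year` that normalises events across eras of
   building resilience, and the expectation

   ```
   E = sum_{I=V..XI} r(I) * (HDI_ref / HDI_event) * Pe(region, I)
   ```

   Parameters are fitted to a damaging-earthquake catalog by minimising
   `ln[(1/N) sum (E_i - O_i)^2] + (1/N) sum [ln(E_i/O_i)]^2` (grid search
   plus Nelder-Mead; fully deterministic). Uncertainty is carried by a
   lognormal with median `E` and log scale `zeta` (the RMS of `ln(E/O)`),
   giving probabilities for the four response tiers: level IV (<= 10
   fatalities), III (10-50], II (50-300], I (> 300).

A synthetic-data module generates catalogs with known parameters, clustered
population rasters, HDI tables and analytic radiation-pattern intensity
fields, so everything runs and is tested fully self-contained. See the
methods vignette (`vignettes/rapid-fatality-estimation.Rmd`) for the models,
numerics and design decisions in detail.

## Worked example

Fit the model to a synthetic catalog, then estimate a scenario in which a
strike-slip event strikes near a populated basin:

```r
library(quakefatal)

hdi     <- gen_hdi_table()
catalog <- gen_catalog(catalog_gen_spec(n_events = 20, zeta = 0.5, seed = 1), hdi)
model   <- fit_fatality_model(catalog, hdi)
model
#> Regionally stratified empirical fatality model
#>   events fitted: 100 in 5 region(s)
#>   coefficients (log r = beta + theta * I):
#>       beta  theta
#> a -14.3303 1.1194
#> b -13.6095 1.0163
#> c -15.6149 1.2476
#> d -15.1468 1.1921
#> e -16.4954 1.3293
#>   log residual zeta (pooled): 0.5103

spec       <- grid_spec(99.0, 25.0, 0.02, 60, 60)
intensity  <- gen_intensity_field(spec, epicenter = c(99.6, 25.6), I0 = 10.2,
                                  lobe_amplitude = 0.8, strike = 138)
population <- gen_population(spec, n_clusters = 8, total_persons = 2e6, seed = 4)
exposure   <- compute_exposure(intensity, population)
exposure
#> Population exposure by intensity class (persons)
#>       V      VI     VII    VIII      IX       X      XI
#>       0  229015 1275270  357960  100458   30148    7022
#> below V: 0 | unassessed: 0 | nodata cells: 0 | total: 1999873

E <- estimate_fatalities(exposure, region = "e", event_year = 2015, model, hdi)
level_probabilities(E, model$zeta_pooled)
#> Fatality estimate
#>   expected: 119.342 (reported: 119)
#>   response level: II
#>   range probabilities:
#>     0-10    (level IV ):   0.0%
#>     10-50   (level III):   4.4%
#>     50-300  (level II ):  92.0%
#>     >300    (level I  ):   3.5%
```

Reading the output: about 1.7 million people sit in cells shaken at class
VII or above; under region `e`'s fitted ratio curve that exposure implies an
expectation of ~119 deaths, and with the fitted log residual (0.51) the
50-300 range carries 92% of the probability, so a level II response is
recommended. The fitted `theta ~ 1.0-1.3` means each intensity class
multiplies the death ratio by roughly a factor of ten, which is why the
modest population at X-XI drives most of the toll.

`run_pipeline("config.yml")` runs the same chain from files on disk — either
from a precomputed intensity raster or all the way from a source model
through the wave simulator — writing the intensity raster, an exposure CSV,
an `estimate.json` and a plain-text report; runs are deterministic and
byte-reproducible.

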