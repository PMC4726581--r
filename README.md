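# bmesoil

Geostatistical mapping of soil respiration (soil CO₂ efflux) on small plots,
for field ecologists and biogeochemists who can afford only a handful of
flux-chamber measurements but can log soil temperature densely.

Soil CO₂ efflux is strongly heterogeneous in space, so sparse chamber
campaigns under-resolve it. Temperature, which is cheap to measure, predicts
flux through the exponential (Arrhenius-type) response

    Rs = a · exp(b · T)

`bmesoil` fits that link by nonlinear least squares and converts every node
of a dense temperature grid into a *probabilistic soft datum* for the flux:
a Student-t density with n − 2 degrees of freedom centred on the regression
prediction and scaled by the classical prediction interval

    R̂s ± t(n−2, 0.025) · S_TP · sqrt(1 + 1/n + (T − T̄)² / S_TT),

truncated below at zero. The soft data are then fused with the hard flux
measurements by **Bayesian Maximum Entropy (BME)**: a maximum-entropy prior
(multivariate Gaussian under mean + covariance knowledge, with covariance
C(h) = sill − γ(h) from a fitted variogram) is conditioned on the hard data
exactly and on each soft density by Gauss–Legendre quadrature, yielding a
full posterior density per estimation point; the posterior expectation is
the point estimate. With no soft data the posterior collapses to the
simple-kriging Gaussian conditional — kriging is the special case of BME.

Classical baselines are included: experimental auto-/cross-variograms with
Gaussian and spherical WLS model fits, ordinary kriging (Σλ = 1) and
cokriging (Σλ₁ = 1, Σλ₂ = 0), hold-out validation (RMSE, bias, Pearson CR),
and a sampling-density experiment that shrinks the design from 49 to 9
points on nested, rotation-symmetric schemes. Because no raw campaign data
are deposited anywhere, a first-class synthetic generator
(`simulate_plot()`) draws coupled temperature/flux realizations of a
35 m × 35 m plot with the published summary statistics, and all
method-comparison claims are tested against that simulated truth.

## Worked example

```r
library(bmesoil)

conf <- day2_defaults()            # the canonical synthetic study conditions
sim  <- simulate_plot(conf, seed = 1)
print(sim$hard)
#> point_samples: n = 49, value mean 5.766, sd 0.4123

mod <- fit_variogram_model(empirical_variogram(sim$hard), "gaussian")
print(mod)
#> variogram_model: gaussian, C0 = 0, C = 0.1689, sill = 0.1689, a = 10.64 m, R2 = 0.755
nugget_sill_ratio(mod)
#> $ratio            0
#> $dependence_class "strong"

fit <- fit_arrhenius(field_value_at(sim$temp, sim$hard$locations),
                     sim$hard$values)
print(fit)
#> arrhenius_fit: Rs = 0.2989 * exp(0.109 T), n = 49, CR = 0.5118
#>   S_TP = 0.358, S_TT = 5.511, T_bar = 27.15, t(df = 47, 95%) = 2.012

compare_methods(sim$hard, sim$temp, seed = 1)
#>   method  rmse    bias      cr
#> 1    BME 0.273  0.0507  0.0886
#> 2  Co-OK 0.406 -0.0995 -0.0370
#> 3     OK 0.257  0.0741  0.1831
```

Reading the output: the 49 simulated flux samples have mean ≈ 5.8 and
SD ≈ 0.41 flux units; their fitted variogram falls in the strong spatial
dependence class (nugget-to-sill < 0.25) with a ~11 m range; temperature
explains CR² ≈ 26% of the flux variance in this realization, so each soft
datum carries an uncertainty of S_TP ≈ 0.36 flux units. On a single 5-point
hold-out the estimators sit within noise of one another; systematic
differences appear over replicates — averaged across 30 simulated plots,
BME's full-grid RMSE beats ordinary kriging at every design size (see
`sampling_density_experiment()`), with the largest margin at the sparsest
(9-point) design.

A YAML-driven pipeline (`run_pipeline()`, thin CLI at `inst/cli/bmesoil`)
chains simulate → variogram → softdata → krige/cokrige/bme → validate and
writes plain-text artifacts (CSV, ESRI ASCII grids, JSON).

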