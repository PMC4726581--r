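---
title: "Mapping soil CO2 efflux by Bayesian Maximum Entropy with temperature-derived soft data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping soil CO2 efflux by Bayesian Maximum Entropy with temperature-derived soft data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmesoil)
```

## The estimation problem

Soil respiration (the CO2 efflux from soil to atmosphere) is strongly
heterogeneous in space, while flux chambers are expensive and slow: a typical
small-plot campaign measures a handful of points on a coarse grid. Soil
temperature, by contrast, can be logged densely and cheaply, and flux and
temperature are linked by a well-established exponential response. `bmesoil`
exploits that asymmetry: it converts a dense temperature grid into
*probabilistic soft data* for the flux via a regression prediction interval,
and fuses those soft data with the sparse *hard* flux measurements using
Bayesian Maximum Entropy (BME). Ordinary kriging (OK) and cokriging (Co-OK)
are implemented as the classical baselines.

The canonical configuration is a 35 m x 35 m plot with a 7 x 7 flux grid at
5 m spacing (49 hard data) and a 35 x 35 temperature grid at 1 m spacing
(1225 readings), with the flux nodes co-located with temperature nodes.

## From temperature to soft data

The flux-temperature link is the exponential (Arrhenius-type) model

$$ R_s = a\,e^{bT}, $$

fitted by nonlinear least squares (`fit_arrhenius()`), initialized from the
linear regression of $\log R_s$ on $T$. A new, unmeasured flux at temperature
$T$ is then described by the classical regression prediction interval

$$ \hat R_s \pm t_{n-2,\,0.025}\; S_{TP}
   \sqrt{1 + \tfrac1n + \tfrac{(T - \bar T)^2}{S_{TT}}}, $$

where $S_{TP}$ is the residual standard deviation and $S_{TT}$ the
temperature sum of squares. `make_soft_data()` turns every temperature node
into a soft datum: a Student-t density with $n - 2$ degrees of freedom,
centred on $\hat R_s$, scaled by the prediction-interval scale, truncated
below at zero (fluxes are non-negative) and renormalized. The full truncated
density — not just the interval — is carried into the estimation, so the 95%
interval is always recoverable from it.

The critical value is *computed* from the Student-t quantile function at
$n - 2$ degrees of freedom. A `t_crit_override` argument exists for
reproducing published arithmetic that used a different tabulated value.

## Spatial structure

Experimental variograms follow the classical estimator
$\hat\gamma(h) = \frac{1}{2N(h)}\sum [Z(x_i)-Z(x_i+h)]^2$
over half-open distance bins, and the cross-variogram replaces the squared
difference by the product of the two variables' increments
(`empirical_variogram()`, `empirical_cross_variogram()`; both are
pair-exact and tested against brute-force enumeration). Two parametric
models are supported, with the effective-range convention for the Gaussian:

* Gaussian: $\gamma(h) = C_0 + C\,(1 - e^{-3h^2/a^2})$
* Spherical: $\gamma(h) = C_0 + C\,(1.5\,h/a - 0.5\,(h/a)^3)$ for
  $h \le a$, constant at the sill beyond.

`fit_variogram_model()` minimizes pair-count-weighted squared residuals
(the GS+-style convention) by L-BFGS-B from five deterministic starting
points spanning the empirical sill and lag span, ties broken by lowest
weighted SSE then smallest range. Defaults: lag width equal to the minimum
sampling spacing, maximum lag half the largest pairwise distance, isotropy
throughout. The nugget-to-sill ratio $C_0/(C_0+C)$ classifies spatial
dependence (strong below 0.25, moderate to 0.75, weak above).

## Estimators

**Ordinary kriging** solves the semivariance-form system with one Lagrange
multiplier ($\sum\lambda_i = 1$) over the nearest `n_neighbors` data
(default 16; distance ties broken lexicographically). With $\gamma(0)=0$ on
the diagonal the predictor interpolates exactly.

**Cokriging** extends the system with a secondary variable through a linear
model of coregionalization. The default constraints are the traditional
unbiased pair $\sum\lambda_1 = 1$, $\sum\lambda_2 = 0$. A published variant
of the system instead constrains the secondary weights to sum to one; it is
available as `constraint = "unit-secondary"` but is biased unless the
secondary variable is rescaled, so it is not the default. Degenerate
systems (e.g. a secondary that duplicates the primary) fall back to the
minimum-norm pseudoinverse solution, which reproduces the OK estimate.

**BME** proceeds in the classical three stages:

1. *Prior.* Under mean and covariance constraints the maximum-entropy joint
   density is multivariate Gaussian, so `build_prior()` constructs it in
   closed form: constant mean (by default the arithmetic mean of the hard
   data — the plot is treated as second-order stationary) and covariance
   $C(h) = (C_0 + C) - \gamma(h)$. The test suite validates the closed form
   against a discretized Lagrange-multiplier solution of the entropy
   maximization in one dimension.
2. *Conditioning.* Hard data enter by exact Gaussian conditioning.
3. *Posterior.* The soft-data integral
   $f_K(x_k) \propto \int f_S(\chi_s)\, f_G(x_k, \chi_{hard}, \chi_s)\,
   d\chi_s$ is evaluated by 21-node Gauss-Legendre tensor quadrature per
   soft dimension (at most 4 soft data per neighbourhood). The quadrature
   interval per dimension is the overlap of the soft density's central
   99.9% support with the hard-conditioned Gaussian marginal's $\pm 8$ SD
   range, so both near-Dirac and effectively vague soft data integrate
   accurately. With no soft data the posterior reduces exactly to the
   simple-kriging Gaussian conditional — kriging is the special case of BME
   under that limited knowledge base.

A soft datum co-located with the estimation point would make the joint
Gaussian singular; it is instead folded in analytically, as a density
factor multiplying the conditional posterior (the exact limit of the
co-located integral). This matters in the canonical design, where every
estimation node carries a temperature reading.

The point estimate is the posterior expectation (`posterior_mean()`, the
default, matching the choice of the expectation-form estimator as the final
one); the posterior mode (`posterior_mode()`) is available by flag and is
refined by local quadratic interpolation with ties broken toward the lower
flux.

### Numerical choices

* Posterior support: automatically built over the prior mean $\pm 6$ prior
  SD (clipped at zero), 281 points for single posteriors and 161 inside
  `bme_map()`. The trapezoid moments of a Gaussian mixture on such a grid
  are tail-limited rather than resolution-limited; supports are auto-widened
  until the estimated mass outside is below $10^{-8}$. The wider $\pm 6$ SD
  window (rather than $\pm 5$) keeps the truncation error in the posterior
  variance below the $10^{-6}$ agreement tolerance of the kriging-reduction
  property.
* Mixture components with less than $10^{-12}$ of the total quadrature mass
  are dropped.
* A conditional SD smaller than half the support step (possible with
  zero-nugget models and soft data almost on top of the target) is floored
  at that step so the density stays resolvable.
* Covariance matrices are symmetrized and jittered (up to $10^{-6}$ of the
  sill) toward positive definiteness; failures report the offending
  location pair.
* Kriging and cokriging systems built from zero-nugget Gaussian structures
  over densely spaced data are catastrophically ill-conditioned (weights can
  explode by orders of magnitude); when the reciprocal condition number
  falls below $10^{-10}$ the solver re-forms the system with an escalating
  measurement-error nugget (up to $10^{-3}$ of the sill) — the standard
  stabilization for Gaussian variograms.

## The synthetic plot

No raw campaign data are available, so `simulate_plot()` generates coupled
realizations with the statistical structure the analysis assumes, and every
claim about estimator behaviour is tested on those realizations:

* temperature: stationary Gaussian field, mean 27.18 C, Gaussian variogram
  with nugget 0.005, partial sill 0.185 and range 16 m. The published
  campaign gives the mean and SD; no temperature variogram is printed
  anywhere, so the range is this package's choice of a realistic half-plot
  scale of thermal patchiness under vegetation. The sill exceeds the square
  of the target SD (0.4 C) because spatial correlation depresses the SD
  *realized* within one plot; it is sized so the expected realized SD is
  0.4 C.
* link: $R_s = 0.1331\,e^{0.1370\,T} + \varepsilon$, the Day-2 parameter
  pair of the reference campaign. (The Day-1 pair implies a mean flux an
  order of magnitude above the measured one and is treated as unreliable.)
* residual $\varepsilon$: zero-mean Gaussian field, spherical variogram with
  nugget 0.05, partial sill 0.13, range 18 m. This sizes the flux field to
  a realized mean $\approx 5.5$ and SD $\approx 0.51$ flux units with a
  truth nugget-to-sill share of $\approx 0.18$ — inside the strong spatial
  dependence class (ratio < 0.25) reported for the fitted variograms, with
  roughly a third of the flux variance explained by temperature, matching
  the published fit correlation of about 0.57.
* fields are drawn by dense Cholesky factorization (exact at <= 1225
  nodes; factors are cached across replicates); negative fluxes are allowed
  and counted rather than silently truncated, so the generator's
  distributional assumptions stay visible to the recovery tests.

Simulation draws are reproducible: the same seed yields bit-identical
fields.

What the generator does *not* emulate: non-Gaussian flux distributions,
anisotropy, temporal drift during a measurement round, instrument error
structure, and — importantly — fine-scale flux variability beyond the
chosen nugget. Passing tests therefore demonstrate correctness of the
machinery and the *direction* of the method comparisons under these
conditions, not field-data performance.

## Sampling designs and validation

`sample_scheme()` provides deterministic nested designs of 9, 21, 37 and 49
points on the 7 x 7 grid. The exact published layout is not printed; this
package's reading spreads points over the four quadrants, the two dividing
axes and the centre (per quadrant 1 / 3 / 6 / 9 points, per axis arm
1 / 2 / 3), is nested, and is invariant under 90-degree rotation of the
plot.

`holdout_split()` draws validation subsets that avoid the plot boundary and
contiguous pairs (no two points within one grid spacing), uniformly at
random under those constraints. `compare_methods()` scores OK, Co-OK and
BME by RMSE, mean bias and Pearson correlation on such a hold-out.
`sampling_density_experiment()` re-estimates the full dense grid from each
design and scores against the simulated truth at every non-sampled node,
aggregating means and SDs over replicate seeds. Both methods share the
spatial-continuity model fitted on the full 49-point realization, so the
comparison isolates estimation quality from variogram-inference noise; the
Arrhenius regression, by contrast, is refitted on each design's own points,
since the soft data are part of what a smaller campaign must supply.

With the default conditions (30 replicates), BME with temperature soft data
beats OK at every shared design size, most at the sparsest design. The
stronger cross-design claim — BME with 9 points beating OK with 37 — does
*not* replicate under these synthetic conditions: a truth field with strong
5 m continuity and a small nugget is kriged well from 37 points, while the
BME floor at 9 points is set by the soft-data scale ($S_{TP} \approx 0.4$
at 7 degrees of freedom). That claim evidently requires a field with much
weaker short-range continuity than the fitted variograms of the reference
campaign suggest; on such data the published OK cross-validation errors
exceed the sample SD several-fold, which is consistent with this reading.

## Known limitations

* Isotropic variograms only; no space-time covariance (days are treated as
  independent replicates); no trend models beyond the constant prior mean.
* At most 4 soft data per BME neighbourhood (tensor-quadrature cost); soft
  data at 1 m spacing are strongly collinear under smooth fitted models, so
  this cap costs little accuracy in the canonical design.
* The Gaussian prior cannot encode skewness constraints; soft densities are
  the only non-Gaussian element.
* `fit_variogram_model()` estimates the range poorly when it approaches the
  plot diameter (the empirical variogram never reaches its sill); recovery
  to about +-30% on average is what the 49-point design supports.
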