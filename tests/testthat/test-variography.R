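test_that("empirical variogram matches hand-enumerated toy cases", {
  ps <- point_samples(rbind(c(0, 0), c(5, 0), c(10, 0)), c(1, 3, 5))
  emp <- empirical_variogram(ps, lag_width = 5, max_lag = 15)
  # pairs: d = 5 twice (sq diffs 4, 4) -> 2.0; d = 10 once (sq diff 16) -> 8.0
  expect_equal(emp$npairs, c(0L, 2L, 1L))
  expect_equal(emp$gamma[2:3], c(2, 8))
  expect_true(is.na(emp$gamma[1]))   # empty bin kept, not dropped

  const <- point_samples(rbind(c(0, 0), c(5, 0), c(10, 0)), c(2, 2, 2))
  expect_warning(e0 <- empirical_variogram(const, 5, 15), "identical")
  expect_equal(e0$gamma[e0$npairs > 0], c(0, 0))
  expect_true(e0$all_constant)

  # permutation invariance
  set.seed(2)
  ps2 <- random_samples(20, seed = 2)
  perm <- sample(20)
  e1 <- empirical_variogram(ps2, 5, 25)
  e2 <- empirical_variogram(point_samples(ps2$locations[perm, ],
                                          ps2$values[perm]), 5, 25)
  expect_equal(e1$gamma, e2$gamma)
  expect_equal(e1$npairs, e2$npairs)
  expect_error(empirical_variogram(ps, 5, -1), "max_lag")
})

test_that("cross-variogram identities and toy value hold", {
  ps <- point_samples(rbind(c(0, 0), c(5, 0), c(10, 0)), c(1, 3, 5))
  same <- empirical_cross_variogram(ps, ps, 5, 15)
  auto <- empirical_variogram(ps, 5, 15)
  expect_equal(same$gamma, auto$gamma)

  neg <- point_samples(ps$locations, -ps$values)
  flip <- empirical_cross_variogram(ps, neg, 5, 15)
  expect_equal(flip$gamma[flip$npairs > 0], -auto$gamma[auto$npairs > 0])

  y <- point_samples(ps$locations, c(2, 2, 8))
  cv <- empirical_cross_variogram(ps, y, 5, 15)
  expect_equal(cv$gamma[2], 3)   # (2*0 + 2*6) / (2*2)

  off <- point_samples(ps$locations + 0.1, ps$values)
  expect_error(empirical_cross_variogram(ps, off), "co-located")
})

test_that("estimators agree with the O(n^2) pair-enumeration oracle", {
  z <- random_samples(50, seed = 11)
  set.seed(12)
  y <- point_samples(z$locations, 2 + 0.5 * z$values + rnorm(50, 0, 0.2))
  emp <- empirical_variogram(z, 4, 20)
  o <- oracle_variogram(z$locations, z$values, lag_width = 4, max_lag = 20)
  expect_equal(emp$gamma, o$gamma, tolerance = 1e-12)
  expect_equal(emp$npairs, o$npairs)
  empx <- empirical_cross_variogram(z, y, 4, 20)
  ox <- oracle_variogram(z$locations, z$values, y$values, 4, 20)
  expect_equal(empx$gamma, ox$gamma, tolerance = 1e-12)
})

test_that("model curves obey their closed forms", {
  g <- variogram_model("gaussian", 0.1, 0.5, 20)
  expect_equal(vgm_gamma(g, 1e-9), 0.1, tolerance = 1e-6)
  expect_equal(vgm_gamma(g, 20), 0.1 + 0.5 * (1 - exp(-3)))
  expect_equal(vgm_gamma(g, 0), 0)
  s <- variogram_model("spherical", 0.1, 0.5, 20)
  expect_equal(vgm_gamma(s, 20), 0.6)
  expect_equal(vgm_gamma(s, 35), 0.6)   # constant beyond the range
  expect_equal(vgm_cov(s, 25), 0)       # covariance vanishes past the range
  expect_equal(vgm_cov(g, 0), 0.6)      # C(0) = sill
})

test_that("WLS fitting recovers exact model parameters", {
  truth <- toy_model()   # spherical C0 = 0.031, C = 0.411, a = 32.11
  lags <- seq(2.5, 40, by = 2.5)
  emp <- structure(list(lag = lags, gamma = vgm_gamma(truth, lags),
                        npairs = rep(50L, length(lags)), lag_width = 2.5,
                        max_lag = 40, all_constant = FALSE),
                   class = "empirical_variogram")
  fit <- fit_variogram_model(emp, "spherical")
  expect_equal(fit$nugget, 0.031, tolerance = 1e-6)
  expect_equal(fit$psill, 0.411, tolerance = 1e-6)
  expect_equal(fit$range, 32.11, tolerance = 1e-6)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-9)
})

test_that("degenerate pure-nugget input yields a flagged fit, not a crash", {
  emp <- structure(list(lag = c(2.5, 7.5, 12.5, 17.5),
                        gamma = rep(0.42, 4), npairs = rep(30L, 4),
                        lag_width = 5, max_lag = 20, all_constant = FALSE),
                   class = "empirical_variogram")
  expect_warning(fit <- fit_variogram_model(emp, "gaussian"),
                 "unidentifiable")
  expect_equal(fit$nugget + fit$psill, 0.42, tolerance = 1e-3)
  expect_true(attr(fit, "degenerate"))
  expect_true(is.na(fit$fit_r2))
})

test_that("noisy fits are at least as good as a coarse grid-search oracle", {
  truth <- variogram_model("gaussian", 0.05, 0.4, 15)
  lags <- seq(2.5, 30, by = 2.5)
  set.seed(21)
  g <- vgm_gamma(truth, lags) + rnorm(length(lags), 0, 0.05 * 0.45)
  emp <- structure(list(lag = lags, gamma = g,
                        npairs = rep(40L, length(lags)), lag_width = 2.5,
                        max_lag = 30, all_constant = FALSE),
                   class = "empirical_variogram")
  fit <- fit_variogram_model(emp, "gaussian")
  wsse <- function(p) sum(40 * (g - vgm_gamma(
    variogram_model("gaussian", p[1], p[2], p[3]), lags))^2)
  grid <- expand.grid(c0 = seq(0, 0.2, 0.01), c = seq(0.1, 0.8, 0.02),
                      a = seq(5, 40, 1))
  best <- min(apply(grid, 1, wsse))
  expect_lte(attr(fit, "wsse"), best + 1e-10)
  # and the parameters sit inside the oracle's near-optimal envelope
  near <- grid[apply(grid, 1, wsse) <= 1.05 * best, ]
  expect_gte(fit$range, min(near$a) - 1)
  expect_lte(fit$range, max(near$a) + 1)
})

test_that("fitted models are invariant to translating all coordinates", {
  z <- random_samples(40, seed = 31)
  fit1 <- fit_variogram_model(empirical_variogram(z, 5, 25), "spherical")
  z2 <- point_samples(sweep(z$locations, 2, c(120, -45), "+"), z$values)
  fit2 <- fit_variogram_model(empirical_variogram(z2, 5, 25), "spherical")
  expect_equal(fit1$nugget, fit2$nugget, tolerance = 1e-8)
  expect_equal(fit1$psill, fit2$psill, tolerance = 1e-8)
  expect_equal(fit1$range, fit2$range, tolerance = 1e-8)
})

test_that("nugget-to-sill ratio classifies spatial dependence", {
  r1 <- nugget_sill_ratio(variogram_model("gaussian", 0.035, 0.436 - 0.035,
                                          18.05))
  expect_equal(round(r1$ratio, 3), 0.080)
  expect_equal(r1$dependence_class, "strong")
  r0 <- nugget_sill_ratio(variogram_model("spherical", 0, 0.4, 10))
  expect_equal(r0$ratio, 0)
  expect_equal(r0$dependence_class, "strong")
  r2 <- nugget_sill_ratio(variogram_model("spherical", 0.232, 0.542 - 0.232,
                                          30.59))
  expect_equal(round(r2$ratio, 3), 0.428)
  expect_equal(r2$dependence_class, "moderate")
  r3 <- nugget_sill_ratio(variogram_model("spherical", 0.8, 0.2, 10))
  expect_equal(r3$dependence_class, "weak")
  degen <- variogram_model("spherical", 0, 1, 10)
  degen$psill <- 0
  expect_error(nugget_sill_ratio(degen), "ratio undefined")
})
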