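test_that("zero-variance model yields a constant field; seeds reproduce bit-identically", {
  s <- grid_spec(0.5, 0.5, 6, 6, 1)
  m0 <- field_model(27.18, variogram_model("gaussian", 0, 1e-300, 10))
  m0$variogram$psill <- 0
  f <- simulate_gaussian_field(s, m0, seed = 1)
  expect_equal(max(abs(f$values - 27.18)), 0)

  m <- field_model(5, variogram_model("spherical", 0.05, 0.2, 8))
  f1 <- simulate_gaussian_field(s, m, seed = 42)
  f2 <- simulate_gaussian_field(s, m, seed = 42)
  f3 <- simulate_gaussian_field(s, m, seed = 43)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, f3$values))
})

test_that("the dense temperature regime reproduces its mean and SD", {
  conf <- day2_defaults()
  f <- simulate_gaussian_field(conf$temp_spec, conf$temp_model, seed = 101)
  # SE of the spatial mean of a correlated field: sqrt(1' Sigma 1) / n
  xy <- grid_coords(conf$temp_spec)
  h <- as.matrix(dist(xy))
  S <- matrix(vgm_cov(conf$temp_model$variogram, h), nrow(h))
  diag(S) <- conf$temp_model$variogram$nugget + conf$temp_model$variogram$psill
  se <- sqrt(sum(S)) / nrow(xy)
  expect_lt(abs(mean(f$values) - 27.18), 3 * se)
  # the realized SD of a single field fluctuates widely under strong
  # correlation; its average over replicates sits near the emulated 0.4
  L <- attr(f, "chol")
  sds <- vapply(1:10, function(s) sd(simulate_gaussian_field(
    conf$temp_spec, conf$temp_model, seed = 200 + s, L = L)$values), 0)
  expect_equal(mean(sds), 0.4, tolerance = 0.2)
})

test_that("simulated fields recover their moments and variogram", {
  s <- grid_spec(0.5, 0.5, 10, 10, 1)
  vm <- variogram_model("spherical", 0.02, 0.18, 4)
  m <- field_model(10, vm)
  L <- NULL
  means <- vars <- numeric(100)
  gsum <- NULL
  for (r in 1:100) {
    f <- simulate_gaussian_field(s, m, seed = 1000 + r, L = L)
    L <- attr(f, "chol")
    v <- as.vector(f$values)
    means[r] <- mean(v)
    vars[r] <- var(v)
    o <- oracle_variogram(grid_coords(s), as.vector(t(f$values)),
                          lag_width = 1, max_lag = 5)
    gsum <- if (is.null(gsum)) o$gamma else gsum + o$gamma
  }
  expect_equal(mean(means), 10, tolerance = 0.05)
  # sample variance of a correlated field is biased below the sill by the
  # average covariance; compare to the exact expectation
  xy <- grid_coords(s)
  S <- matrix(vgm_cov(vm, as.matrix(dist(xy))), 100, 100)
  diag(S) <- vm$nugget + vm$psill
  ev <- (sum(diag(S)) - sum(S) / 100) / 99
  expect_equal(mean(vars), ev, tolerance = 0.05)
  gbar <- gsum / 100
  # expected value per bin: pair-weighted mean of the model semivariance at
  # the actual pair distances (the estimator is unbiased for this, not for
  # the model value at the bin centre)
  d_all <- as.vector(dist(grid_coords(s)))
  expected_bin <- sapply(1:5, function(k) {
    dk <- d_all[d_all >= k - 1 & d_all < k & d_all < 5]
    if (!length(dk)) NA else mean(vgm_gamma(vm, dk))
  })
  inside <- c(2, 3, 4)   # populated bins strictly inside the range
  expect_lt(max(abs(gbar[inside] - expected_bin[inside]) /
                expected_bin[inside]), 0.10)
  # and the package estimator agrees with the oracle exactly
  f <- simulate_gaussian_field(s, m, seed = 7, L = L)
  emp <- empirical_variogram(field_to_points(f), lag_width = 1, max_lag = 5)
  o <- oracle_variogram(grid_coords(s), as.vector(t(f$values)),
                        lag_width = 1, max_lag = 5)
  expect_equal(emp$gamma, o$gamma, tolerance = 1e-12)
  expect_equal(emp$npairs, o$npairs)
})

test_that("flux link is exact in the noiseless limit and matches scalar arithmetic", {
  s <- grid_spec(0.5, 0.5, 5, 5, 1)
  temp <- grid_field(s, matrix(27.18, 5, 5))
  res0 <- field_model(0, variogram_model("gaussian", 0, 1e-300, 10))
  res0$variogram$psill <- 0
  fl <- simulate_flux_from_temperature(temp, 0.1331, 0.1370, res0, seed = 1)
  expect_equal(max(abs(fl$values - 0.1331 * exp(0.1370 * 27.18))), 0)

  # b = 0: temperature has no effect; the downstream fit finds b ~ 0
  set.seed(5)
  tv <- grid_field(s, matrix(rnorm(25, 27, 0.4), 5, 5))
  res <- field_model(0, variogram_model("spherical", 0.01, 0.0001, 3))
  fl0 <- simulate_flux_from_temperature(tv, 5, 0, res, seed = 2)
  fit <- fit_arrhenius(as.vector(tv$values), as.vector(fl0$values))
  expect_lt(abs(fit$b), 0.05)

  expect_error(
    simulate_flux_from_temperature(temp, 1, 1000, res, seed = 1),
    "overflow")
  # negative fluxes counted, clipped only on request
  noisy <- field_model(0, variogram_model("spherical", 1, 4, 3))
  fln <- simulate_flux_from_temperature(
    grid_field(s, matrix(0, 5, 5)), 0.01, 0, noisy, seed = 3)
  expect_gt(attr(fln, "n_negative"), 0)
  flc <- simulate_flux_from_temperature(
    grid_field(s, matrix(0, 5, 5)), 0.01, 0, noisy, seed = 3,
    clip_negative = TRUE)
  expect_true(all(flc$values >= 0))
})

test_that("sampling schemes are nested, symmetric and complete", {
  spec <- grid_spec(2.5, 2.5, 7, 7, 5)
  schemes <- lapply(c(9, 21, 37, 49), function(n) sample_scheme(spec, n))
  expect_equal(vapply(schemes, nrow, 0L), c(9L, 21L, 37L, 49L))
  expect_equal(schemes[[4]][order(schemes[[4]][, 2], schemes[[4]][, 1]), ],
               grid_coords(spec), ignore_attr = TRUE)
  key <- function(m) paste(m[, 1], m[, 2])
  for (i in 1:3)
    expect_true(all(key(schemes[[i]]) %in% key(schemes[[i + 1]])))
  # 90-degree rotation about the plot centre (17.5, 17.5) maps each scheme
  # onto itself
  for (sch in schemes) {
    rot <- cbind(17.5 + (sch[, 2] - 17.5), 17.5 - (sch[, 1] - 17.5))
    expect_setequal(key(rot), key(sch))
  }
  expect_error(sample_scheme(spec, 10), "9, 21, 37, 49")
  expect_error(sample_scheme(grid_spec(0, 0, 5, 5, 1), 9), "7 x 7")
})
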