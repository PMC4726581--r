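gk_toy <- function() general_knowledge(
  5.8, variogram_model("gaussian", 0.03, 0.41, 15))

test_that("the prior covariance follows the variogram's covariance law", {
  gk <- general_knowledge(5, variogram_model("spherical", 0.05, 0.35, 20))
  pr <- build_prior(gk, rbind(c(0, 0), c(0, 0), c(50, 0), c(10, 0)))
  expect_equal(pr$cov[1, 2], 0.40, tolerance = 1e-6)  # coincident -> sill
  expect_equal(pr$cov[1, 3], 0)                       # beyond the range
  expect_equal(pr$cov[1, 4], 0.40 - vgm_gamma(gk$variogram, 10))
  expect_equal(unname(diag(pr$cov)), rep(0.40, 4), tolerance = 1e-6)
  expect_true(all(eigen(pr$cov, symmetric = TRUE)$values > -1e-12))
})

test_that("the Gaussian prior solves the discretized maximum-entropy problem", {
  # 1-D oracle: maximize -sum p log p on a grid under mean and variance
  # constraints by solving for the Lagrange multipliers; the solution must
  # be the Gaussian density with those moments
  m <- 5.8; v <- 0.44
  x <- seq(m - 6 * sqrt(v), m + 6 * sqrt(v), length.out = 801)
  moments <- function(lam) {
    q <- exp(lam[1] * x + lam[2] * x^2)
    q <- q / oracle_trapz(x, q)
    c(oracle_trapz(x, x * q) - m, oracle_trapz(x, x^2 * q) - (v + m^2))
  }
  sol <- optim(c(m / v, -0.5 / v), function(l) sum(moments(l)^2),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(sol$value, 1e-12)
  q <- exp(sol$par[1] * x + sol$par[2] * x^2)
  q <- q / oracle_trapz(x, q)
  expect_lt(max(abs(q - dnorm(x, m, sqrt(v)))), 1e-4)
  # entropy of the discretized solution matches the Gaussian closed form
  H <- -oracle_trapz(x, q * log(q))
  expect_equal(H, 0.5 * log(2 * pi * exp(1) * v), tolerance = 1e-3)
})

test_that("with no soft data the posterior is the Gaussian conditional", {
  set.seed(42)
  gk <- gk_toy()
  loc_h <- cbind(runif(20, 0, 35), runif(20, 0, 35))
  vals <- 5.8 + rnorm(20, 0, 0.5)
  for (i in 1:10) {
    tgt <- c(runif(1, 0, 35), runif(1, 0, 35))
    prior <- build_prior(gk, rbind(tgt, loc_h))
    post <- posterior_density(prior, vals)
    o <- oracle_gaussian_conditional(prior$mean, prior$cov, vals)
    expect_equal(post$mean, o$mean, tolerance = 1e-6)
    expect_equal(post$sd^2, o$var, tolerance = 1e-6)
    expect_equal(post$mode, o$mean, tolerance = 1e-4)
  }
})

test_that("a near-Dirac soft datum acts as hard data", {
  gk <- gk_toy()
  locs <- rbind(c(10, 10), c(5, 10), c(14, 12))   # target, hard, soft
  v_soft <- 6.2
  prior <- build_prior(gk, locs)
  sdat <- soft_datum(c(14, 12), center = v_soft, scale = 1e-6, df = 47)
  post <- posterior_density(prior, 5.6, soft = list(sdat))
  o <- oracle_gaussian_conditional(prior$mean, prior$cov, c(5.6, v_soft))
  expect_equal(post$mean, o$mean, tolerance = 1e-4)
  expect_equal(post$sd^2, o$var, tolerance = 1e-4)
})

test_that("the posterior matches a fine-grid double-integration oracle", {
  gk <- general_knowledge(5, variogram_model("spherical", 0.05, 0.4, 20))
  locs <- rbind(c(10, 10), c(5, 10), c(14, 10))
  prior <- build_prior(gk, locs)
  sdat <- soft_datum(c(14, 10), center = 5.4, scale = 0.45, df = 47)
  post <- posterior_density(prior, hard_values = 5.6, soft = list(sdat))
  dens_o <- oracle_posterior_1soft(prior, 5.6, sdat, post$support)
  expect_lt(max(abs(dens_o - post$density)), 1e-4)
  expect_equal(oracle_trapz(post$support, post$density), 1, tolerance = 1e-6)
})

test_that("every posterior normalizes and keeps its mass on the support", {
  set.seed(77)
  gk <- gk_toy()
  for (r in 1:8) {
    nh <- sample(2:6, 1); ns <- sample(0:3, 1)
    locs <- cbind(runif(1 + nh + ns, 0, 35), runif(1 + nh + ns, 0, 35))
    prior <- build_prior(gk, locs)
    soft <- lapply(seq_len(ns), function(i)
      soft_datum(locs[1 + nh + i, ], center = runif(1, 4.5, 7),
                 scale = runif(1, 0.2, 0.8), df = 47))
    post <- posterior_density(prior, 5.8 + rnorm(nh, 0, 0.5), soft)
    expect_equal(oracle_trapz(post$support, post$density), 1,
                 tolerance = 1e-6)
    edge <- max(post$density[1], post$density[length(post$density)])
    expect_lt(edge, 1e-3 * max(post$density))
  }
})

test_that("point estimators agree with quadrature oracles on toy densities", {
  x <- seq(0, 10, length.out = 2001)
  # skewed density
  y <- dgamma(x, shape = 3, rate = 1)
  p <- structure(list(support = x, density = y / oracle_trapz(x, y)),
                 class = "bme_posterior")
  expect_equal(posterior_mean(p),
               oracle_trapz(x, x * p$density) / oracle_trapz(x, p$density),
               tolerance = 1e-12)
  expect_equal(posterior_mode(p), 2, tolerance = 0.01)  # gamma(3,1) mode
  # symmetric density: mean = mode = centre of symmetry
  ys <- dnorm(x, 5, 0.8)
  ps <- structure(list(support = x, density = ys), class = "bme_posterior")
  expect_equal(posterior_mean(ps), 5, tolerance = 1e-6)
  expect_equal(posterior_mode(ps), 5, tolerance = 1e-6)
  # bimodal with unequal peaks: the taller one wins
  yb <- dnorm(x, 3, 0.3) + 0.7 * dnorm(x, 7, 0.3)
  pb <- structure(list(support = x, density = yb), class = "bme_posterior")
  expect_equal(posterior_mode(pb), 3, tolerance = 0.01)
})

test_that("bme_map reduces to kriging without soft data and is exact at data", {
  gk <- gk_toy()
  hard <- random_samples(15, seed = 81)
  set.seed(82)
  tgt <- cbind(runif(12, 2, 33), runif(12, 2, 33))
  bm <- bme_map(hard, soft = list(), gk, tgt, n_hard_neighbors = 15,
                n_soft_neighbors = 0)
  for (i in seq_len(nrow(tgt))) {
    prior <- build_prior(gk, rbind(tgt[i, ], hard$locations))
    o <- oracle_gaussian_conditional(prior$mean, prior$cov, hard$values)
    expect_equal(bm$estimate[i], o$mean, tolerance = 1e-6)
    expect_equal(bm$sd[i]^2, o$var, tolerance = 1e-6)
  }
  at <- bme_map(hard, list(), gk, hard$locations[3, , drop = FALSE], 15, 0)
  expect_equal(at$estimate, hard$values[3])
  expect_equal(at$sd, 0)
})

test_that("vague soft data wash out of the map", {
  gk <- gk_toy()
  hard <- random_samples(12, seed = 91)
  set.seed(92)
  soft_xy <- cbind(runif(30, 0, 35), runif(30, 0, 35))
  vague <- lapply(seq_len(30), function(i)
    soft_datum(soft_xy[i, ], center = 5.8, scale = 1e6, df = 47,
               lower_trunc = -Inf))
  tgt <- cbind(runif(6, 2, 33), runif(6, 2, 33))
  with_soft <- bme_map(hard, vague, gk, tgt, 12, 3)
  no_soft <- bme_map(hard, list(), gk, tgt, 12, 0)
  expect_lt(max(abs(with_soft$estimate - no_soft$estimate)), 1e-3)
})

test_that("an informative co-located soft datum tightens the posterior", {
  gk <- gk_toy()
  hard <- random_samples(10, seed = 95)
  tgt <- matrix(c(17.2, 18.4), 1)
  no_soft <- bme_map(hard, list(), gk, tgt, 10, 0)
  informative <- list(soft_datum(tgt[1, ], center = no_soft$estimate,
                                 scale = 0.3, df = 47))
  with_soft <- bme_map(hard, informative, gk, tgt, 10, 1)
  expect_lt(with_soft$sd, no_soft$sd + 1e-9)
  # grid-shaped targets return grid fields
  spec <- grid_spec(10, 10, 2, 2, 5)
  bm <- bme_map(hard, informative, gk, spec, 10, 1)
  expect_s3_class(bm$estimate, "grid_field")
  expect_equal(dim(bm$estimate$values), c(2, 2))
})
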