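# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain double loops and dense linear algebra.

# O(n^2) pair-enumeration (cross-)variogram estimator
oracle_variogram <- function(loc, z, y = z, lag_width, max_lag) {
  n <- nrow(loc)
  nbins <- ceiling(max_lag / lag_width)
  ssum <- rep(0, nbins); cnt <- rep(0L, nbins)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((loc[i, ] - loc[j, ])^2))
    if (d >= max_lag) next
    k <- floor(d / lag_width) + 1L
    if (k > nbins) next
    ssum[k] <- ssum[k] + (z[i] - z[j]) * (y[i] - y[j])
    cnt[k] <- cnt[k] + 1L
  }
  list(lag = (seq_len(nbins) - 0.5) * lag_width,
       gamma = ifelse(cnt > 0, ssum / (2 * cnt), NA_real_), npairs = cnt)
}

# dense ordinary-kriging solve using ALL data (no neighbourhood search)
oracle_ok <- function(loc, vals, model, target) {
  n <- nrow(loc)
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    G[i, j] <- vgm_gamma(model, sqrt(sum((loc[i, ] - loc[j, ])^2)))
  g0 <- sapply(1:n, function(i)
    vgm_gamma(model, sqrt(sum((loc[i, ] - target)^2))))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  sol <- solve(A, c(g0, 1))
  list(weights = sol[1:n],
       estimate = sum(sol[1:n] * vals),
       variance = sum(sol * c(g0, 1)))
}

# dense cokriging solve using all primary and secondary data
oracle_cok <- function(l1, v1, l2, v2, coreg, target, s2sum = 0) {
  n1 <- nrow(l1); n2 <- nrow(l2)
  gam <- function(m, p, q) vgm_gamma(m, sqrt(sum((p - q)^2)))
  A <- matrix(0, n1 + n2 + 2, n1 + n2 + 2)
  for (i in 1:n1) for (j in 1:n1)
    A[i, j] <- gam(coreg$primary_model, l1[i, ], l1[j, ])
  for (i in 1:n2) for (j in 1:n2)
    A[n1 + i, n1 + j] <- gam(coreg$secondary_model, l2[i, ], l2[j, ])
  for (i in 1:n1) for (j in 1:n2) {
    A[i, n1 + j] <- gam(coreg$cross_model, l1[i, ], l2[j, ])
    A[n1 + j, i] <- A[i, n1 + j]
  }
  A[1:n1, n1 + n2 + 1] <- 1; A[n1 + n2 + 1, 1:n1] <- 1
  A[n1 + 1:n2, n1 + n2 + 2] <- 1; A[n1 + n2 + 2, n1 + 1:n2] <- 1
  b <- c(sapply(1:n1, function(i) gam(coreg$primary_model, l1[i, ], target)),
         sapply(1:n2, function(j) gam(coreg$cross_model, l2[j, ], target)),
         1, s2sum)
  sol <- solve(A, b)
  list(w1 = sol[1:n1], w2 = sol[n1 + 1:n2],
       estimate = sum(sol[1:n1] * v1) + sum(sol[n1 + 1:n2] * v2))
}

# Gaussian conditional (simple-kriging) moments of index 1 given the rest
oracle_gaussian_conditional <- function(mean_vec, cov, values) {
  S <- cov
  m <- mean_vec[1] + S[1, -1] %*% solve(S[-1, -1], values - mean_vec[-1])
  v <- S[1, 1] - S[1, -1] %*% solve(S[-1, -1], S[-1, 1])
  list(mean = as.numeric(m), var = as.numeric(v))
}

# multivariate normal density without external packages
oracle_dmvnorm <- function(x, mu, S) {
  k <- length(mu)
  d <- x - mu
  exp(-0.5 * as.numeric(t(d) %*% solve(S, d))) /
    sqrt((2 * pi)^k * det(S))
}

oracle_trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# brute-force BME posterior for 1 target + hard values + 1 soft datum:
# f(xk) propto integral over the soft value of f_S(s) * N((xk, hard, s))
oracle_posterior_1soft <- function(prior, hard_values, sdat, support,
                                   n_int = 2000) {
  nh <- length(hard_values)
  lim <- c(sdat$center - 10 * sdat$scale, sdat$center + 10 * sdat$scale)
  lim[1] <- max(lim[1], sdat$lower_trunc)
  s_grid <- seq(lim[1], lim[2], length.out = n_int)
  fs <- dsoft(sdat, s_grid)
  dens <- sapply(support, function(xk) {
    fg <- sapply(s_grid, function(s)
      oracle_dmvnorm(c(xk, hard_values, s), prior$mean, prior$cov))
    oracle_trapz(s_grid, fs * fg)
  })
  dens / oracle_trapz(support, dens)
}

# shared small fixtures -------------------------------------------------

toy_model <- function() variogram_model("spherical", 0.031, 0.411, 32.11)

random_samples <- function(n, seed, extent = 35, mean = 5.8, sd = 0.5) {
  set.seed(seed)
  point_samples(cbind(runif(n, 0, extent), runif(n, 0, extent)),
                mean + rnorm(n, 0, sd))
}
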