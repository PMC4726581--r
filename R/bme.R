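#' General knowledge for the BME prior
#'
#' The "general knowledge" of the maximum-entropy prior: a constant mean and
#' a variogram describing spatial covariance.  Under mean and covariance
#' constraints, entropy maximization yields a multivariate Gaussian prior in
#' closed form, with \eqn{C(h) = (C_0 + C) - \gamma(h)}.
#'
#' @param mean Constant prior mean (attribute units); the conventional
#'   choice is the arithmetic mean of the hard data.
#' @param variogram A \code{\link{variogram_model}} with positive sill.
#' @return An object of class \code{general_knowledge}.
#' @export
general_knowledge <- function(mean, variogram) {
  stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean),
            inherits(variogram, "variogram_model"))
  if (variogram$nugget + variogram$psill <= 0)
    stop("general knowledge requires a positive sill")
  structure(list(mean = mean, variogram = variogram),
            class = "general_knowledge")
}

#' Maximum-entropy Gaussian prior over a set of locations
#'
#' Builds the joint Gaussian moments implied by the general knowledge: a
#' constant mean vector and covariance matrix \eqn{C(h_{ij})} with
#' \eqn{C(0)} equal to the sill.  The matrix is symmetrized and, if needed,
#' jittered towards positive definiteness (co-located points are perfectly
#' correlated and make it singular up to jitter).
#'
#' @param gk A \code{\link{general_knowledge}}.
#' @param locations Two-column matrix of locations, ordered as the caller
#'   intends to use them (e.g. estimation point first, then hard, then soft).
#' @return List with \code{mean} (vector), \code{cov} (matrix) and
#'   \code{locations}.
#' @export
build_prior <- function(gk, locations) {
  stopifnot(inherits(gk, "general_knowledge"))
  locations <- as_locations(locations)
  h <- as.matrix(stats::dist(locations))
  n <- nrow(locations)
  sill <- gk$variogram$nugget + gk$variogram$psill
  C <- matrix(vgm_cov(gk$variogram, h), n, n)
  diag(C) <- sill
  C <- (C + t(C)) / 2
  ok <- FALSE
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    Cj <- C + diag(jit * sill, n)
    if (!inherits(tryCatch(chol(Cj), error = function(e) e), "error")) {
      C <- Cj; ok <- TRUE; break
    }
  }
  if (!ok) {
    off <- which(h == min(h[upper.tri(h)]), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("prior covariance not positive definite after ",
                        "jitter; closest location pair: (%g, %g) and (%g, %g)"),
                 locations[off[1], 1], locations[off[1], 2],
                 locations[off[2], 1], locations[off[2], 2]))
  }
  list(mean = rep(gk$mean, n), cov = C, locations = locations)
}

# Gaussian conditioning: moments of x[keep] given x[given] = values
condition_gaussian <- function(mean, cov, given, values) {
  keep <- setdiff(seq_along(mean), given)
  if (length(given) == 0)
    return(list(mean = mean[keep], cov = cov[keep, keep, drop = FALSE]))
  Sgg <- cov[given, given, drop = FALSE]
  Skg <- cov[keep, given, drop = FALSE]
  B <- Skg %*% solve(Sgg)
  list(mean = mean[keep] + as.vector(B %*% (values - mean[given])),
       cov = cov[keep, keep, drop = FALSE] - B %*% t(Skg))
}

#' BME posterior density at one estimation point
#'
#' Computes the posterior density
#' \deqn{f_K(x_k) = A^{-1} \int f_S(\chi_{soft})
#'   f_G(x_k, \chi_{hard}, \chi_{soft}) \, d\chi_{soft}}
#' by Gaussian conditioning on the hard data and fixed-order Gauss-Legendre
#' tensor quadrature over the soft-data dimensions.  The quadrature interval
#' in each soft dimension is the overlap of the soft density's central
#' 99.9\% support and the hard-conditioned Gaussian marginal's +-8 SD range,
#' so both sharply informative and effectively vague soft data integrate
#' accurately.
#'
#' The \code{prior} must be ordered: estimation point first, then
#' \code{length(hard_values)} hard locations, then \code{length(soft)} soft
#' locations.  Soft data co-located with the estimation point cannot enter
#' the prior (the joint covariance would be singular); pass them through
#' \code{soft_at_target} and their densities multiply the posterior directly
#' (the exact limit of the co-located integral).
#'
#' @param prior Output of \code{\link{build_prior}}.
#' @param hard_values Numeric vector of hard data values.
#' @param soft List of \code{\link{soft_datum}} objects (at most 4).
#' @param xk_support Optional numeric grid of flux values on which to
#'   evaluate the posterior; by default 281 points spanning the prior mean
#'   +- 6 prior SD, clipped below at \code{lower_bound} and auto-widened
#'   until the estimated mass outside is negligible.
#' @param soft_at_target Optional list of \code{soft_datum} co-located with
#'   the estimation point.
#' @param n_quad Gauss-Legendre nodes per soft dimension (default 21).
#' @param lower_bound Physical lower bound of the attribute (default 0 for
#'   fluxes; use -Inf to disable).
#' @param n_support Number of support points when \code{xk_support} is
#'   built automatically.
#' @return An object of class \code{bme_posterior} with fields
#'   \code{support, density, normalizer, mean, mode, sd}.
#' @export
posterior_density <- function(prior, hard_values, soft = list(),
                              xk_support = NULL, soft_at_target = list(),
                              n_quad = 21, lower_bound = 0,
                              n_support = 281) {
  nh <- length(hard_values)
  ns <- length(soft)
  if (ns > 4) stop("at most 4 soft data per neighbourhood (quadrature cap)")
  if (length(prior$mean) != 1 + nh + ns)
    stop("prior dimension does not match 1 + hard + soft")
  for (s in c(soft, soft_at_target))
    stopifnot(inherits(s, "soft_datum"))

  # condition (target, soft) on the hard data
  cond <- condition_gaussian(prior$mean, prior$cov,
                             given = 1 + seq_len(nh), values = hard_values)
  m_k <- cond$mean[1]
  if (ns > 0) {
    m_s <- cond$mean[-1]
    S_kk <- cond$cov[1, 1]
    S_ks <- cond$cov[1, -1, drop = FALSE]
    S_ss <- cond$cov[-1, -1, drop = FALSE]
    # per-dimension quadrature intervals
    gl <- pracma::gaussLegendre(n_quad, 0, 1)   # reference nodes on (0, 1)
    nodes1 <- vector("list", ns)
    wts1 <- vector("list", ns)
    for (i in seq_len(ns)) {
      ssd <- sqrt(max(S_ss[i, i], 0))
      sup <- soft_support(soft[[i]])
      lo <- max(sup[1], m_s[i] - 8 * ssd)
      hi <- min(sup[2], m_s[i] + 8 * ssd)
      if (!(hi > lo)) { lo <- sup[1]; hi <- sup[2] }  # disjoint: trust the soft pdf
      nodes1[[i]] <- lo + (hi - lo) * gl$x
      wts1[[i]] <- (hi - lo) * gl$w * dsoft(soft[[i]], nodes1[[i]])
    }
    # tensor grid over soft dimensions
    grid_idx <- as.matrix(expand.grid(lapply(rep(n_quad, ns), seq_len)))
    X <- matrix(0, nrow(grid_idx), ns)
    W <- rep(1, nrow(grid_idx))
    for (i in seq_len(ns)) {
      X[, i] <- nodes1[[i]][grid_idx[, i]]
      W <- W * wts1[[i]][grid_idx[, i]]
    }
    # Gaussian density of the soft block given hard, and the conditional
    # moments of the target given (hard, soft)
    Sinv <- solve(S_ss)
    dev <- sweep(X, 2, m_s)
    qform <- rowSums((dev %*% Sinv) * dev)
    logdet <- determinant(S_ss, logarithm = TRUE)$modulus
    fG_s <- exp(-0.5 * qform - 0.5 * (ns * log(2 * pi) + as.numeric(logdet)))
    B <- as.vector(S_ks %*% Sinv)
    mu_mix <- m_k + as.vector(dev %*% B)
    v_cond <- max(S_kk - sum(B * as.vector(S_ks)), 0)
    w_mix <- W * fG_s
    if (!all(is.finite(w_mix)))
      stop(sprintf("non-finite quadrature weights (soft scales: %s)",
                   paste(signif(vapply(soft, `[[`, 0, "scale"), 4),
                         collapse = ", ")))
    if (sum(w_mix) <= 0)
      stop("zero normalizer: soft data incompatible with the prior")
    A_norm <- sum(w_mix)
    # negligible mixture components contribute < ~1e-9 of the posterior mass
    keep <- w_mix > 1e-12 * A_norm
    w_mix <- w_mix[keep]
    mu_mix <- mu_mix[keep]
  } else {
    mu_mix <- m_k
    v_cond <- max(cond$cov[1, 1], 0)
    w_mix <- 1
    A_norm <- 1
  }
  sd_cond <- sqrt(max(v_cond, 1e-300))

  # posterior support: prior-based default, auto-widened
  p_mean <- prior$mean[1]
  p_sd <- sqrt(prior$cov[1, 1])
  if (is.null(xk_support)) {
    lo <- max(lower_bound, p_mean - 6 * p_sd)
    hi <- p_mean + 6 * p_sd
    for (rep_i in 1:8) {
      out_hi <- sum(w_mix * stats::pnorm(hi, mu_mix, sd_cond,
                                         lower.tail = FALSE)) / sum(w_mix)
      out_lo <- if (lo > lower_bound)
        sum(w_mix * stats::pnorm(lo, mu_mix, sd_cond)) / sum(w_mix) else 0
      if (out_hi < 1e-8 && out_lo < 1e-8) break
      if (out_hi >= 1e-8) hi <- hi + 3 * p_sd
      if (out_lo >= 1e-8) lo <- max(lower_bound, lo - 3 * p_sd)
    }
    # a sharply informative co-located soft datum confines the posterior to
    # (essentially) its own support; clip so the grid resolves it
    if (length(soft_at_target)) {
      sup <- vapply(soft_at_target, soft_support, numeric(2), p = 1e-4)
      slo <- max(lower_bound, max(sup[1, ])); shi <- min(sup[2, ])
      lo2 <- max(lo, slo); hi2 <- min(hi, shi)
      if (hi2 > lo2) { lo <- lo2; hi <- hi2 }
      else if (shi > slo) { lo <- slo; hi <- shi }
    }
    xk_support <- seq(lo, hi, length.out = n_support)
  }

  # a near-degenerate conditional (e.g. zero-nugget model with a soft datum
  # almost on top of the target) must stay resolvable on the support grid
  step <- min(diff(xk_support))
  sd_cond <- max(sd_cond, step / 2)

  dens <- mixture_density(xk_support, w_mix, mu_mix, sd_cond)
  for (s in soft_at_target) dens <- dens * dsoft(s, xk_support)
  Z <- trapz_(xk_support, dens)
  if (!is.finite(Z) || Z <= 0)
    stop("zero normalizer: posterior density vanished on its support")
  dens <- dens / Z

  post <- structure(list(support = xk_support, density = dens,
                         normalizer = A_norm * Z),
                    class = "bme_posterior")
  post$mean <- posterior_mean(post)
  post$sd <- sqrt(max(trapz_(xk_support, dens * xk_support^2) - post$mean^2, 0))
  post$mode <- posterior_mode(post)
  post
}

# sum_j w_j Normal(x; mu_j, sd) evaluated on a vector x, vectorized over
# mixture components
mixture_density <- function(x, w, mu, sd) {
  if (length(mu) == 1) return(w * stats::dnorm(x, mu, sd))
  M <- stats::dnorm(outer(x, mu, "-") / sd) / sd
  as.vector(M %*% w)
}

trapz_ <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' @export
print.bme_posterior <- function(x, ...) {
  cat(sprintf(paste0("bme_posterior: support [%.4g, %.4g] (%d pts), mean = ",
                     "%.4g, mode = %.4g, sd = %.4g\n"),
              min(x$support), max(x$support), length(x$support),
              x$mean, x$mode, x$sd))
  invisible(x)
}

#' Posterior expectation estimator
#'
#' Trapezoid expectation \eqn{\int x f_K(x) dx} over the support grid; the
#' default BME point estimate.
#'
#' @param p A \code{\link{posterior_density}} result.
#' @return Flux estimate.
#' @export
posterior_mean <- function(p) {
  stopifnot(inherits(p, "bme_posterior"))
  trapz_(p$support, p$density * p$support) / trapz_(p$support, p$density)
}

#' Posterior mode estimator
#'
#' Argmax of the posterior over the support grid, refined by local quadratic
#' interpolation through the three points around the discrete maximum; ties
#' are broken towards the lower flux value.
#'
#' @param p A \code{\link{posterior_density}} result.
#' @return Flux estimate.
#' @export
posterior_mode <- function(p) {
  stopifnot(inherits(p, "bme_posterior"))
  i <- which.max(p$density)   # first (lowest-flux) maximum on ties
  n <- length(p$support)
  if (i == 1 || i == n) return(p$support[i])
  x <- p$support[(i - 1):(i + 1)]
  y <- p$density[(i - 1):(i + 1)]
  denom <- (y[1] - 2 * y[2] + y[3])
  if (abs(denom) < 1e-300) return(p$support[i])
  # vertex of the parabola through the three points (uniform spacing)
  p$support[i] + 0.5 * (x[2] - x[1]) * (y[1] - y[3]) / denom
}

#' BME estimation map
#'
#' For each target, selects the nearest hard and soft neighbours, builds the
#' maximum-entropy Gaussian prior, conditions on the hard values and soft
#' densities and stores the posterior mean (or mode) and posterior SD.
#' Targets co-located with a hard datum return that value with SD 0
#' (exactness).  Soft data co-located with a target are folded in exactly as
#' a density factor rather than through quadrature.  Deterministic given its
#' inputs.
#'
#' @param hard Hard \code{\link{point_samples}}.
#' @param soft List of \code{\link{soft_datum}} objects (may be empty).
#' @param gk A \code{\link{general_knowledge}}.
#' @param targets A \code{\link{grid_spec}} or a two-column location matrix.
#' @param n_hard_neighbors,n_soft_neighbors Neighbourhood sizes (soft
#'   capped at 4).
#' @param estimator "mean" (posterior expectation, the default) or "mode".
#' @param n_support Posterior support resolution per target; the default 161
#'   resolves point estimates and SDs to well below sampling error (the
#'   trapezoid moments are tail-limited, not resolution-limited).
#' @param verbose Print a progress line every 100 targets?
#' @return If \code{targets} is a grid: list of two \code{grid_field}s,
#'   \code{estimate} and \code{sd}.  Otherwise a data frame with columns
#'   \code{x, y, estimate, sd}.
#' @export
bme_map <- function(hard, soft, gk, targets, n_hard_neighbors = 12,
                    n_soft_neighbors = 3, estimator = c("mean", "mode"),
                    n_support = 161, verbose = FALSE) {
  stopifnot(inherits(hard, "point_samples"),
            inherits(gk, "general_knowledge"))
  estimator <- match.arg(estimator)
  if (n_soft_neighbors > 4)
    stop("n_soft_neighbors must be <= 4 (quadrature cap)")
  as_grid <- inherits(targets, "grid_spec")
  tgt <- if (as_grid) grid_coords(targets) else as_locations(targets)
  soft_loc <- if (length(soft))
    do.call(rbind, lapply(soft, `[[`, "location")) else
    matrix(numeric(0), 0, 2)
  est <- sdv <- numeric(nrow(tgt))
  for (t in seq_len(nrow(tgt))) {
    p <- tgt[t, ]
    dh <- sqrt((hard$locations[, 1] - p[1])^2 + (hard$locations[, 2] - p[2])^2)
    if (any(dh < 1e-9)) {          # exactness at hard data
      est[t] <- hard$values[which.min(dh)]
      sdv[t] <- 0
      next
    }
    ih <- nearest_idx(hard$locations, p, n_hard_neighbors)
    soft_sel <- list()
    if (length(soft) && n_soft_neighbors > 0) {
      is_ <- nearest_idx(soft_loc, p, n_soft_neighbors)
      soft_sel <- soft[is_]
    }
    co <- vapply(soft_sel, function(s)
      sqrt(sum((s$location - p)^2)) < 1e-9, logical(1))
    soft_at <- soft_sel[co]
    soft_q <- soft_sel[!co]
    locs <- rbind(p, hard$locations[ih, , drop = FALSE],
                  if (length(soft_q))
                    do.call(rbind, lapply(soft_q, `[[`, "location")))
    prior <- build_prior(gk, locs)
    post <- posterior_density(prior, hard$values[ih], soft_q,
                              soft_at_target = soft_at,
                              n_support = n_support)
    est[t] <- if (estimator == "mean") post$mean else post$mode
    sdv[t] <- post$sd
    if (verbose && t %% 100 == 0)
      message(sprintf("bme_map: %d / %d targets", t, nrow(tgt)))
  }
  if (as_grid) {
    shape <- function(v) grid_field(targets,
      matrix(v, nrow = targets$n_y, ncol = targets$n_x, byrow = TRUE))
    list(estimate = shape(est), sd = shape(sdv))
  } else {
    data.frame(x = tgt[, 1], y = tgt[, 2], estimate = est, sd = sdv)
  }
}
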