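#' Fit the exponential (Arrhenius-type) flux-temperature regression
#'
#' Nonlinear least squares on \eqn{R_s = a e^{bT}}, initialized from the
#' linear regression of \eqn{\ln R_s} on \eqn{T} (or from a fixed fallback
#' when non-positive fluxes preclude the log transform).  Alongside the
#' parameters the fit carries the interval statistics needed to build
#' prediction intervals: the residual standard deviation
#' \eqn{S_{T P} = \sqrt{SSE/(n-2)}}, the temperature sum of squares
#' \eqn{S_{TT} = \sum (T_i - \bar T)^2}, the mean temperature \eqn{\bar T},
#' and the two-sided 95\% Student-t critical value at \eqn{n - 2} degrees of
#' freedom.  \code{CR} is the Pearson correlation between fitted and
#' observed fluxes.
#'
#' @param temps Soil temperatures (degrees C), length n >= 3, not all equal.
#' @param fluxes Observed CO2 effluxes (flux units), same length.
#' @param t_crit_override Optional fixed critical value replacing the
#'   computed Student-t quantile (for reproducing published arithmetic that
#'   used a different tabulated value).
#' @return An object of class \code{arrhenius_fit} with fields
#'   \code{a, b, n, CR, S_TP, S_TT, T_bar, t_crit, df}.
#' @export
fit_arrhenius <- function(temps, fluxes, t_crit_override = NULL) {
  temps <- as.numeric(temps); fluxes <- as.numeric(fluxes)
  n <- length(temps)
  if (length(fluxes) != n) stop("temps and fluxes must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(temps)) || !all(is.finite(fluxes)))
    stop("temps and fluxes must be finite")
  if (stats::sd(temps) == 0) stop("degenerate temperatures: all equal")

  if (all(fluxes > 0)) {
    lf <- stats::lm(log(fluxes) ~ temps)
    start <- list(a = exp(stats::coef(lf)[[1]]), b = stats::coef(lf)[[2]])
  } else {
    b0 <- 0.1
    start <- list(a = mean(fluxes) * exp(-b0 * mean(temps)), b = b0)
  }
  df <- data.frame(T = temps, R = fluxes)
  fit <- minpack.lm::nlsLM(R ~ a * exp(b * T), data = df, start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  co <- stats::coef(fit)
  fitted <- co[["a"]] * exp(co[["b"]] * temps)
  sse <- sum((fluxes - fitted)^2)
  dfree <- n - 2
  out <- list(a = co[["a"]], b = co[["b"]], n = n,
              CR = suppressWarnings(stats::cor(fitted, fluxes)),
              S_TP = sqrt(sse / dfree),
              S_TT = sum((temps - mean(temps))^2),
              T_bar = mean(temps),
              df = dfree,
              t_crit = if (is.null(t_crit_override))
                stats::qt(0.975, dfree) else t_crit_override,
              vcov = tryCatch(stats::vcov(fit), error = function(e) NULL))
  class(out) <- "arrhenius_fit"
  out
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(paste0("arrhenius_fit: Rs = %.4g * exp(%.4g T), n = %d, ",
                     "CR = %.4f\n  S_TP = %.4g, S_TT = %.4g, T_bar = %.4g, ",
                     "t(df = %d, 95%%) = %.4g\n"),
              x$a, x$b, x$n, x$CR, x$S_TP, x$S_TT, x$T_bar, x$df, x$t_crit))
  invisible(x)
}

#' 95% prediction interval for a new flux observation
#'
#' \deqn{\hat R_s \pm t_{n-2, 0.025} S_{TP}
#'   \sqrt{1 + 1/n + (T - \bar T)^2 / S_{TT}}}
#' The half-width is minimal at \eqn{T = \bar T} and increases monotonically
#' in \eqn{|T - \bar T|}.
#'
#' @param fit An \code{\link{arrhenius_fit}}.
#' @param T Temperature(s) in degrees C.
#' @return A matrix with columns \code{lower, upper} (one row per
#'   temperature).
#' @export
prediction_interval <- function(fit, T) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  center <- fit$a * exp(fit$b * T)
  half <- fit$t_crit * soft_scale(fit, T)
  cbind(lower = center - half, upper = center + half)
}

# prediction-interval scale (half-width divided by t_crit)
soft_scale <- function(fit, T) {
  fit$S_TP * sqrt(1 + 1 / fit$n + (T - fit$T_bar)^2 / fit$S_TT)
}

#' Convert a temperature field into probabilistic soft data
#'
#' Each grid node not excluded becomes one soft datum: an unmeasured flux
#' described by a Student-t density with \eqn{n - 2} degrees of freedom,
#' centred on the regression prediction \eqn{a e^{bT}} and scaled by the
#' prediction-interval scale, truncated below at \code{lower_trunc}
#' (fluxes are physically non-negative) and renormalized.
#'
#' @param fit An \code{\link{arrhenius_fit}}.
#' @param temp_field Temperature \code{\link{grid_field}}.
#' @param exclude Optional matrix of locations to skip (typically the hard
#'   flux sites, which need no soft surrogate).
#' @param lower_trunc Lower truncation bound (default 0).
#' @return A list of \code{soft_datum} objects, each with fields
#'   \code{location, center, scale, df, lower_trunc}.
#' @export
make_soft_data <- function(fit, temp_field, exclude = NULL, lower_trunc = 0) {
  stopifnot(inherits(fit, "arrhenius_fit"), inherits(temp_field, "grid_field"))
  if (!all(is.finite(temp_field$values)))
    stop("temperature grid must be finite")
  pts <- field_to_points(temp_field)
  keep <- rep(TRUE, n_samples(pts))
  if (!is.null(exclude) && NROW(exclude) > 0) {
    ex <- as_locations(exclude)
    for (i in seq_len(nrow(ex)))
      keep <- keep & (abs(pts$locations[, 1] - ex[i, 1]) > 1e-9 |
                      abs(pts$locations[, 2] - ex[i, 2]) > 1e-9)
  }
  idx <- which(keep)
  lapply(idx, function(i) {
    T <- pts$values[i]
    ctr <- fit$a * exp(fit$b * T)
    # an exactly-zero residual SD (noiseless fit) degenerates to a point
    # mass; keep a strictly positive scale
    sc <- max(soft_scale(fit, T), 1e-10 * max(abs(ctr), 1))
    soft_datum(pts$locations[i, ], center = ctr, scale = sc, df = fit$df,
               lower_trunc = lower_trunc)
  })
}

#' Construct a single soft datum
#'
#' @param location (x, y) pair in metres.
#' @param center Density centre (flux units).
#' @param scale Positive scale (flux units).
#' @param df Degrees of freedom of the Student-t.
#' @param lower_trunc Lower truncation bound (\code{-Inf} disables).
#' @return An object of class \code{soft_datum}.
#' @export
soft_datum <- function(location, center, scale, df, lower_trunc = 0) {
  stopifnot(is.numeric(center), is.numeric(scale), scale > 0, df > 0)
  structure(list(location = as.numeric(location)[1:2], center = center,
                 scale = scale, df = df, lower_trunc = lower_trunc),
            class = "soft_datum")
}

#' Soft-datum density
#'
#' Truncated, renormalized scaled/shifted Student-t density.
#'
#' @param sd_ A \code{\link{soft_datum}}.
#' @param x Flux values at which to evaluate.
#' @return Density values (0 below the truncation bound).
#' @export
dsoft <- function(sd_, x) {
  stopifnot(inherits(sd_, "soft_datum"))
  z <- (x - sd_$center) / sd_$scale
  dens <- stats::dt(z, df = sd_$df) / sd_$scale
  if (is.finite(sd_$lower_trunc)) {
    ptrunc <- stats::pt((sd_$lower_trunc - sd_$center) / sd_$scale, sd_$df)
    dens <- ifelse(x < sd_$lower_trunc, 0, dens / (1 - ptrunc))
  }
  dens
}

# central interval of a soft datum's untruncated density (for quadrature
# support); p is the total tail mass excluded
soft_support <- function(sd_, p = 1e-3) {
  q <- stats::qt(1 - p / 2, df = sd_$df)
  lo <- sd_$center - q * sd_$scale
  hi <- sd_$center + q * sd_$scale
  if (is.finite(sd_$lower_trunc)) lo <- max(lo, sd_$lower_trunc)
  c(lo, hi)
}
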