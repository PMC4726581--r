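#' Root mean squared error
#'
#' \eqn{\sqrt{\sum (x^*_k - x_k)^2 / n}}.
#'
#' @param estimates,observations Equal-length numeric vectors.
#' @return RMSE in attribute units.
#' @export
rmse <- function(estimates, observations) {
  check_pair(estimates, observations)
  sqrt(mean((estimates - observations)^2))
}

#' Pearson correlation between estimates and observations
#'
#' The validation statistic CR; errors on a constant vector (undefined
#' correlation) rather than returning NA.
#'
#' @inheritParams rmse
#' @return Correlation in [-1, 1].
#' @export
correlation <- function(estimates, observations) {
  check_pair(estimates, observations)
  if (stats::sd(estimates) == 0 || stats::sd(observations) == 0)
    stop("correlation undefined: constant vector")
  stats::cor(estimates, observations)
}

#' Mean bias (average deviation)
#'
#' \eqn{\sum (x^*_k - x_k) / n}.
#'
#' @inheritParams rmse
#' @return Bias in attribute units.
#' @export
bias <- function(estimates, observations) {
  check_pair(estimates, observations)
  mean(estimates - observations)
}

check_pair <- function(estimates, observations) {
  if (length(estimates) != length(observations))
    stop("estimates and observations must have equal length")
  if (length(estimates) == 0) stop("empty vectors")
  invisible(TRUE)
}

#' Hold-out split for cross-validation on a sampling grid
#'
#' Selects \code{n_holdout} validation points that are interior (not on the
#' outer edge of the sampling grid) and mutually non-adjacent (no two within
#' one grid spacing of each other), uniformly at random under those
#' constraints.  This formalizes the usual practice of avoiding validation
#' points that sit on the boundary or form contiguous runs.
#'
#' @param samples \code{\link{point_samples}} on a regular grid.
#' @param n_holdout Number of validation points (default 5, about 10\% of a
#'   49-point campaign).
#' @param seed Integer RNG seed.
#' @return List with \code{train} and \code{test} \code{point_samples} and
#'   the selected indices \code{test_idx}.
#' @export
holdout_split <- function(samples, n_holdout = 5, seed = 1) {
  stopifnot(inherits(samples, "point_samples"))
  n <- n_samples(samples)
  if (n_holdout >= n) stop("n_holdout must be smaller than the sample count")
  loc <- samples$locations
  if (n_holdout == 0) {
    return(list(train = samples,
                test = NULL, test_idx = integer(0)))
  }
  interior <- which(loc[, 1] > min(loc[, 1]) & loc[, 1] < max(loc[, 1]) &
                    loc[, 2] > min(loc[, 2]) & loc[, 2] < max(loc[, 2]))
  spacing <- min(stats::dist(loc))
  if (length(interior) < n_holdout)
    stop(sprintf("constraints unsatisfiable: only %d interior points",
                 length(interior)))
  set.seed(as.integer(seed))
  pick <- NULL
  for (try_i in seq_len(10000)) {
    cand <- sample(interior, n_holdout)
    if (n_holdout == 1 ||
        min(stats::dist(loc[cand, , drop = FALSE])) > spacing + 1e-9) {
      pick <- sort(cand); break
    }
  }
  if (is.null(pick)) {
    # greedy bound on what is feasible, for the error message
    left <- interior; kept <- integer(0)
    while (length(left)) {
      kept <- c(kept, left[1])
      d <- sqrt((loc[left, 1] - loc[left[1], 1])^2 +
                (loc[left, 2] - loc[left[1], 2])^2)
      left <- left[d > spacing + 1e-9]
    }
    stop(sprintf(paste0("could not draw %d mutually non-adjacent interior ",
                        "points; at most about %d are feasible"),
                 n_holdout, length(kept)))
  }
  list(train = point_samples(loc[-pick, , drop = FALSE],
                             samples$values[-pick]),
       test = point_samples(loc[pick, , drop = FALSE],
                            samples$values[pick]),
       test_idx = pick)
}

# fit both candidate variogram models and keep the better (unweighted R2,
# ties to gaussian); returns a variogram_model
fit_best_variogram <- function(emp, kinds = c("gaussian", "spherical")) {
  fits <- list()
  for (k in kinds) {
    f <- tryCatch(suppressWarnings(fit_variogram_model(emp, k)),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[k]] <- f
  }
  if (!length(fits)) stop("no variogram model could be fitted")
  r2 <- vapply(fits, function(f) ifelse(is.finite(f$fit_r2), f$fit_r2, -Inf),
               0)
  fits[[which.max(r2)]]
}

#' Compare OK, cokriging and BME on a hold-out split
#'
#' Runs the three estimators on the training part of a hold-out split of the
#' hard flux data and evaluates RMSE, bias and CR on the held-out points.
#' OK uses the flux samples only; cokriging adds the dense temperature grid
#' as a secondary attribute through a fitted cross-variogram; BME converts
#' the temperature grid into Student-t soft data through the Arrhenius-type
#' regression fitted on the training samples.
#'
#' @param hard Hard flux \code{\link{point_samples}} (co-located with
#'   temperature grid nodes).
#' @param temp_grid Temperature \code{\link{grid_field}}.
#' @param config Optional list of knobs: \code{n_holdout} (5),
#'   \code{n_neighbors} (16), \code{n_hard_neighbors} (12),
#'   \code{n_soft_neighbors} (3), \code{methods} (c("BME","Co-OK","OK")),
#'   \code{kinds} (candidate variogram kinds).
#' @param seed Integer RNG seed for the hold-out draw.
#' @return Data frame with one row per method: \code{method, rmse, bias, cr}.
#' @export
compare_methods <- function(hard, temp_grid, config = list(), seed = 1) {
  stopifnot(inherits(hard, "point_samples"), inherits(temp_grid, "grid_field"))
  cf <- utils::modifyList(list(n_holdout = 5, n_neighbors = 16,
                               n_hard_neighbors = 12, n_soft_neighbors = 3,
                               methods = c("BME", "Co-OK", "OK"),
                               kinds = c("gaussian", "spherical")), config)
  split <- holdout_split(hard, cf$n_holdout, seed)
  train <- split$train; test <- split$test
  tgt <- test$locations

  emp_f <- empirical_variogram(train)
  mod_f <- fit_best_variogram(emp_f, cf$kinds)

  rows <- list()
  for (method in cf$methods) {
    estimate <- switch(method,
      "OK" = ordinary_kriging(train, mod_f, tgt, cf$n_neighbors)$estimate,
      "Co-OK" = {
        temp_at_train <- point_samples(train$locations,
                                       field_value_at(temp_grid,
                                                      train$locations))
        emp_x <- empirical_cross_variogram(train, temp_at_train)
        mod_x <- fit_best_variogram(emp_x, cf$kinds)
        emp_t <- empirical_variogram(field_to_points(temp_grid))
        mod_t <- fit_best_variogram(emp_t, cf$kinds)
        coreg <- coregionalization(mod_f, mod_t, mod_x)
        cokriging(train, field_to_points(temp_grid), coreg, tgt,
                  cf$n_neighbors, cf$n_neighbors)$estimate
      },
      "BME" = {
        temp_at_train <- field_value_at(temp_grid, train$locations)
        fit <- fit_arrhenius(temp_at_train, train$values)
        soft <- make_soft_data(fit, temp_grid, exclude = train$locations)
        gk <- general_knowledge(mean(train$values), mod_f)
        bme_map(train, soft, gk, tgt, cf$n_hard_neighbors,
                cf$n_soft_neighbors)$estimate
      },
      stop("unknown method: ", method))
    rows[[method]] <- data.frame(method = method,
                                 rmse = rmse(estimate, test$values),
                                 bias = bias(estimate, test$values),
                                 cr = correlation(estimate, test$values))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sampling-density experiment
#'
#' For each replicate seed, simulates a coupled temperature/flux realization
#' of the synthetic study plot, then for every sampling scheme estimates the
#' flux over the full dense grid from the scheme's points and scores the
#' estimates against the simulated truth at every non-sampled grid node
#' (the estimation set the shrinking-design comparison maps).  BME uses soft data
#' derived from the dense temperature grid through an Arrhenius regression
#' refitted on each scheme's own samples; OK uses the flux samples alone.
#' The spatial-continuity model is fitted once per replicate on the full
#' 49-point realization (a prior structural analysis shared by both
#' methods), so the comparison isolates estimation, not variogram inference.
#'
#' @param conf Study conditions as from \code{\link{day2_defaults}}.
#' @param schemes Subset of c(9, 21, 37, 49).
#' @param seeds Integer vector of replicate seeds.
#' @param methods Subset of c("BME", "OK").
#' @param config Optional knobs passed to the estimators (see
#'   \code{\link{compare_methods}}).
#' @return Data frame with columns
#'   \code{seed, scheme, method, rmse, cr, bias}.
#' @export
sampling_density_experiment <- function(conf = day2_defaults(),
                                        schemes = c(9, 21, 37, 49),
                                        seeds = 1:30,
                                        methods = c("BME", "OK"),
                                        config = list()) {
  cf <- utils::modifyList(list(n_neighbors = 16, n_hard_neighbors = 12,
                               n_soft_neighbors = 3,
                               kinds = c("gaussian", "spherical")), config)
  L_temp <- NULL; L_resid <- NULL
  rows <- list()
  for (seed in seeds) {
    sim <- simulate_plot(conf, seed, L_temp, L_resid)
    L_temp <- sim$L_temp; L_resid <- sim$L_resid
    mod_f <- fit_best_variogram(empirical_variogram(sim$hard), cf$kinds)
    all_xy <- grid_coords(conf$temp_spec)
    flux_all <- field_value_at(sim$flux, all_xy)
    for (scheme in schemes) {
      sxy <- sample_scheme(conf$flux_spec, scheme)
      in_scheme <- apply(all_xy, 1, function(p)
        any(abs(sxy[, 1] - p[1]) < 1e-9 & abs(sxy[, 2] - p[2]) < 1e-9))
      train <- point_samples(sxy, field_value_at(sim$flux, sxy))
      tgt <- all_xy[!in_scheme, , drop = FALSE]
      truth <- flux_all[!in_scheme]
      for (method in methods) {
        estimate <- switch(method,
          "OK" = ordinary_kriging(train, mod_f, tgt,
                                  cf$n_neighbors)$estimate,
          "BME" = {
            temp_at <- field_value_at(sim$temp, train$locations)
            fit <- fit_arrhenius(temp_at, train$values)
            soft <- make_soft_data(fit, sim$temp,
                                   exclude = train$locations)
            gk <- general_knowledge(mean(train$values), mod_f)
            bme_map(train, soft, gk, tgt, cf$n_hard_neighbors,
                    cf$n_soft_neighbors)$estimate
          },
          stop("unknown method: ", method))
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, scheme = scheme, method = method,
          rmse = rmse(estimate, truth),
          cr = correlation(estimate, truth),
          bias = bias(estimate, truth))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate an experiment table over replicate seeds
#'
#' @param results Output of \code{\link{sampling_density_experiment}}.
#' @return Data frame with mean and SD of RMSE and CR per scheme and method.
#' @export
aggregate_experiment <- function(results) {
  agg <- stats::aggregate(cbind(rmse, cr) ~ scheme + method, data = results,
                          FUN = mean)
  sds <- stats::aggregate(cbind(rmse, cr) ~ scheme + method, data = results,
                          FUN = stats::sd)
  names(agg)[3:4] <- c("rmse_mean", "cr_mean")
  agg$rmse_sd <- sds$rmse
  agg$cr_sd <- sds$cr
  agg[order(agg$method, agg$scheme), ]
}
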