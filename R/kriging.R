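#' Coregionalization structure for cokriging
#'
#' Bundles the primary and secondary auto-variogram models with the
#' cross-variogram model.  The linear-model-of-coregionalization screen
#' \eqn{|sill_{12}| \le \sqrt{sill_1 sill_2}} is checked and violation
#' raises a warning (the cokriging system may then be non-positive
#' definite).
#'
#' @param primary_model,secondary_model,cross_model
#'   \code{\link{variogram_model}} objects.
#' @return An object of class \code{coregionalization}.
#' @export
coregionalization <- function(primary_model, secondary_model, cross_model) {
  for (m in list(primary_model, secondary_model, cross_model))
    stopifnot(inherits(m, "variogram_model"))
  s1 <- primary_model$nugget + primary_model$psill
  s2 <- secondary_model$nugget + secondary_model$psill
  s12 <- cross_model$nugget + cross_model$psill
  if (abs(s12) > sqrt(s1 * s2) + 1e-12)
    warning(sprintf(
      "coregionalization check violated: |cross sill| = %.4g > sqrt(%.4g * %.4g)",
      abs(s12), s1, s2))
  structure(list(primary_model = primary_model,
                 secondary_model = secondary_model,
                 cross_model = cross_model),
            class = "coregionalization")
}

# nearest-neighbour indices with deterministic lexicographic (x, y) tie-break
nearest_idx <- function(locations, target, k) {
  d <- sqrt((locations[, 1] - target[1])^2 + (locations[, 2] - target[2])^2)
  ord <- order(d, locations[, 1], locations[, 2])
  ord[seq_len(min(k, length(d)))]
}

# nugget-augmented copy of a model: zero-nugget Gaussian structures make
# kriging systems catastrophically ill-conditioned at dense spacings, and a
# vanishing measurement-error nugget is the standard stabilization
augment_nugget <- function(model, eps) {
  if (eps <= 0) return(model)
  sill <- abs(model$nugget + model$psill)
  variogram_model(model$kind, model$nugget + eps * max(sill, 1e-12),
                  model$psill, model$range, model$fit_r2)
}

# escalating regularization levels tried until the system is well-conditioned
kkt_jitters <- c(0, 1e-8, 1e-6, 1e-4, 1e-3, 1e-2)

# a solution is accepted when the system is numerically sound AND the
# weights are physically plausible: sound kriging weights are O(1), while
# zero-nugget Gaussian systems can be solvable yet return weights of +-1e5
kkt_ok <- function(A, sol, nw) {
  rcond(A) > 1e-10 && max(abs(sol[seq_len(nw)])) < 10
}

#' Ordinary kriging
#'
#' Solves, per target, the ordinary kriging system in semivariance form over
#' the \code{n_neighbors} nearest data: weights \eqn{\lambda} satisfy
#' \eqn{\Gamma \lambda + \mu = \gamma_0} with the unbiasedness constraint
#' \eqn{\sum \lambda_i = 1}, and the estimate is
#' \eqn{Z^*(V_0) = \sum \lambda_i Z(V_i)}.  Since \eqn{\gamma(0) = 0}
#' the predictor is exact at data locations.
#'
#' @param hard A \code{\link{point_samples}} object (>= 1 point).
#' @param model A \code{\link{variogram_model}} for the attribute.
#' @param targets Two-column matrix of target locations.
#' @param n_neighbors Number of nearest data used per target (default 16).
#' @return A data frame with columns \code{x, y, estimate, variance}; the
#'   per-target weight vectors are attached as the list attribute
#'   \code{"weights"} (named by the indices of the contributing data).
#' @export
ordinary_kriging <- function(hard, model, targets, n_neighbors = 16) {
  stopifnot(inherits(hard, "point_samples"),
            inherits(model, "variogram_model"))
  targets <- as_locations(targets)
  n <- n_samples(hard)
  est <- var <- numeric(nrow(targets))
  wts <- vector("list", nrow(targets))
  for (t in seq_len(nrow(targets))) {
    tgt <- targets[t, ]
    idx <- nearest_idx(hard$locations, tgt, n_neighbors)
    m <- length(idx)
    loc <- hard$locations[idx, , drop = FALSE]
    hmat <- as.matrix(stats::dist(loc))
    d0 <- sqrt((loc[, 1] - tgt[1])^2 + (loc[, 2] - tgt[2])^2)
    sol <- NULL
    for (jit in kkt_jitters) {
      mj <- augment_nugget(model, jit)
      A <- rbind(cbind(matrix(vgm_gamma(mj, hmat), m, m), 1),
                 c(rep(1, m), 0))
      b <- c(vgm_gamma(mj, d0), 1)
      sj <- tryCatch(solve(A, b), error = function(e) NULL)
      if (!is.null(sj) && kkt_ok(A, sj, m)) { sol <- sj; break }
    }
    if (is.null(sol)) {
      dup <- which(hmat < 1e-12 & upper.tri(hmat), arr.ind = TRUE)
      if (nrow(dup) > 0)
        stop(sprintf("singular kriging system: duplicate locations (%g, %g)",
                     loc[dup[1, 1], 1], loc[dup[1, 1], 2]), call. = FALSE)
      stop("singular kriging system", call. = FALSE)
    }
    lambda <- sol[seq_len(m)]
    est[t] <- sum(lambda * hard$values[idx])
    var[t] <- sum(sol * b)
    names(lambda) <- idx
    wts[[t]] <- lambda
  }
  out <- data.frame(x = targets[, 1], y = targets[, 2],
                    estimate = est, variance = var)
  attr(out, "weights") <- wts
  out
}

#' Ordinary cokriging with a secondary attribute
#'
#' Solves the cokriging system in semivariance form over the nearest primary
#' and secondary neighbours.  The default constraint set is the traditional
#' unbiased one, \eqn{\sum \lambda_1 = 1} and \eqn{\sum \lambda_2 = 0};
#' \code{constraint = "unit-secondary"} instead imposes
#' \eqn{\sum \lambda_2 = 1}, a non-standard convention that biases the
#' estimate unless the secondary attribute is rescaled to the primary mean.
#'
#' Near-singular systems (e.g. a secondary attribute duplicating the primary
#' at the same locations) fall back to the minimum-norm pseudoinverse
#' solution, whose estimate coincides with ordinary kriging in that
#' degenerate case.
#'
#' @param primary Primary \code{\link{point_samples}} (the attribute being
#'   estimated).
#' @param secondary Secondary co-variable \code{\link{point_samples}}.
#' @param coreg A \code{\link{coregionalization}}.
#' @param targets Two-column matrix of target locations.
#' @param n_neighbors_primary,n_neighbors_secondary Neighbourhood sizes
#'   (default 16 each).
#' @param constraint "traditional" (secondary weights sum to 0) or
#'   "unit-secondary" (they sum to 1).
#' @return As \code{\link{ordinary_kriging}}; the \code{"weights"} attribute
#'   holds lists with elements \code{primary} and \code{secondary}.
#' @export
cokriging <- function(primary, secondary, coreg, targets,
                      n_neighbors_primary = 16, n_neighbors_secondary = 16,
                      constraint = c("traditional", "unit-secondary")) {
  stopifnot(inherits(primary, "point_samples"),
            inherits(secondary, "point_samples"),
            inherits(coreg, "coregionalization"))
  constraint <- match.arg(constraint)
  s2sum <- if (constraint == "traditional") 0 else 1
  targets <- as_locations(targets)
  est <- var <- numeric(nrow(targets))
  wts <- vector("list", nrow(targets))
  for (t in seq_len(nrow(targets))) {
    tgt <- targets[t, ]
    i1 <- nearest_idx(primary$locations, tgt, n_neighbors_primary)
    i2 <- nearest_idx(secondary$locations, tgt, n_neighbors_secondary)
    if (length(i2) < 1) stop("no secondary data available in neighbourhood")
    l1 <- primary$locations[i1, , drop = FALSE]
    l2 <- secondary$locations[i2, , drop = FALSE]
    n1 <- nrow(l1); n2 <- nrow(l2)
    dall <- as.matrix(stats::dist(rbind(l1, l2)))
    d1 <- sqrt((l1[, 1] - tgt[1])^2 + (l1[, 2] - tgt[2])^2)
    d2 <- sqrt((l2[, 1] - tgt[1])^2 + (l2[, 2] - tgt[2])^2)
    G12 <- matrix(vgm_gamma(coreg$cross_model,
                            dall[seq_len(n1), n1 + seq_len(n2), drop = FALSE]),
                  n1, n2)
    g20 <- vgm_gamma(coreg$cross_model, d2)
    sol <- NULL
    for (jit in kkt_jitters) {
      m1 <- augment_nugget(coreg$primary_model, jit)
      m2 <- augment_nugget(coreg$secondary_model, jit)
      G11 <- matrix(vgm_gamma(m1, dall[seq_len(n1), seq_len(n1)]), n1, n1)
      G22 <- matrix(vgm_gamma(m2, dall[n1 + seq_len(n2), n1 + seq_len(n2)]),
                    n2, n2)
      A <- rbind(
        cbind(G11, G12, 1, 0),
        cbind(t(G12), G22, 0, 1),
        c(rep(1, n1), rep(0, n2), 0, 0),
        c(rep(0, n1), rep(1, n2), 0, 0))
      b <- c(vgm_gamma(m1, d1), g20, 1, s2sum)
      sj <- tryCatch(solve(A, b), error = function(e) NULL)
      if (jit == 0 && is.null(sj)) {
        # exactly singular (e.g. secondary duplicating the primary): take
        # the minimum-norm solution, whose estimate matches ordinary kriging
        sol <- as.vector(MASS::ginv(A) %*% b)
        break
      }
      if (!is.null(sj) && kkt_ok(A, sj, n1 + n2)) { sol <- sj; break }
    }
    if (is.null(sol)) sol <- as.vector(MASS::ginv(A) %*% b)
    lam1 <- sol[seq_len(n1)]
    lam2 <- sol[n1 + seq_len(n2)]
    est[t] <- sum(lam1 * primary$values[i1]) + sum(lam2 * secondary$values[i2])
    var[t] <- sum(sol * b)
    names(lam1) <- i1; names(lam2) <- i2
    wts[[t]] <- list(primary = lam1, secondary = lam2)
  }
  out <- data.frame(x = targets[, 1], y = targets[, 2],
                    estimate = est, variance = var)
  attr(out, "weights") <- wts
  out
}
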