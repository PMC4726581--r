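#' Stationary field model
#'
#' Simulation truth for a Gaussian random field: a constant mean plus a
#' \code{\link{variogram_model}} describing spatial covariance through
#' \eqn{C(h) = (C_0 + C) - \gamma(h)}.
#'
#' @param mean Constant field mean (attribute units).
#' @param variogram A \code{\link{variogram_model}} with \code{psill >= 0}.
#' @return An object of class \code{field_model}.
#' @export
field_model <- function(mean, variogram) {
  stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean),
            inherits(variogram, "variogram_model"))
  if (variogram$psill < 0) stop("partial sill must be >= 0 for simulation")
  structure(list(mean = mean, variogram = variogram), class = "field_model")
}

# Cholesky factor (upper triangular) of the covariance matrix over grid
# nodes, with escalating diagonal jitter relative to the sill.
cov_chol <- function(spec, model) {
  xy <- grid_coords(spec)
  h <- as.matrix(stats::dist(xy))
  sill <- model$variogram$nugget + model$variogram$psill
  C <- matrix(vgm_cov(model$variogram, h), nrow(h), ncol(h))
  C <- (C + t(C)) / 2
  for (jit in c(1e-10, 1e-8, 1e-6)) {
    L <- tryCatch(chol(C + diag(jit * sill, nrow(C))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop(sprintf(paste0("covariance matrix not positive semi-definite after ",
                      "jitter (kind = %s, C0 = %g, C = %g, a = %g)"),
               model$variogram$kind, model$variogram$nugget,
               model$variogram$psill, model$variogram$range))
}

#' Simulate a stationary Gaussian random field on a grid
#'
#' One unconditional realization via dense Cholesky factorization of the
#' full covariance matrix (exact at the <= few-thousand-node grids used
#' here).  The same seed and parameters always reproduce the same field.
#'
#' @param spec A \code{\link{grid_spec}} (total nodes should stay below a
#'   few thousand for the dense-decomposition path).
#' @param model A \code{\link{field_model}}.
#' @param seed Integer RNG seed.
#' @param L Optional pre-computed Cholesky factor from an earlier call with
#'   the same \code{spec} and \code{model} (reused across replicates).
#' @return A \code{\link{grid_field}}; the factor used is attached as
#'   attribute \code{"chol"} for reuse.
#' @export
simulate_gaussian_field <- function(spec, model, seed, L = NULL) {
  stopifnot(inherits(spec, "grid_spec"), inherits(model, "field_model"))
  n <- spec$n_x * spec$n_y
  sill <- model$variogram$nugget + model$variogram$psill
  set.seed(as.integer(seed))
  if (sill <= 0) {
    v <- rep(model$mean, n)
  } else {
    if (is.null(L)) L <- cov_chol(spec, model)
    z <- stats::rnorm(n)
    v <- model$mean + as.vector(crossprod(L, z))
  }
  # grid_coords runs x fastest: value k maps to matrix cell (y, x)
  out <- grid_field(spec, matrix(v, nrow = spec$n_y, ncol = spec$n_x,
                                 byrow = TRUE))
  attr(out, "chol") <- L
  out
}

#' Derive a flux field from a temperature field
#'
#' Applies the exponential (Arrhenius-type) link
#' \eqn{R_s(s) = a e^{b T(s)} + \varepsilon(s)} where \eqn{\varepsilon} is a
#' zero-mean Gaussian random field with the given residual structure.
#' Negative fluxes are allowed by default (and counted in the attribute
#' \code{"n_negative"}); set \code{clip_negative = TRUE} to truncate at 0.
#'
#' @param temp A temperature \code{\link{grid_field}}.
#' @param a Rate coefficient (flux units).
#' @param b Temperature sensitivity (per degree C).
#' @param residual A \code{\link{field_model}} for the residual field (its
#'   mean is ignored; residuals are zero-mean).
#' @param seed Integer RNG seed for the residual field.
#' @param clip_negative Truncate negative fluxes at 0?
#' @param L Optional pre-computed residual Cholesky factor.
#' @return A flux \code{\link{grid_field}} on the temperature grid.
#' @export
simulate_flux_from_temperature <- function(temp, a, b, residual, seed,
                                           clip_negative = FALSE, L = NULL) {
  stopifnot(inherits(temp, "grid_field"), inherits(residual, "field_model"))
  if (!all(is.finite(temp$values))) stop("temperature field must be finite")
  expo <- b * temp$values
  if (any(expo > 700))
    stop("exp overflow in flux link: rescale a/b or temperature units")
  res0 <- field_model(0, residual$variogram)
  eps <- simulate_gaussian_field(temp$spec, res0, seed, L = L)
  v <- a * exp(expo) + eps$values
  nneg <- sum(v < 0)
  if (clip_negative) v[v < 0] <- 0
  out <- grid_field(temp$spec, v)
  attr(out, "n_negative") <- nneg
  attr(out, "chol") <- attr(eps, "chol")
  out
}

#' Nested symmetric sampling schemes on the 7 x 7 flux grid
#'
#' Deterministic point layouts with 9, 21, 37 or 49 sampling locations on an
#' odd x odd grid (the 7 x 7 design of the 35 m plot).  Points are spread
#' across the four quadrants plus the two dividing axes and the centre; the
#' schemes are nested (9 in 21 in 37 in 49) and each scheme is invariant
#' under 90-degree rotation of the plot.  49 is the full grid.
#'
#' @param spec A \code{\link{grid_spec}} with \code{n_x = n_y = 7}.
#' @param n_points One of 9, 21, 37, 49.
#' @return A two-column matrix of (x, y) locations, ordered by (y, x).
#' @export
sample_scheme <- function(spec, n_points) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spec$n_x != 7L || spec$n_y != 7L)
    stop("sampling schemes are defined on a 7 x 7 grid")
  if (!n_points %in% c(9, 21, 37, 49))
    stop("unsupported n_points: supported schemes are 9, 21, 37, 49")
  c0 <- 3L  # centre index (0-based)
  # nested order of per-quadrant cells (0-based indices within the 3x3
  # lower-left quadrant), chosen for even spread
  quad_order <- list(c(1, 1), c(0, 0), c(2, 2), c(2, 0), c(0, 2),
                     c(1, 0), c(0, 1), c(2, 1), c(1, 2))
  # nested order of axis-arm offsets from the centre (1..3): middle, outer, inner
  arm_order <- c(2L, 3L, 1L)
  counts <- list(`9` = c(quad = 1L, arm = 1L), `21` = c(quad = 3L, arm = 2L),
                 `37` = c(quad = 6L, arm = 3L), `49` = c(quad = 9L, arm = 3L))
  k <- counts[[as.character(n_points)]]
  rot <- function(ij) c(ij[2], 6L - ij[1])   # 90-degree rotation about centre
  pts <- list(c(c0, c0))
  for (d in arm_order[seq_len(k["arm"])]) {
    p <- c(c0, c0 - d)                       # south arm, distance d
    for (r in 1:4) { pts[[length(pts) + 1L]] <- p; p <- rot(p) }
  }
  for (q in quad_order[seq_len(k["quad"])]) {
    p <- c(q[1], q[2])                       # lower-left quadrant cell
    for (r in 1:4) { pts[[length(pts) + 1L]] <- p; p <- rot(p) }
  }
  idx <- unique(do.call(rbind, pts))
  stopifnot(nrow(idx) == n_points)
  xy <- cbind(x = spec$origin_x + idx[, 1] * spec$spacing,
              y = spec$origin_y + idx[, 2] * spec$spacing)
  xy[order(xy[, 2], xy[, 1]), , drop = FALSE]
}

#' Default Day-2-like synthetic study conditions
#'
#' The canonical configuration emulated by the synthetic generator: a
#' 35 m x 35 m grassland plot with a 35 x 35 temperature grid at 1 m
#' spacing, a 7 x 7 flux grid at 5 m spacing, an exponential
#' flux-temperature link with a = 0.1331 and b = 0.1370 per degree C,
#' a smooth temperature field (mean 27.18 C) and a spatially autocorrelated
#' flux residual.  Sills are sized so one realization shows a temperature SD
#' near 0.4 C and a flux SD near 0.51 flux units (spatial correlation
#' depresses the realized SD below the model sill), with a truth
#' nugget-to-sill share in the strong-dependence class (< 0.25).
#'
#' @return A named list with elements \code{temp_spec}, \code{flux_spec},
#'   \code{temp_model}, \code{link} (a, b) and \code{residual_model}.
#' @export
day2_defaults <- function() {
  list(
    temp_spec = grid_spec(0.5, 0.5, 35, 35, 1),
    flux_spec = grid_spec(2.5, 2.5, 7, 7, 5),
    temp_model = field_model(
      27.18, variogram_model("gaussian", nugget = 0.005, psill = 0.185,
                             range = 16)),
    link = c(a = 0.1331, b = 0.1370),
    residual_model = field_model(
      0, variogram_model("spherical", nugget = 0.05, psill = 0.13,
                         range = 18))
  )
}

#' Simulate one coupled temperature/flux realization
#'
#' Convenience wrapper producing the dense temperature field, the flux field
#' on the same grid, and the 49 hard flux samples at the 7 x 7 flux nodes.
#'
#' @param conf Configuration list as returned by \code{\link{day2_defaults}}.
#' @param seed Integer RNG seed (temperature uses \code{seed}; the flux
#'   residual uses \code{seed + 1000000} so consecutive replicate seeds draw
#'   disjoint streams).
#' @param L_temp,L_resid Optional cached Cholesky factors.
#' @return List with \code{temp} and \code{flux} grid fields, the hard-data
#'   \code{point_samples} \code{hard}, and the factors \code{L_temp},
#'   \code{L_resid} for reuse.
#' @export
simulate_plot <- function(conf = day2_defaults(), seed = 1,
                          L_temp = NULL, L_resid = NULL) {
  temp <- simulate_gaussian_field(conf$temp_spec, conf$temp_model, seed,
                                  L = L_temp)
  flux <- simulate_flux_from_temperature(temp, conf$link[["a"]],
                                         conf$link[["b"]],
                                         conf$residual_model,
                                         seed = seed + 1000000L, L = L_resid)
  hard_xy <- grid_coords(conf$flux_spec)
  hard <- point_samples(hard_xy, field_value_at(flux, hard_xy))
  list(temp = temp, flux = flux, hard = hard,
       L_temp = attr(temp, "chol"), L_resid = attr(flux, "chol"))
}
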