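#' Regular grid specification
#'
#' Defines a regular 2-D grid by its origin (coordinate of the first node),
#' node counts and spacing.  Node coordinates follow a cell-centre
#' convention: node \code{(i, j)} (0-based) sits at
#' \code{origin + index * spacing}.
#'
#' @param origin_x,origin_y Coordinates (metres) of the first node.
#' @param n_x,n_y Number of nodes in x and y (>= 1).
#' @param spacing Node spacing in metres (> 0).
#' @return An object of class \code{grid_spec}.
#' @examples
#' grid_spec(2.5, 2.5, 7, 7, 5)   # 7 x 7 flux grid on a 35 m plot
#' grid_spec(0.5, 0.5, 35, 35, 1) # 35 x 35 temperature grid
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, n_x, n_y, spacing) {
  stopifnot(is.numeric(n_x), is.numeric(n_y), is.numeric(spacing))
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_x < 1L || n_y < 1L) stop("n_x and n_y must be >= 1")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 n_x = n_x, n_y = n_y, spacing = spacing),
            class = "grid_spec")
}

#' Node coordinates of a grid
#'
#' @param spec A \code{\link{grid_spec}}.
#' @return A two-column matrix \code{(x, y)} with \code{n_x * n_y} rows,
#'   ordered row-major with y varying slowest (south-to-north).
#' @export
grid_coords <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  x <- spec$origin_x + (seq_len(spec$n_x) - 1L) * spec$spacing
  y <- spec$origin_y + (seq_len(spec$n_y) - 1L) * spec$spacing
  cbind(x = rep(x, times = spec$n_y), y = rep(y, each = spec$n_x))
}

#' Gridded attribute field
#'
#' Couples a \code{\link{grid_spec}} with a matrix of attribute values
#' (\code{n_y} rows by \code{n_x} columns; row 1 is the southernmost row).
#'
#' @param spec A \code{\link{grid_spec}}.
#' @param values Numeric matrix of dimension \code{n_y x n_x}, all finite
#'   (or NA for missing cells when reading files).
#' @return An object of class \code{grid_field}.
#' @export
grid_field <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$n_y || ncol(values) != spec$n_x)
    stop(sprintf("values must be %d x %d (n_y x n_x), got %d x %d",
                 spec$n_y, spec$n_x, nrow(values), ncol(values)))
  if (any(is.infinite(values)))
    stop("grid values must be finite")
  structure(list(spec = spec, values = values), class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  s <- x$spec
  cat(sprintf("grid_field: %d x %d nodes, spacing %g m, origin (%g, %g)\n",
              s$n_x, s$n_y, s$spacing, s$origin_x, s$origin_y))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
                mean(v), stats::sd(v), min(v), max(v)))
  invisible(x)
}

#' Flatten a grid field to point samples
#'
#' @param field A \code{\link{grid_field}}.
#' @return A \code{\link{point_samples}} object with one point per grid node
#'   (NA cells dropped).
#' @export
field_to_points <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  xy <- grid_coords(field$spec)
  # values matrix is (row = y index, col = x index); grid_coords runs x fastest
  v <- as.vector(t(field$values))
  keep <- !is.na(v)
  point_samples(xy[keep, , drop = FALSE], v[keep])
}

#' Look up grid values at arbitrary co-located points
#'
#' Values are read off the nearest grid node; an error is raised when a
#' requested point is further than \code{tol} from any node, since the
#' pipeline assumes exact co-location of the flux and temperature grids.
#'
#' @param field A \code{\link{grid_field}}.
#' @param locations Two-column matrix of (x, y) coordinates.
#' @param tol Co-location tolerance in metres.
#' @return Numeric vector of values at the requested points.
#' @export
field_value_at <- function(field, locations, tol = 1e-6) {
  stopifnot(inherits(field, "grid_field"))
  locations <- as_locations(locations)
  s <- field$spec
  ix <- round((locations[, 1] - s$origin_x) / s$spacing)
  iy <- round((locations[, 2] - s$origin_y) / s$spacing)
  dx <- abs(locations[, 1] - (s$origin_x + ix * s$spacing))
  dy <- abs(locations[, 2] - (s$origin_y + iy * s$spacing))
  bad <- dx > tol | dy > tol | ix < 0 | ix >= s$n_x | iy < 0 | iy >= s$n_y
  if (any(bad))
    stop(sprintf("point (%g, %g) is not co-located with a grid node",
                 locations[which(bad)[1], 1], locations[which(bad)[1], 2]))
  field$values[cbind(iy + 1L, ix + 1L)]
}

# coerce matrices / data frames / length-2 vectors to an (x, y) matrix
as_locations <- function(loc) {
  if (is.null(dim(loc))) {
    if (length(loc) != 2) stop("a location must be an (x, y) pair")
    loc <- matrix(loc, ncol = 2)
  }
  loc <- as.matrix(loc)[, 1:2, drop = FALSE]
  storage.mode(loc) <- "double"
  colnames(loc) <- c("x", "y")
  loc
}

#' Point samples of a single attribute
#'
#' The container for hard data: measurement locations plus values.
#' Duplicate locations are rejected (they make kriging systems singular).
#'
#' @param locations Two-column matrix (x, y) in metres.
#' @param values Numeric vector, one value per location, all finite.
#' @return An object of class \code{point_samples}.
#' @export
point_samples <- function(locations, values) {
  locations <- as_locations(locations)
  values <- as.numeric(values)
  if (nrow(locations) != length(values))
    stop("locations and values must have equal length")
  if (!all(is.finite(locations)) || !all(is.finite(values)))
    stop("locations and values must be finite")
  key <- paste(signif(locations[, 1], 12), signif(locations[, 2], 12))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate sample locations at (", d, ")")
  }
  structure(list(locations = locations, values = values),
            class = "point_samples")
}

#' @export
print.point_samples <- function(x, ...) {
  cat(sprintf("point_samples: n = %d, value mean %.4g, sd %.4g\n",
              length(x$values), mean(x$values),
              if (length(x$values) > 1) stats::sd(x$values) else NA))
  invisible(x)
}

#' Number of samples
#' @param samples A \code{\link{point_samples}} object.
#' @return Integer count.
#' @export
n_samples <- function(samples) length(samples$values)
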