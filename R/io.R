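#' Read point samples from CSV
#'
#' Expects a header \code{x,y,value}.  Malformed or non-finite rows and
#' duplicate locations are rejected with the offending line number.
#'
#' @param path Path to a CSV file.
#' @return A \code{\link{point_samples}} object.
#' @export
read_point_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "value")
  if (!all(need %in% names(df)))
    stop("point CSV must have header x,y,value; got: ",
         paste(names(df), collapse = ","))
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data line %d of %s",
                   col, bad[1], path))
    df[[col]] <- v
  }
  point_samples(cbind(df$x, df$y), df$value)
}

#' Write point samples to CSV
#'
#' @param samples A \code{\link{point_samples}} object.
#' @param path Output path.
#' @param digits Significant digits for numeric output.
#' @return The path, invisibly.
#' @export
write_point_csv <- function(samples, path, digits = 6) {
  stopifnot(inherits(samples, "point_samples"))
  df <- data.frame(x = signif(samples$locations[, 1], digits),
                   y = signif(samples$locations[, 2], digits),
                   value = signif(samples$values, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text raster dialect with header keys
#' \code{ncols, nrows, xllcorner, yllcorner, cellsize} and optional
#' \code{NODATA_value}, followed by \code{nrows} rows of values ordered
#' north-to-south.  Node coordinates are taken at cell centres.
#'
#' @param path Path to a .asc file.
#' @return A \code{\link{grid_field}} (NODATA cells become NA).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]]))
      stop("ASCII grid header missing key: ", key)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr)
    stop(sprintf("expected %d values, found %d", nc * nr, length(vals)))
  if (!is.null(hdr$nodata_value))
    vals[vals == hdr$nodata_value] <- NA
  # file rows run north-to-south; internal rows run south-to-north
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  spec <- grid_spec(hdr$xllcorner + hdr$cellsize / 2,
                    hdr$yllcorner + hdr$cellsize / 2,
                    nc, nr, hdr$cellsize)
  grid_field(spec, m)
}

#' Write an ESRI ASCII grid
#'
#' @param field A \code{\link{grid_field}}.
#' @param path Output path.
#' @param digits Significant digits for values.
#' @param nodata NODATA sentinel written for NA cells.
#' @return The path, invisibly.
#' @export
write_ascii_grid <- function(field, path, digits = 6, nodata = -9999) {
  stopifnot(inherits(field, "grid_field"))
  s <- field$spec
  hdr <- c(sprintf("ncols %d", s$n_x),
           sprintf("nrows %d", s$n_y),
           sprintf("xllcorner %.10g", s$origin_x - s$spacing / 2),
           sprintf("yllcorner %.10g", s$origin_y - s$spacing / 2),
           sprintf("cellsize %.10g", s$spacing),
           sprintf("NODATA_value %g", nodata))
  m <- field$values[s$n_y:1, , drop = FALSE]  # north-to-south rows
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
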