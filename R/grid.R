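#' Regular latitude-longitude grid
#'
#' Lightweight container for a single 2-D field on a cell-centered regular
#' lat/lon grid. Values are stored as a matrix with one row per latitude
#' (descending, north to south) and one column per longitude (ascending,
#' starting in the western hemisphere). `NA` marks masked cells.
#'
#' @param values numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lat numeric vector of cell-center latitudes, strictly descending.
#' @param lon numeric vector of cell-center longitudes, strictly ascending,
#'   in `[-180, 180)`.
#' @param name optional variable name carried through I/O.
#' @return an object of class `c4grid`.
#' @examples
#' g <- c4grid(matrix(1:8, 2, 4), lat = c(45, -45), lon = c(-135, -45, 45, 135))
#' grid_resolution(g)
#' @export
c4grid <- function(values, lat, lon, name = "value") {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("'values' must be numeric")
  storage.mode(values) <- "double"
  if (nrow(values) != length(lat))
    stop("grid shape mismatch: ", nrow(values), " rows but ", length(lat), " latitudes")
  if (ncol(values) != length(lon))
    stop("grid shape mismatch: ", ncol(values), " columns but ", length(lon), " longitudes")
  if (length(lat) > 1 && any(diff(lat) >= 0))
    stop("'lat' must be strictly descending (north to south)")
  if (length(lon) > 1 && any(diff(lon) <= 0))
    stop("'lon' must be strictly ascending")
  structure(list(values = unname(values), lat = as.numeric(lat),
                 lon = as.numeric(lon), name = as.character(name)[1]),
            class = "c4grid")
}

#' @export
print.c4grid <- function(x, ...) {
  cat(sprintf("<c4grid '%s'> %d x %d cells, %.3g deg, lat [%g, %g], lon [%g, %g]\n",
              x$name, length(x$lat), length(x$lon), grid_resolution(x),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  %d valid cells, range [%.4g, %.4g], mean %.4g\n",
                length(v), min(v), max(v), mean(v)))
  else cat("  all cells masked\n")
  invisible(x)
}

#' Grid cell size in degrees
#' @param g a [c4grid()].
#' @return cell size (degrees), assuming square cells.
#' @export
grid_resolution <- function(g) {
  stopifnot(inherits(g, "c4grid"))
  if (length(g$lon) > 1) return(g$lon[2] - g$lon[1])
  if (length(g$lat) > 1) return(g$lat[1] - g$lat[2])
  stop("cannot infer resolution from a 1x1 grid")
}

#' Check that two grids share cell geometry
#' @param a,b [c4grid()] objects.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; errors naming `what` on mismatch.
#' @export
stopifnot_same_grid <- function(a, b, what = "grid") {
  if (!isTRUE(all.equal(a$lat, b$lat)) || !isTRUE(all.equal(a$lon, b$lon)))
    stop("grid mismatch in field '", what, "': coordinates differ")
  invisible(TRUE)
}

#' Construct a grid like another, with new values
#' @param g template [c4grid()].
#' @param values replacement matrix (recycled scalar allowed).
#' @param name variable name for the result.
#' @return a [c4grid()] with `g`'s geometry.
#' @export
grid_like <- function(g, values, name = g$name) {
  if (length(values) == 1)
    values <- matrix(values, length(g$lat), length(g$lon))
  c4grid(values, g$lat, g$lon, name = name)
}

#' Build an empty global grid at a given resolution
#' @param res_deg cell size in degrees (must divide 180).
#' @param fill initial cell value (default `NA`).
#' @param name variable name.
#' @return a [c4grid()] spanning the globe.
#' @export
global_grid <- function(res_deg = 5, fill = NA_real_, name = "value") {
  if (180 %% res_deg != 0) stop("'res_deg' must divide 180")
  lat <- seq(90 - res_deg / 2, -90 + res_deg / 2, by = -res_deg)
  lon <- seq(-180 + res_deg / 2, 180 - res_deg / 2, by = res_deg)
  c4grid(matrix(fill, length(lat), length(lon)), lat, lon, name = name)
}

#' Write a grid to a plain-text raster file
#'
#' Serializes a [c4grid()] as a long-format CSV (`lat,lon,value`) preceded by
#' `#`-prefixed metadata lines. The format round-trips values bitwise (17
#' significant digits) and is the package's raster interchange format; no
#' binary raster library is required.
#'
#' @param g a [c4grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_grid()]
#' @export
write_grid <- function(g, path) {
  stopifnot(inherits(g, "c4grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# c4grid name=%s", g$name),
               sprintf("# nlat=%d nlon=%d", length(g$lat), length(g$lon))), con)
  df <- data.frame(lat = rep(g$lat, times = length(g$lon)),
                   lon = rep(g$lon, each = length(g$lat)),
                   value = as.vector(g$values))
  writeLines("lat,lon,value", con)
  writeLines(paste(format(df$lat, digits = 17, trim = TRUE, scientific = FALSE),
                   format(df$lon, digits = 17, trim = TRUE, scientific = FALSE),
                   ifelse(is.na(df$value), "NA",
                          formatC(df$value, digits = 17, format = "g")),
                   sep = ","), con)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#' @param path file path.
#' @return a [c4grid()].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  head1 <- readLines(path, n = 1)
  if (!grepl("^# c4grid", head1))
    stop("malformed raster file (missing c4grid header): ", path)
  name <- sub("^# c4grid name=", "", head1)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("lat", "lon", "value") %in% names(df)))
    stop("malformed raster file (need lat,lon,value columns): ", path)
  lat <- sort(unique(df$lat), decreasing = TRUE)
  lon <- sort(unique(df$lon))
  if (nrow(df) != length(lat) * length(lon))
    stop("malformed raster file: ", nrow(df), " rows, expected ",
         length(lat) * length(lon))
  m <- matrix(NA_real_, length(lat), length(lon))
  m[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  c4grid(m, lat, lon, name = name)
}

#' Area-weighted global mean of a grid
#' @param g a [c4grid()]; masked cells are skipped.
#' @param mask optional logical/0-1 [c4grid()] restricting the domain.
#' @return scalar weighted mean.
#' @export
grid_mean <- function(g, mask = NULL) {
  w <- matrix(cos(g$lat * pi / 180), length(g$lat), length(g$lon))
  keep <- !is.na(g$values)
  if (!is.null(mask)) {
    stopifnot_same_grid(g, mask, "mask")
    keep <- keep & !is.na(mask$values) & mask$values > 0
  }
  if (!any(keep)) stop("no valid cells under the mask")
  sum(g$values[keep] * w[keep]) / sum(w[keep])
}

#' Per-cell surface area on the sphere
#' @param g a [c4grid()].
#' @return matrix of cell areas in km^2 (Earth radius 6371 km).
#' @export
cell_area_km2 <- function(g) {
  res <- grid_resolution(g)
  r <- 6371
  lat_hi <- pmin(g$lat + res / 2, 90) * pi / 180
  lat_lo <- pmax(g$lat - res / 2, -90) * pi / 180
  band <- r^2 * (res * pi / 180) * (sin(lat_hi) - sin(lat_lo))
  matrix(band, length(g$lat), length(g$lon))
}

#' Aggregate a grid to a coarser resolution by block means
#'
#' Coarsens a ratio (or any) grid from its native resolution to an integer
#' multiple by averaging valid cells in each block; blocks with no valid cell
#' are masked. Used to bring model output to the scale of the observations
#' (e.g. 0.5 to 1 or 10 degrees); the ratio-coverage relationship is treated
#' as scale-independent.
#'
#' @param g a [c4grid()].
#' @param scale_deg target resolution, an integer multiple of the native one.
#' @return a [c4grid()] at `scale_deg`.
#' @export
aggregate_ratio <- function(g, scale_deg) {
  res <- grid_resolution(g)
  k <- scale_deg / res
  if (abs(k - round(k)) > 1e-8)
    stop("'scale_deg' (", scale_deg, ") is not a multiple of the native resolution (", res, ")")
  k <- as.integer(round(k))
  if (k == 1L) return(g)
  nlat <- length(g$lat) %/% k
  nlon <- length(g$lon) %/% k
  if (nlat * k != length(g$lat) || nlon * k != length(g$lon))
    stop("grid extent is not divisible into ", scale_deg, "-degree blocks")
  out <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    blk <- g$values[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k)]
    if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
  }
  lat <- colMeans(matrix(g$lat, k))
  lon <- colMeans(matrix(g$lon, k))
  c4grid(out, lat, lon, name = g$name)
}
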