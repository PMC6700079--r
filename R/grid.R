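#' Define a geographic raster grid
#'
#' A `grid_spec` describes a regular longitude/latitude raster in EPSG:4326.
#' Pixel values are stored in matrices whose first row is the *northernmost*
#' row of pixels; coordinates refer to pixel centers. Pixel counts are derived
#' by floor division of the extent by the resolution, so a grid survives a
#' write/read round trip unchanged.
#'
#' @param lon_min,lon_max,lat_min,lat_max Extent in decimal degrees.
#' @param resolution Pixel edge length in degrees (same in both axes).
#' @return An object of class `grid_spec` with elements `lon_min`, `lat_max`,
#'   `resolution`, `nrow`, `ncol` (plus the stated extent).
#' @examples
#' g <- grid_spec(17, 42, -35, 15, resolution = 0.83)
#' dim_grid(g)
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, resolution) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  if (!(lon_min < lon_max) || !(lat_min < lat_max))
    stop("grid extent must satisfy lon_min < lon_max and lat_min < lat_max")
  nc <- floor((lon_max - lon_min) / resolution + 1e-9)
  nr <- floor((lat_max - lat_min) / resolution + 1e-9)
  if (nr < 1L || nc < 1L) stop("degenerate grid: zero pixels in at least one axis")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 resolution = resolution, nrow = as.integer(nr),
                 ncol = as.integer(nc)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
dim_grid <- function(grid) c(grid$nrow, grid$ncol)

#' Pixel-center coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return A list with vectors `lat` (length `nrow`, north to south) and
#'   `lon` (length `ncol`, west to east), and matrices `lat_mat`, `lon_mat`
#'   of per-pixel centers.
#' @export
grid_centers <- function(grid) {
  lat <- grid$lat_max - (seq_len(grid$nrow) - 0.5) * grid$resolution
  lon <- grid$lon_min + (seq_len(grid$ncol) - 0.5) * grid$resolution
  list(lat = lat, lon = lon,
       lat_mat = matrix(lat, grid$nrow, grid$ncol),
       lon_mat = matrix(lon, grid$nrow, grid$ncol, byrow = TRUE))
}

grids_identical <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(unclass(a)[c("lon_min", "lat_max", "resolution")],
                   unclass(b)[c("lon_min", "lat_max", "resolution")],
                   tolerance = tol)) &&
    a$nrow == b$nrow && a$ncol == b$ncol
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d pixels at %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$nrow, x$ncol, x$resolution, x$lon_min, x$lon_max,
              x$lat_min, x$lat_max))
  invisible(x)
}

#' Pixel areas on the sphere
#'
#' Area of every pixel of a grid, treating pixels as spherical rectangles on a
#' sphere of radius 6371 km: area = R^2 * dlon * dlat * cos(lat_center), with
#' angles in radians.
#'
#' @param grid A `grid_spec`.
#' @return Matrix of areas in km^2, one entry per pixel.
#' @export
pixel_area_km2 <- function(grid) {
  d <- grid$resolution * pi / 180
  ctr <- grid_centers(grid)
  R <- 6371
  matrix(R^2 * d * d * cos(ctr$lat * pi / 180), grid$nrow, grid$ncol)
}

#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange. The header records the grid extent and a nodata
#' value; values are written row by row from the northernmost row, which is
#' also the in-memory matrix layout used throughout the package. GeoTIFF
#' rasters can be converted to this format with standard GIS tooling
#' (e.g. `gdal_translate -of AAIGrid`).
#'
#' @param values Numeric matrix (rows north to south).
#' @param grid A `grid_spec` consistent with `dim(values)`.
#' @param path File path.
#' @param nodata Value written for `NA` cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a list with `grid` and `values` (NA where nodata).
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  # south edge of the pixel block: rows hang from the north edge, so under
  # floor division the block's south edge can sit above lat_min
  south <- grid$lat_max - grid$nrow * grid$resolution
  hdr <- c(sprintf("ncols %d", grid$ncol),
           sprintf("nrows %d", grid$nrow),
           sprintf("xllcorner %.10f", grid$lon_min),
           sprintf("yllcorner %.10f", south),
           sprintf("cellsize %.10f", grid$resolution),
           sprintf("NODATA_value %g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 17), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  m <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr))
    m[i, ] <- as.numeric(strsplit(trimws(lines[6 + i]), "\\s+")[[1]])
  m[m == nodata] <- NA_real_
  g <- grid_spec(xll, xll + nc * cs, yll, yll + nr * cs, cs)
  list(grid = g, values = m)
}
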