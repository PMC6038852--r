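#' Burn-date raster
#'
#' A `burn_raster` is a georeferenced grid of per-pixel day-of-burn values on
#' a geographic (longitude/latitude) grid: `0` marks unburned pixels,
#' negative values mark unmapped/no-data pixels, and positive integers give
#' the day of burn (day-of-year, or days since 1 January of `year` when a
#' record spans several months). Row 1 is the northernmost row; `origin` is
#' the upper-left *corner* of the grid, so the center of pixel `(r, c)` lies
#' at `origin + pixel size * (c - 1/2, -(r - 1/2))`.
#'
#' @param values Integer matrix of burn dates (rows x cols; row 1 = north).
#' @param origin Numeric length-2, `c(lon, lat)` of the upper-left corner in
#'   degrees.
#' @param pixel_size Pixel size in degrees (square pixels), `> 0`.
#' @param year Calendar year the date axis is anchored to (day 1 = 1 Jan).
#' @param crs Character tag for the coordinate system; only geographic
#'   (`"EPSG:4326"`) grids are supported.
#'
#' @return An object of class `burn_raster`.
#' @export
#' @examples
#' r <- burn_raster(matrix(c(0, 10, 12, 0), 2, 2), origin = c(0, 1),
#'                  pixel_size = 0.01)
#' n_burned(r)
burn_raster <- function(values, origin, pixel_size, year = 2001L,
                        crs = "EPSG:4326") {
  stopifnot(is.matrix(values), nrow(values) > 0, ncol(values) > 0)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (degrees)")
  if (length(origin) != 2 || !is.numeric(origin))
    stop("`origin` must be c(lon, lat) of the upper-left corner")
  if (any(abs(values - round(values)) > 1e-9, na.rm = TRUE))
    stop("burn dates must be integers (day numbers)")
  storage.mode(values) <- "integer"
  values[is.na(values)] <- -1L
  structure(
    list(values = values, origin = as.numeric(origin),
         pixel_size = as.numeric(pixel_size), year = as.integer(year),
         crs = crs),
    class = "burn_raster"
  )
}

#' @export
print.burn_raster <- function(x, ...) {
  cat(sprintf(
    "<burn_raster> %d x %d pixels, %.6g deg/pixel, UL corner (%.4f, %.4f)\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$origin[1], x$origin[2]))
  cat(sprintf("  burned pixels: %d; date range: %s; year %d\n",
              n_burned(x),
              if (n_burned(x)) paste(range(x$values[x$values > 0]),
                                     collapse = "..") else "-",
              x$year))
  invisible(x)
}

#' Number of burned pixels in a raster
#' @param raster A [burn_raster()].
#' @return Integer count of pixels with a positive burn date.
#' @export
n_burned <- function(raster) sum(raster$values > 0L)

#' Longitude of pixel centers for given columns
#' @param raster A [burn_raster()].
#' @param col,row Column / row indices (1-based).
#' @return Numeric degrees.
#' @export
pixel_lon <- function(raster, col) raster$origin[1] + (col - 0.5) * raster$pixel_size

#' @rdname pixel_lon
#' @export
pixel_lat <- function(raster, row) raster$origin[2] - (row - 0.5) * raster$pixel_size

#' Geodesic area of pixels in each raster row
#'
#' Pixel areas on a spherical Earth (radius 6371 km): the area of the
#' spherical quadrangle spanned by the pixel's longitude and latitude bounds,
#' which varies with latitude as approximately `cos(lat)`.
#'
#' @param raster A [burn_raster()].
#' @return Numeric vector, one area in hectares per raster row.
#' @export
pixel_area_ha <- function(raster) {
  ps <- raster$pixel_size
  rows <- seq_len(nrow(raster$values))
  lat_top <- (raster$origin[2] - (rows - 1) * ps) * pi / 180
  lat_bot <- (raster$origin[2] - rows * ps) * pi / 180
  dlon <- ps * pi / 180
  area_m2 <- EARTH_RADIUS_M^2 * dlon * (sin(lat_top) - sin(lat_bot))
  area_m2 / 1e4
}

#' Read a burn-date raster from an ESRI ASCII grid
#'
#' Reads the plain-text `.asc` exchange format (header of `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, then one text row of
#' values per raster row, north first). No-data cells are mapped to the
#' unmapped code (-1). Only geographic (degree) grids are supported; a
#' `projection` header line declaring a projected CRS is rejected.
#'
#' @param path Path to the `.asc` file.
#' @param year Calendar year to anchor the date axis to.
#' @return A [burn_raster()].
#' @seealso [write_burn_raster()]
#' @export
read_burn_raster <- function(path, year = 2001L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- paste(parts[-1], collapse = " ")
    i <- i + 1
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  if (!is.null(hdr$projection) && !grepl("geographic|4326", hdr$projection,
                                         ignore.case = TRUE))
    stop("projected CRS not supported; reproject to geographic lon/lat first")
  if (!is.null(hdr$nbands) && as.integer(hdr$nbands) != 1L)
    stop("multi-band rasters are not supported")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- as.numeric(hdr$cellsize)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else as.numeric(hdr$nodata_value)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- -1
  burn_raster(m,
              origin = c(as.numeric(hdr$xllcorner),
                         as.numeric(hdr$yllcorner) + nr * cs),
              pixel_size = cs, year = year)
}

#' Write a burn-date raster as an ESRI ASCII grid
#'
#' @param raster A [burn_raster()].
#' @param path Output path (`.asc`).
#' @return `path`, invisibly.
#' @export
write_burn_raster <- function(raster, path) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2] - nr * raster$pixel_size),
    sprintf("cellsize %.10g", raster$pixel_size),
    "NODATA_value -1",
    "projection GEOGRAPHIC (EPSG:4326)"
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Crop a burn raster to a lon/lat extent
#'
#' Keeps the pixels whose centers fall inside the half-open extent
#' `[west, east) x [south, north)`. Used by the tiling scheme so that the
#' cropped grid stays aligned with the parent grid.
#'
#' @param raster A [burn_raster()].
#' @param extent Numeric length-4: `c(west, south, east, north)` degrees.
#' @return A [burn_raster()] covering the intersection (errors if empty).
#' @export
crop_burn_raster <- function(raster, extent) {
  stopifnot(length(extent) == 4)
  ps <- raster$pixel_size
  lon <- pixel_lon(raster, seq_len(ncol(raster$values)))
  lat <- pixel_lat(raster, seq_len(nrow(raster$values)))
  cols <- which(lon >= extent[1] & lon < extent[3])
  rows <- which(lat >= extent[2] & lat < extent[4])
  if (!length(cols) || !length(rows)) stop("crop extent contains no pixels")
  burn_raster(raster$values[rows, cols, drop = FALSE],
              origin = c(raster$origin[1] + (min(cols) - 1) * ps,
                         raster$origin[2] - (min(rows) - 1) * ps),
              pixel_size = ps, year = raster$year, crs = raster$crs)
}

#' Plot a burn-date raster
#'
#' @param object A [burn_raster()].
#' @param ... Unused.
#' @return A ggplot: burn date per pixel, unburned in grey.
#' @export
autoplot.burn_raster <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  df$burn_date <- object$values[cbind(df$row, df$col)]
  df$lon <- pixel_lon(object, df$col)
  df$lat <- pixel_lat(object, df$row)
  df$burn_date[df$burn_date <= 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$burn_date)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "burn date") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}
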