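#' Create a GeoRaster
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` is nodata.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @return A [GeoRaster-class] object.
#' @examples
#' r <- geoRaster(matrix(1:12, 3, 4), extent = c(0, 4, 0, 3))
#' res(r)
#' @export
geoRaster <- function(values, extent) {
  new("GeoRaster", values = as.matrix(values), extent = as.numeric(extent))
}

#' @describeIn geoRaster raster values as a matrix.
#' @param x,object a `GeoRaster`.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @export
setMethod("values", "GeoRaster", function(x) x@values)

#' @describeIn geoRaster extent as `c(xmin, xmax, ymin, ymax)`.
#' @export
setGeneric("extent", function(x) standardGeneric("extent"))

#' @export
setMethod("extent", "GeoRaster", function(x) x@extent)

#' @describeIn geoRaster cell size `c(dx, dy)` in degrees.
#' @export
setGeneric("res", function(x) standardGeneric("res"))

#' @export
setMethod("res", "GeoRaster", function(x) {
  e <- x@extent
  c(dx = (e[2] - e[1]) / ncol(x@values), dy = (e[4] - e[3]) / nrow(x@values))
})

#' @export
setMethod("dim", "GeoRaster", function(x) dim(x@values))

setMethod("show", "GeoRaster", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d cells, extent [%.4f, %.4f] x [%.4f, %.4f]\n",
              class(object), nrow(v), ncol(v),
              object@extent[1], object@extent[2], object@extent[3], object@extent[4]))
  fin <- v[!is.na(v)]
  if (length(fin)) cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
                               min(fin), max(fin), sum(is.na(v))))
  if (is(object, "CostSurface")) cat("  provenance:", object@provenance, "\n")
  invisible(object)
})

#' Longitudes and latitudes of all cell centers
#'
#' @param x a `GeoRaster`.
#' @return list with matrices `lon` and `lat`, same shape as `values(x)`.
#' @export
cellCenters <- function(x) {
  stopifnot(is(x, "GeoRaster"))
  e <- x@extent; r <- res(x); d <- dim(x@values)
  lon <- e[1] + (seq_len(d[2]) - 0.5) * r[1]
  lat <- e[4] - (seq_len(d[1]) - 0.5) * r[2]
  list(lon = matrix(lon, d[1], d[2], byrow = TRUE),
       lat = matrix(lat, d[1], d[2]))
}

#' Row/column of the cell containing each point
#'
#' Points on an internal cell boundary belong to the cell on the
#' south/west side of the boundary.
#'
#' @param x a `GeoRaster`.
#' @param lon,lat numeric point coordinates in degrees.
#' @return integer matrix with columns `row`, `col`; `NA` outside the extent.
#' @export
cellFromLonLat <- function(x, lon, lat) {
  e <- x@extent; r <- res(x); d <- dim(x@values)
  col <- ceiling((lon - e[1]) / r[1])
  col[!is.na(lon) & lon == e[1]] <- 1L
  row <- ceiling((e[4] - lat) / r[2])
  # a point exactly on a horizontal boundary goes to the row south of it
  on_edge <- !is.na(lat) &
    abs((e[4] - lat) / r[2] - round((e[4] - lat) / r[2])) < 1e-12 & lat < e[4] & lat > e[3]
  row[on_edge] <- round((e[4] - lat[on_edge]) / r[2]) + 1L
  row[!is.na(lat) & lat == e[3]] <- d[1]
  bad <- is.na(lon) | is.na(lat) | lon < e[1] | lon > e[2] | lat < e[3] | lat > e[4]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(pmin(pmax(row, 1L), d[1])) , col = as.integer(pmin(pmax(col, 1L), d[2])))
}

#' Extract raster values at points
#'
#' @inheritParams cellFromLonLat
#' @return numeric vector of cell values (`NA` outside extent or at nodata).
#' @export
extractAt <- function(x, lon, lat) {
  rc <- cellFromLonLat(x, lon, lat)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- x@values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Test grid alignment of rasters
#'
#' @param ... `GeoRaster` objects.
#' @return `TRUE` if all share shape and extent (to 1e-9 degrees).
#' @export
sameGrid <- function(...) {
  rs <- list(...)
  if (length(rs) == 1L && is.list(rs[[1]]) && !is(rs[[1]], "GeoRaster")) rs <- rs[[1]]
  ref <- rs[[1]]
  all(vapply(rs[-1], function(r) {
    identical(dim(r@values), dim(ref@values)) && max(abs(r@extent - ref@extent)) < 1e-9
  }, logical(1)))
}

#' Read an Esri ASCII grid
#'
#' Parses the plain-text AAIGrid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows from north
#' to south).
#'
#' @param path file path.
#' @return A [GeoRaster-class].
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1]) && !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed Esri ASCII grid '", path, "': header must define ", paste(need, collapse = ", "))
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("malformed Esri ASCII grid '", path, "': expected ", nc * nr, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  ext <- c(hdr$xllcorner, hdr$xllcorner + nc * hdr$cellsize,
           hdr$yllcorner, hdr$yllcorner + nr * hdr$cellsize)
  geoRaster(m, ext)
}

#' Write an Esri ASCII grid
#'
#' @param x a `GeoRaster`.
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(x, path, nodata = -9999) {
  stopifnot(is(x, "GeoRaster"))
  e <- x@extent; d <- dim(x@values); r <- res(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.12g", e[1]), sprintf("yllcorner %.12g", e[3]),
    sprintf("cellsize %.12g", r[1]), sprintf("NODATA_value %g", nodata)
  ), con)
  v <- x@values
  v[is.na(v)] <- nodata
  utils::write.table(format(v, trim = TRUE, digits = 15, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @return numeric distances in km.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}
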