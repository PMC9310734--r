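#' Generate a synthetic landscape with elevation, bioclim layers and epochs
#'
#' Elevation is a seeded spectral (1/f^`spectralExponent`) noise field whose
#' amplitude is controlled by `roughness` (0 = perfectly flat plateau,
#' 1 = full relief spanning 0-4000 m). Four bioclimatic layers are
#' deterministic functions of elevation and smooth spatial gradients plus
#' seeded noise: a temperature layer decreasing with elevation at a
#' 6.5 K/km lapse rate, a diurnal-range layer, an annual-precipitation
#' layer with a west-east gradient, and a precipitation-seasonality layer
#' with a south-north gradient. Past-epoch layers (mid-epoch and glacial)
#' shift the temperature-like layers additively and scale the
#' precipitation-like layers multiplicatively.
#'
#' The bundle also records the parameters of the true suitability function
#' (a Gaussian niche on the temperature and precipitation layers) used by
#' [trueSuitability()] and [generateOccurrences()] so downstream estimators
#' can be validated against known ground truth.
#'
#' @param nrow,ncol grid shape; both must be >= 8.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in degrees within
#'   +-180 / +-90.
#' @param roughness amplitude fraction in `[0, 1]` of the elevation relief.
#' @param seed integer; the same seed reproduces the bundle byte for byte.
#' @param spectralExponent spectral slope of the underlying 1/f noise.
#' @param epochOffsets list with `temp` (additive, degrees) and `precip`
#'   (multiplicative) offsets for the three epochs
#'   (current, mid, glacial).
#' @return A list of class `LandscapeBundle`: `elevation` ([GeoRaster-class]),
#'   `bioclim` (named list of 4 rasters), `epochs` (per-epoch bioclim lists),
#'   `truth` (suitability-function parameters), `seed`.
#' @export
generateLandscape <- function(nrow, ncol, extent = c(-79, -78, -1, -1 + nrow * (1 / ncol)),
                              roughness = 0.8, seed = 1,
                              spectralExponent = 2,
                              epochOffsets = list(temp = c(current = 0, mid = -1.5, glacial = -4.5),
                                                  precip = c(current = 1, mid = 0.95, glacial = 0.8))) {
  if (nrow < 8 || ncol < 8) stop("grid shape must be at least 8 x 8")
  if (roughness < 0 || roughness > 1) stop("roughness must be a fraction in [0, 1]")
  ext <- as.numeric(extent)
  if (length(ext) != 4 || ext[1] >= ext[2] || ext[3] >= ext[4] ||
      ext[1] < -180 || ext[2] > 180 || ext[3] < -90 || ext[4] > 90)
    stop("invalid extent: need xmin < xmax, ymin < ymax within +-180/+-90")

  withSeed(seed, {
    elevField <- spectralNoise(nrow, ncol, spectralExponent)
    noise <- replicate(4, matrix(stats::rnorm(nrow * ncol), nrow, ncol), simplify = FALSE)
  })
  # rescale field to [0,1]; amplitude set by roughness around a 2000 m plateau
  rng <- range(elevField)
  unit <- if (diff(rng) > 0) (elevField - rng[1]) / diff(rng) else elevField * 0 + 0.5
  elev <- 2000 + roughness * (unit - 0.5) * 4000

  xg <- matrix(seq(0, 1, length.out = ncol), nrow, ncol, byrow = TRUE)
  yg <- matrix(seq(0, 1, length.out = nrow), nrow, ncol)
  bio1 <- 30 - 6.5 * elev / 1000 + 0.3 * noise[[1]]          # annual mean temperature (deg C)
  bio2 <- 9 + 2 * xg + 0.5 * noise[[2]]                      # mean diurnal range (deg C)
  bio12 <- 800 + 1800 * xg + 0.25 * elev + 40 * noise[[3]]   # annual precipitation (mm)
  bio15 <- 35 + 40 * yg + 2 * noise[[4]]                     # precipitation seasonality (%)

  mk <- function(m) geoRaster(m, ext)
  bioclim <- list(bio1 = mk(bio1), bio2 = mk(bio2), bio12 = mk(bio12), bio15 = mk(bio15))

  epochs <- lapply(c(current = 1L, mid = 2L, glacial = 3L), function(i) {
    list(bio1 = mk(bio1 + epochOffsets$temp[i]),
         bio2 = mk(bio2),
         bio12 = mk(bio12 * epochOffsets$precip[i]),
         bio15 = mk(bio15))
  })

  truth <- list(
    suitability = list(optTemp = 22, widthTemp = 4, optPrecip = 2000, widthPrecip = 900),
    epochOffsets = epochOffsets, roughness = roughness,
    spectralExponent = spectralExponent
  )
  structure(list(elevation = mk(elev), bioclim = bioclim, epochs = epochs,
                 truth = truth, seed = seed),
            class = "LandscapeBundle")
}

# seeded 2D spectral noise with power spectrum 1/f^exponent
spectralNoise <- function(nrow, ncol, exponent) {
  white <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  fr <- c(0:floor(nrow / 2), -(ceiling(nrow / 2) - 1):-1) / nrow
  fc <- c(0:floor(ncol / 2), -(ceiling(ncol / 2) - 1):-1) / ncol
  f <- sqrt(outer(fr^2, fc^2, `+`))
  amp <- 1 / pmax(f, min(f[f > 0]))^(exponent / 2)
  amp[1, 1] <- 0
  Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (nrow * ncol)
}

#' True habitat suitability of a synthetic landscape
#'
#' Evaluates the generating Gaussian niche (recorded in `bundle$truth`) on
#' the bioclim layers of the requested epoch, giving the ground-truth
#' suitability raster in `[0, 1]`.
#'
#' @param bundle a `LandscapeBundle` from [generateLandscape()].
#' @param epoch `"current"`, `"mid"` or `"glacial"`.
#' @return A [GeoRaster-class] with values in `[0, 1]`.
#' @export
trueSuitability <- function(bundle, epoch = "current") {
  p <- bundle$truth$suitability
  bc <- bundle$epochs[[epoch]]
  s <- exp(-((bc$bio1@values - p$optTemp)^2 / (2 * p$widthTemp^2) +
             (bc$bio12@values - p$optPrecip)^2 / (2 * p$widthPrecip^2)))
  geoRaster(s, bundle$elevation@extent)
}

#' Sample occurrence points proportional to suitability
#'
#' Draws `n` cells with probability proportional to suitability and places
#' one point per draw at the cell center with uniform sub-cell jitter, so
#' every point falls inside a non-nodata cell.
#'
#' @param suitability [GeoRaster-class] with values in `[0, 1]`.
#' @param n number of points.
#' @param seed integer RNG seed.
#' @return data.frame with columns `lon`, `lat`.
#' @export
generateOccurrences <- function(suitability, n, seed = 1) {
  stopifnot(is(suitability, "GeoRaster"))
  v <- suitability@values
  p <- as.vector(v)
  p[is.na(p)] <- 0
  if (min(p) < -1e-12 || max(p) > 1 + 1e-12) stop("suitability values must lie in [0, 1]")
  if (sum(p) <= 0) stop("suitability is zero everywhere; cannot place occurrences")
  ctr <- cellCenters(suitability)
  r <- res(suitability)
  withSeed(seed, {
    cells <- sample.int(length(p), n, replace = TRUE, prob = p)
    jx <- stats::runif(n, -0.49, 0.49) * r[1]
    jy <- stats::runif(n, -0.49, 0.49) * r[2]
  })
  data.frame(lon = as.vector(ctr$lon)[cells] + jx,
             lat = as.vector(ctr$lat)[cells] + jy)
}

#' Place sampling localities on a landscape
#'
#' Chooses `k` locality centroids on non-nodata cells such that exactly one
#' pair lies closer than `nearPairKm` and all other pairs farther than
#' `minSepKm`, then scatters member individuals within 1 km of each
#' centroid. Centroids are recomputed as the arithmetic mean of member
#' coordinates.
#'
#' @param raster [GeoRaster-class] defining the landscape and nodata mask.
#' @param k number of localities (>= 3).
#' @param nIndPerLocality individuals per locality (scalar or length-`k`).
#' @param minSepKm minimum separation of all non-adjacent pairs (km).
#' @param nearPairKm the single close pair is placed below this distance (km).
#' @param seed integer RNG seed.
#' @param maxTries bounded rejection-sampling attempts before giving up.
#' @return A [LocalityTable-class].
#' @export
placeLocalities <- function(raster, k, nIndPerLocality = 13, minSepKm = 20,
                            nearPairKm = 12, seed = 1, maxTries = 500) {
  stopifnot(is(raster, "GeoRaster"))
  if (k < 3) stop("k must be at least 3")
  nInd <- rep_len(nIndPerLocality, k)
  ctr <- cellCenters(raster)
  ok <- !is.na(raster@values)
  lons <- ctr$lon[ok]; lats <- ctr$lat[ok]
  if (length(lons) < k) stop("not enough passable cells for ", k, " localities")

  withSeed(seed, {
    placed <- NULL
    for (try in seq_len(maxTries)) {
      idx <- sample.int(length(lons), k - 1)
      P <- cbind(lon = lons[idx], lat = lats[idx])
      D <- kmMatrix(P)
      if (any(D[lower.tri(D)] <= minSepKm)) next
      # near partner: passable cell within (2 km, nearPairKm) of locality 1,
      # farther than minSepKm from all others
      dAll <- haversineKm(lons, lats, P[1, 1], P[1, 2])
      cand <- which(dAll > 2 & dAll < nearPairKm * 0.95)
      if (!length(cand)) next
      keep <- cand[vapply(cand, function(j) {
        all(haversineKm(P[-1, 1], P[-1, 2], lons[j], lats[j]) > minSepKm)
      }, logical(1))]
      if (!length(keep)) next
      j <- keep[sample.int(length(keep), 1)]
      placed <- rbind(P, c(lons[j], lats[j]))
      break
    }
    if (is.null(placed))
      stop("could not satisfy the locality geometry (one pair < ", nearPairKm,
           " km, others > ", minSepKm, " km) after ", maxTries, " attempts")
    samples <- do.call(rbind, lapply(seq_len(k), function(i) {
      ang <- stats::runif(nInd[i], 0, 2 * pi)
      rad <- sqrt(stats::runif(nInd[i])) * 0.5   # <= 0.5 km radius => 1 km span
      dlat <- rad * sin(ang) / 111.195
      dlon <- rad * cos(ang) / (111.195 * cos(placed[i, 2] * pi / 180))
      data.frame(individual = sprintf("L%d_i%02d", i, seq_len(nInd[i])),
                 locality = sprintf("L%d", i),
                 lon = placed[i, 1] + dlon, lat = placed[i, 2] + dlat)
    }))
  })
  localityTable(samples)
}

# pairwise haversine km matrix for a 2-column lon/lat matrix
kmMatrix <- function(P) {
  n <- nrow(P)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d <- haversineKm(P[i, 1], P[i, 2], P[(i + 1):n, 1], P[(i + 1):n, 2])
    D[i, (i + 1):n] <- d; D[(i + 1):n, i] <- d
  }
  D
}

#' Build a LocalityTable from a sample sheet
#'
#' @param samples data.frame with columns `individual`, `locality`, `lon`, `lat`.
#' @return A [LocalityTable-class]; centroids are the arithmetic means of
#'   member coordinates.
#' @export
localityTable <- function(samples) {
  samples <- as.data.frame(samples)
  locs <- unique(samples$locality)
  centroids <- data.frame(
    locality = locs,
    lon = vapply(locs, function(l) mean(samples$lon[samples$locality == l]), numeric(1)),
    lat = vapply(locs, function(l) mean(samples$lat[samples$locality == l]), numeric(1)),
    row.names = NULL
  )
  new("LocalityTable", samples = samples, centroids = centroids)
}

#' @describeIn localityTable the per-individual sample sheet.
#' @param x a `LocalityTable`.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @export
setMethod("samples", "LocalityTable", function(x) x@samples)

#' @describeIn localityTable locality centroids (mean member coordinates).
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @export
setMethod("centroids", "LocalityTable", function(x) x@centroids)

setMethod("show", "LocalityTable", function(object) {
  cat(sprintf("LocalityTable: %d localities, %d individuals\n",
              nrow(object@centroids), nrow(object@samples)))
  print(object@centroids)
  invisible(object)
})

#' Write / read the sample sheet CSV (individual,locality,lon,lat)
#'
#' @param x a `LocalityTable`.
#' @param path file path.
#' @return `readSampleSheet` returns a [LocalityTable-class].
#' @export
writeSampleSheet <- function(x, path) {
  utils::write.csv(x@samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  localityTable(utils::read.csv(path, stringsAsFactors = FALSE))
}
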