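#' @import methods
NULL

#' Single-band georeferenced raster grid
#'
#' A minimal lon/lat raster: a numeric matrix whose first row is the
#' northernmost row, an extent in decimal degrees, and `NA` as the nodata
#' mask. Cell centers sit at `(west + (col - 0.5) * dx, north - (row - 0.5) * dy)`.
#'
#' @slot values numeric matrix (row 1 = north); `NA` marks nodata.
#' @slot extent numeric of length 4: `c(xmin, xmax, ymin, ymax)` in degrees.
#'
#' @export
setClass("GeoRaster",
  representation(values = "matrix", extent = "numeric"),
  validity = function(object) {
    msg <- character()
    e <- object@extent
    if (length(e) != 4L || anyNA(e)) msg <- c(msg, "extent must be 4 finite numbers (xmin, xmax, ymin, ymax)")
    else {
      if (e[2] <= e[1] || e[4] <= e[3]) msg <- c(msg, "extent must satisfy xmin < xmax and ymin < ymax")
      if (e[1] < -180 - 1e-9 || e[2] > 180 + 1e-9 || e[3] < -90 - 1e-9 || e[4] > 90 + 1e-9)
        msg <- c(msg, "extent must lie within [-180, 180] x [-90, 90]")
    }
    if (!is.numeric(object@values)) msg <- c(msg, "values must be a numeric matrix")
    if (nrow(object@values) < 1L || ncol(object@values) < 1L) msg <- c(msg, "raster must have at least one cell")
    if (length(msg) == 0L) {
      dx <- (e[2] - e[1]) / ncol(object@values)
      dy <- (e[4] - e[3]) / nrow(object@values)
      if (abs(dx - dy) > 0.01 * max(dx, dy)) msg <- c(msg, "cells must be square within 1% (dx ~ dy)")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Resistance cost surface
#'
#' A [GeoRaster] carrying non-negative resistance values plus provenance:
#' `"terrain-tier"` surfaces hold only the tier costs 1/2/4/8/16,
#' `"one-minus-suitability"` and `"one-minus-stability"` surfaces are
#' continuous in `[0, 1]`. Masked (`NA`) cells are impassable.
#'
#' @slot provenance character; one of `"terrain-tier"`,
#'   `"one-minus-suitability"`, `"one-minus-stability"`.
#' @slot tiers data.frame of tier thresholds (empty unless tiered).
#'
#' @export
setClass("CostSurface",
  contains = "GeoRaster",
  representation(provenance = "character", tiers = "data.frame"),
  validity = function(object) {
    v <- object@values[!is.na(object@values)]
    if (object@provenance == "terrain-tier") {
      if (!all(v %in% c(1, 2, 4, 8, 16))) return("tiered cost surface may contain only the costs 1, 2, 4, 8, 16")
    } else if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12)) {
      return("continuous cost surface values must lie in [0, 1]")
    }
    TRUE
  }
)

#' Genotype likelihoods at biallelic sites
#'
#' Per-individual, per-site likelihoods of carrying 0, 1 or 2 copies of the
#' derived (unfolded polarization) or minor (folded) allele, stored in
#' beagle-normalized space: each individual/site triple is scaled so its
#' maximum is 1; a triple of three equal values marks missing data.
#'
#' @slot gl numeric array `sites x individuals x 3`.
#' @slot sites character site identifiers.
#' @slot alleles character matrix `sites x 2` (major/ancestral, minor/derived
#'   allele codes).
#' @slot individuals character labels.
#' @slot polarization `"unfolded"` or `"folded"`.
#'
#' @export
setClass("GenotypeLikelihoodSet",
  representation(gl = "array", sites = "character", alleles = "matrix",
                 individuals = "character", polarization = "character"),
  validity = function(object) {
    d <- dim(object@gl)
    if (length(d) != 3L || d[3] != 3L) return("gl must be a sites x individuals x 3 array")
    if (d[1] < 1L) return("at least one site is required")
    if (length(object@sites) != d[1]) return("length(sites) must equal dim(gl)[1]")
    if (length(object@individuals) != d[2]) return("length(individuals) must equal dim(gl)[2]")
    if (!object@polarization %in% c("unfolded", "folded")) return("polarization must be 'unfolded' or 'folded'")
    rng <- range(object@gl, na.rm = TRUE)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-9) return("likelihoods must be normalized to [0, 1]")
    TRUE
  }
)

#' Site frequency spectrum
#'
#' Expected counts of sites per derived-allele (unfolded; classes
#' `0..2N`) or minor-allele (folded; classes `0..N`) count class for a
#' sample of `N` diploids.
#'
#' @slot counts numeric vector of expected site counts per class.
#' @slot nSites total number of sites the spectrum was estimated from.
#' @slot folded logical.
#' @slot converged logical; `FALSE` if the EM hit its iteration cap.
#' @slot loglik numeric trace of EM log-likelihoods (may be empty).
#'
#' @export
setClass("SiteFrequencySpectrum",
  representation(counts = "numeric", nSites = "numeric", folded = "logical",
                 converged = "logical", loglik = "numeric"),
  validity = function(object) {
    if (any(object@counts < -1e-9)) return("SFS counts must be non-negative")
    if (abs(sum(object@counts) - object@nSites) > 1e-6 * max(1, object@nSites))
      return("sum(counts) must equal nSites within 1e-6 relative tolerance")
    TRUE
  }
)

#' Labelled symmetric distance matrix
#'
#' @slot values numeric symmetric matrix with zero diagonal and dimnames.
#' @slot kind character tag: one of `"IBD"`, `"IBR_Terrain"`,
#'   `"IBR_Habitat"`, `"IBI"`, `"IBE"`, `"FST"`, `"genetic"`.
#'
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", kind = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (is.null(rownames(v)) || is.null(colnames(v))) return("matrix must carry row and column labels")
    if (!identical(rownames(v), colnames(v))) return("row and column labels must match")
    fin <- is.finite(v)
    if (max(abs(v[fin] - t(v)[fin])) > 1e-12) return("matrix must be symmetric to 1e-12")
    if (any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
    TRUE
  }
)

#' Sampling localities and their member individuals
#'
#' @slot samples data.frame with columns `individual`, `locality`, `lon`, `lat`.
#' @slot centroids data.frame with columns `locality`, `lon`, `lat`; each
#'   centroid is the arithmetic mean of its members' coordinates.
#'
#' @export
setClass("LocalityTable",
  representation(samples = "data.frame", centroids = "data.frame"),
  validity = function(object) {
    s <- object@samples; ctr <- object@centroids
    need <- c("individual", "locality", "lon", "lat")
    if (!all(need %in% names(s))) return("samples needs columns individual, locality, lon, lat")
    if (!all(c("locality", "lon", "lat") %in% names(ctr))) return("centroids needs columns locality, lon, lat")
    if (anyDuplicated(s$individual)) return("every individual must belong to exactly one locality")
    for (k in seq_len(nrow(ctr))) {
      m <- s[s$locality == ctr$locality[k], ]
      if (nrow(m) == 0L) return(sprintf("locality '%s' has no members", ctr$locality[k]))
      if (abs(mean(m$lon) - ctr$lon[k]) > 1e-9 || abs(mean(m$lat) - ctr$lat[k]) > 1e-9)
        return(sprintf("centroid of '%s' must equal the mean of member coordinates", ctr$locality[k]))
    }
    TRUE
  }
)

#' Penalized presence/background suitability model
#'
#' An L1-penalized logistic classifier on standardized linear and quadratic
#' terms of the bioclimatic layers, fitted over replicate train/validation
#' splits; suitability is the averaged classifier probability.
#'
#' @slot coefficients numeric matrix, one row per replicate fit
#'   (intercept + 2 features per layer).
#' @slot layerNames character names of the training layers, in order.
#' @slot center,scale numeric feature standardization constants.
#' @slot lambda numeric L1 regularization weight.
#' @slot meta list of training metadata (n presences, n background, seed,
#'   per-replicate training AUC).
#'
#' @export
setClass("SuitabilityModel",
  representation(coefficients = "matrix", layerNames = "character",
                 center = "numeric", scale = "numeric", lambda = "numeric",
                 meta = "list"),
  validity = function(object) {
    if (ncol(object@coefficients) != 1L + 2L * length(object@layerNames))
      return("coefficient columns must be intercept + linear and quadratic term per layer")
    TRUE
  }
)

#' Generalized dissimilarity model
#'
#' Dissimilarity `1 - exp(-eta)` with `eta = intercept + sum of non-negative
#' I-spline transforms` of predictor distances.
#'
#' @slot intercept non-negative numeric.
#' @slot coefficients numeric matrix `nSplines x nPredictors`, all entries >= 0.
#' @slot knots list of per-predictor knot vectors.
#' @slot devianceExplained percent of the null binomial deviance explained.
#' @slot importance data.frame of per-predictor importance and permutation p
#'   (zero rows when elimination was not run).
#' @slot history list of per-round elimination tables.
#' @slot converged logical.
#'
#' @export
setClass("GDMModel",
  representation(intercept = "numeric", coefficients = "matrix", knots = "list",
                 devianceExplained = "numeric", importance = "data.frame",
                 history = "list", converged = "logical"),
  validity = function(object) {
    if (object@intercept < -1e-12) return("intercept must be non-negative")
    if (any(object@coefficients < -1e-12)) return("I-spline coefficients must be non-negative")
    if (is.finite(object@devianceExplained) &&
        (object@devianceExplained < -1e-6 || object@devianceExplained > 100 + 1e-6))
      return("devianceExplained must lie in [0, 100]")
    TRUE
  }
)
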