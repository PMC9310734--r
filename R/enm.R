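# standardized linear + quadratic feature matrix from 4-layer bioclim values
# (columns: one linear and one quadratic term per layer)
enmFeatures <- function(X, center, scale) {
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  cbind(Z, Z^2)
}

#' Fit a presence/background habitat suitability model
#'
#' Surrogate for maximum-entropy niche modelling: an L1-penalized logistic
#' presence/background classifier on standardized linear and quadratic
#' terms of the bioclimatic layers (penalized GLMs are the established
#' equivalent of the maximum-entropy formulation). Background points are
#' sampled from non-presence, non-nodata cells; the model is fitted over
#' `reps` random train/validation splits and the final suitability is the
#' mean of the replicate probabilities.
#'
#' @param presences data.frame with `lon`, `lat` (>= 20 rows).
#' @param bioclim named list of aligned [GeoRaster-class] layers.
#' @param nBackground number of pseudo-absence points.
#' @param trainFrac fraction of presences used for training per replicate.
#' @param reps number of replicate fits.
#' @param lambda L1 regularization weight.
#' @param maxit optimizer iteration cap per fit.
#' @param seed integer RNG seed; refitting with the same data and seed
#'   reproduces the coefficients.
#' @return A [SuitabilityModel-class]; per-replicate validation AUC is in
#'   `meta(model)$validationAUC`.
#' @export
fitSuitability <- function(presences, bioclim, nBackground = 10000, trainFrac = 0.8,
                           reps = 10, lambda = 0.001, maxit = 500, seed = 1) {
  if (nrow(presences) < 20) stop("need at least 20 presence points")
  if (!sameGrid(bioclim)) stop("bioclim layers must share one grid")
  layerNames <- names(bioclim)
  ref <- bioclim[[1]]

  presCells <- cellFromLonLat(ref, presences$lon, presences$lat)
  presIdx <- presCells[, 1] + (presCells[, 2] - 1L) * nrow(ref@values)
  ok <- !is.na(ref@values)
  bgPool <- setdiff(which(ok), unique(presIdx))
  if (length(bgPool) < 2) stop("no background cells available")
  dropped <- character(0)

  Xall <- vapply(bioclim, function(r) as.vector(r@values), numeric(length(ref@values)))
  withSeed(seed, {
    bgIdx <- sample(bgPool, min(nBackground, length(bgPool)),
                    replace = length(bgPool) < nBackground)
    splitSeeds <- sample.int(.Machine$integer.max - 1L, reps)
  })
  Xp <- Xall[presIdx, , drop = FALSE]
  Xb <- Xall[bgIdx, , drop = FALSE]
  X <- rbind(Xp, Xb)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xb)))

  vr <- apply(X, 2, stats::sd)
  if (any(vr == 0)) {
    dropped <- layerNames[vr == 0]
    warning("dropping zero-variance layers: ", paste(dropped, collapse = ", "))
    keepL <- vr > 0
    if (!any(keepL)) stop("all layers have zero variance")
    X <- X[, keepL, drop = FALSE]; Xall <- Xall[, keepL, drop = FALSE]
    layerNames <- layerNames[keepL]; vr <- vr[keepL]
  }
  center <- colMeans(X); scale <- vr
  FX <- enmFeatures(X, center, scale)

  nP <- nrow(Xp)
  coefs <- matrix(0, reps, 1 + ncol(FX))
  vAUC <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- withSeed(splitSeeds[r], sample.int(nP, max(2, round(trainFrac * nP))))
    rows <- c(tr, nP + seq_len(length(bgIdx)))
    # a short decreasing lambda path gives glmnet warm starts; the last
    # (target) lambda is the regularization weight actually used
    path <- exp(seq(log(max(1, lambda * 100)), log(lambda), length.out = 15))
    fit <- glmnet::glmnet(FX[rows, , drop = FALSE], y[rows], family = "binomial",
                          alpha = 1, lambda = path, maxit = maxit,
                          standardize = FALSE)
    coefs[r, ] <- as.numeric(stats::coef(fit, s = min(fit$lambda)))
    te <- setdiff(seq_len(nP), tr)
    if (length(te) >= 1) {
      eta <- cbind(1, FX) %*% coefs[r, ]
      pr <- 1 / (1 + exp(-eta))
      vAUC[r] <- aucScore(pr[te], pr[nP + seq_len(length(bgIdx))])
    }
  }
  new("SuitabilityModel", coefficients = coefs, layerNames = layerNames,
      center = center, scale = scale, lambda = lambda,
      meta = list(nPresences = nP, nBackground = length(bgIdx), seed = seed,
                  trainFrac = trainFrac, validationAUC = vAUC,
                  droppedLayers = dropped,
                  backgroundIdx = bgIdx))
}

#' @describeIn fitSuitability training metadata list.
#' @param x a `SuitabilityModel`.
#' @export
setGeneric("meta", function(x) standardGeneric("meta"))

#' @export
setMethod("meta", "SuitabilityModel", function(x) x@meta)

setMethod("show", "SuitabilityModel", function(object) {
  cat(sprintf("SuitabilityModel: %d replicate fits on layers %s (lambda = %g)\n",
              nrow(object@coefficients), paste(object@layerNames, collapse = ", "),
              object@lambda))
  cat(sprintf("  mean validation AUC: %.3f\n", mean(object@meta$validationAUC)))
  invisible(object)
})

#' Predict habitat suitability on a raster stack
#'
#' Evaluates every replicate classifier on the (possibly past-epoch) layers
#' and averages the probabilities; nodata propagates.
#'
#' @param model a [SuitabilityModel-class].
#' @param bioclim named list of aligned [GeoRaster-class] layers covering the
#'   training layer names.
#' @return A [GeoRaster-class] of suitability in `[0, 1]`.
#' @export
predictSuitability <- function(model, bioclim) {
  stopifnot(is(model, "SuitabilityModel"))
  if (!all(model@layerNames %in% names(bioclim)))
    stop("missing layers: ", paste(setdiff(model@layerNames, names(bioclim)), collapse = ", "))
  bioclim <- bioclim[model@layerNames]
  if (!sameGrid(bioclim)) stop("bioclim layers must share one grid")
  ref <- bioclim[[1]]
  X <- vapply(bioclim, function(r) as.vector(r@values), numeric(length(ref@values)))
  FX <- cbind(1, enmFeatures(X, model@center, model@scale))
  eta <- FX %*% t(model@coefficients)
  pr <- rowMeans(1 / (1 + exp(-eta)))
  geoRaster(matrix(pr, nrow(ref@values), ncol(ref@values)), ref@extent)
}

#' Ranking AUC with tied pairs counted one half
#'
#' @param pos,neg score vectors for presences and background.
#' @return the Mann-Whitney AUC in `[0, 1]`.
#' @export
aucScore <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0 || n2 == 0) stop("both score sets must be non-empty")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Maximum true skill statistic over score thresholds
#'
#' `TSS = max_t (sensitivity(t) + specificity(t) - 1)` over all observed
#' score thresholds (prediction positive when score >= t).
#'
#' @inheritParams aucScore
#' @return list with `tss` and the maximizing `threshold`.
#' @export
tssScore <- function(pos, neg) {
  th <- sort(unique(c(pos, neg)))
  tss <- vapply(th, function(t) mean(pos >= t) + mean(neg < t) - 1, numeric(1))
  best <- which.max(tss)
  list(tss = tss[best], threshold = th[best])
}

#' Evaluate a suitability model on held-out presences
#'
#' Scores test presences and background locations with the averaged model
#' and reports AUC (Mann-Whitney rank statistic, ties counted one half) and
#' the maximum TSS with its threshold.
#'
#' @param model a [SuitabilityModel-class].
#' @param testPresences data.frame `lon`, `lat` (>= 5 rows).
#' @param background data.frame `lon`, `lat` of background points.
#' @param bioclim named list of layers to score on.
#' @return list of class `EvaluationReport`: `auc`, `tss`, `threshold`,
#'   `nTest`, `nBackground`.
#' @export
evaluateModel <- function(model, testPresences, background, bioclim) {
  if (nrow(testPresences) < 5) stop("need at least 5 test presences")
  if (nrow(background) == 0) stop("need background points")
  suit <- predictSuitability(model, bioclim)
  pos <- extractAt(suit, testPresences$lon, testPresences$lat)
  neg <- extractAt(suit, background$lon, background$lat)
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  t <- tssScore(pos, neg)
  structure(list(auc = aucScore(pos, neg), tss = t$tss, threshold = t$threshold,
                 nTest = length(pos), nBackground = length(neg)),
            class = "EvaluationReport")
}

#' Fourfold spatial-block cross-validation folds
#'
#' Partitions the bounding extent into a 2 x 2 grid of contiguous
#' rectangular blocks and assigns each point the block containing it; a
#' point exactly on an internal boundary goes to the block on its
#' south/west side. Fold roles rotate: fold k is the test set of rotation k.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`; defaults to the point
#'   bounding box.
#' @param k number of folds; the 2 x 2 spatial split fixes `k = 4`.
#' @param seed integer seed controlling the random block-to-fold labelling.
#' @return list with `fold` (integer per point), `folds` (list of
#'   `train`/`test` index vectors); empty folds are dropped with a warning.
#' @export
spatialBlockCV <- function(points, extent = NULL, k = 4, seed = 1) {
  if (k != 4) stop("the spatial-block design uses a fixed 2 x 2 split (k = 4)")
  if (is.null(extent)) extent <- c(range(points$lon), range(points$lat))
  midx <- (extent[1] + extent[2]) / 2
  midy <- (extent[3] + extent[4]) / 2
  east <- points$lon > midx      # on-boundary points stay west
  north <- points$lat > midy     # on-boundary points stay south
  block <- 1L + east + 2L * north
  if (length(unique(block)) < 2) stop("presences must spread over at least 2 blocks")
  lab <- withSeed(seed, sample.int(4))
  fold <- lab[block]
  folds <- lapply(sort(unique(fold)), function(f)
    list(test = which(fold == f), train = which(fold != f)))
  empty <- setdiff(1:4, unique(fold))
  if (length(empty)) warning("folds without presences skipped: ", paste(empty, collapse = ", "))
  list(fold = fold, folds = folds)
}

#' Multivariate environmental similarity surface
#'
#' Per cell and variable, with `f` the percentage of reference values
#' strictly below the cell value `v`:
#' `f = 0` gives `100 (v - min) / (max - min)` (negative when extrapolating
#' below the reference range), `0 < f <= 50` gives `2 f`,
#' `50 < f < 100` gives `2 (100 - f)`, and `f = 100` gives
#' `100 (max - v) / (max - min)`. The cell's MESS is the minimum over
#' variables; negative values flag conditions outside the reference range.
#'
#' @param reference data.frame / matrix of reference (training) values, one
#'   column per variable (>= 2 rows).
#' @param target named list of [GeoRaster-class] layers matching the
#'   reference columns.
#' @return A [GeoRaster-class] of MESS values.
#' @export
messSurface <- function(reference, target) {
  reference <- as.data.frame(reference)
  vars <- intersect(names(reference), names(target))
  if (length(vars) == 0) stop("reference columns and target layers do not match")
  if (!sameGrid(target[vars])) stop("target layers must share one grid")
  ref1 <- target[[vars[1]]]
  sim <- NULL
  for (v in vars) {
    rv <- sort(reference[[v]])
    if (length(rv) < 2) stop("need at least 2 reference values per variable")
    mn <- rv[1]; mx <- rv[length(rv)]
    if (mx == mn) { warning("variable '", v, "' is constant in the reference; skipped"); next }
    x <- as.vector(target[[v]]@values)
    f <- 100 * findInterval(x, rv, left.open = TRUE) / length(rv)  # % strictly below
    s <- ifelse(f == 0, 100 * (x - mn) / (mx - mn),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                         100 * (mx - x) / (mx - mn))))
    sim <- if (is.null(sim)) s else pmin(sim, s)
  }
  if (is.null(sim)) stop("all variables were constant; MESS undefined")
  geoRaster(matrix(sim, nrow(ref1@values), ncol(ref1@values)), ref1@extent)
}

#' Habitat stability across epochs
#'
#' Cellwise arithmetic mean of suitability rasters for the three time
#' slices; a cell fully suitable at all times scores 1, fully unsuitable 0.
#'
#' @param suitabilityByEpoch list of aligned [GeoRaster-class] suitability
#'   rasters (one per epoch).
#' @return A [GeoRaster-class] stability raster in `[0, 1]`.
#' @export
habitatStability <- function(suitabilityByEpoch) {
  if (!sameGrid(suitabilityByEpoch)) stop("epoch rasters are misaligned")
  m <- Reduce(`+`, lapply(suitabilityByEpoch, function(r) r@values)) / length(suitabilityByEpoch)
  geoRaster(m, suitabilityByEpoch[[1]]@extent)
}
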