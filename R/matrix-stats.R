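#' Geographic distance matrix
#'
#' Great-circle (haversine, R = 6371 km) distances between locality
#' centroids or between individuals. With `logTransform = TRUE` distances
#' are natural-log transformed after replacing zero off-diagonal distances
#' by half the smallest positive distance (with a warning naming the
#' substitution).
#'
#' @param localities a [LocalityTable-class], or a data.frame with `lon`,
#'   `lat` and a label column (`locality` or `individual`).
#' @param level `"locality"` (centroids) or `"individual"`.
#' @param logTransform log-transform the distances.
#' @return A [DistanceMatrix-class] of kind `"IBD"` (km, or log km).
#' @export
geographicDistanceMatrix <- function(localities, level = c("locality", "individual"),
                                     logTransform = FALSE) {
  level <- match.arg(level)
  if (is(localities, "LocalityTable")) {
    df <- if (level == "locality") localities@centroids else localities@samples
    labels <- if (level == "locality") df$locality else df$individual
  } else {
    df <- as.data.frame(localities)
    pref <- if (level == "individual") c("individual", "locality", "label")
            else c("locality", "individual", "label")
    labels <- df[[intersect(pref, names(df))[1]]]
  }
  if (nrow(df) < 2) stop("need at least 2 points")
  D <- kmMatrix(cbind(df$lon, df$lat))
  dimnames(D) <- list(labels, labels)
  if (logTransform) {
    off <- D[lower.tri(D)]
    if (any(off == 0)) {
      sub <- min(off[off > 0]) / 2
      warning("zero distances replaced by ", signif(sub, 4), " km before log transform")
      D[D == 0] <- sub
    }
    D <- log(D)
    diag(D) <- 0
  }
  distanceMatrix(D, kind = "IBD")
}

#' Environmental distance matrix
#'
#' Euclidean distances between localities in the raw (unstandardized)
#' space of the bioclimatic variables.
#'
#' @param env data.frame or matrix of per-locality variable values; row
#'   names are locality labels.
#' @return A [DistanceMatrix-class] of kind `"IBE"`.
#' @export
environmentalDistanceMatrix <- function(env) {
  env <- as.matrix(env)
  if (anyNA(env)) stop("missing environmental values for: ",
                       paste(rownames(env)[rowSums(is.na(env)) > 0], collapse = ", "))
  D <- as.matrix(stats::dist(env))
  distanceMatrix(D, kind = "IBE")
}

#' Normalize an FST matrix for isolation-by-distance regression
#'
#' Elementwise `x / (1 - x)`, the linearizing transform of FST under
#' isolation by distance; the zero diagonal is preserved.
#'
#' @param fst a [DistanceMatrix-class] with values in `[0, 1)`.
#' @return A [DistanceMatrix-class] of the same kind.
#' @export
normalizeFst <- function(fst) {
  stopifnot(is(fst, "DistanceMatrix"))
  v <- fst@values
  if (any(v >= 1) || any(v < 0)) stop("FST values must lie in [0, 1)")
  distanceMatrix(v / (1 - v), kind = fst@kind)
}

# permute rows+columns of a square matrix, keeping the original labels in
# place (so downstream label alignment cannot undo the permutation)
permuteMatrix <- function(m, perm) {
  out <- m[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(m)
  out
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower triangles of two distance matrices with
#' significance from joint row/column permutations of one matrix. The
#' default tail tests for positive association, the standard direction for
#' isolation-by-distance; `p = (1 + exceedances) / (1 + nPerm)`. With
#' `exhaustive = TRUE` all `n!` permutations are enumerated (n <= 7) and
#' `p = #(r_perm >= r_obs) / n!` with the identity counted.
#'
#' @param X,Y [DistanceMatrix-class] objects (or labelled square matrices)
#'   over the same labels; matrices are aligned by label.
#' @param nPerm number of sampled permutations.
#' @param standardizeByMean divide each matrix by its off-diagonal mean
#'   before correlating (accounts for scale; leaves `r` unchanged).
#' @param tail `"positive"` (one-tailed) or `"two-sided"`.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @param seed integer seed of the permutation stream.
#' @return list of class `MantelResult`: `r`, `r2`, `p`, `nPerm`, `tail`.
#' @export
mantelTest <- function(X, Y, nPerm = 10000, standardizeByMean = FALSE,
                       tail = c("positive", "two-sided"), exhaustive = FALSE, seed = 1) {
  tail <- match.arg(tail)
  labels <- rownames(if (is(X, "DistanceMatrix")) X@values else X)
  x <- alignTo(X, labels); y <- alignTo(Y, labels)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 labels")
  if (standardizeByMean) {
    x <- x / mean(x[lower.tri(x)])
    y <- y / mean(y[lower.tri(y)])
  }
  xv <- x[lower.tri(x)]
  if (stats::sd(xv) == 0 || stats::sd(y[lower.tri(y)]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  rObs <- stats::cor(xv, y[lower.tri(y)])
  stat <- function(rp) if (tail == "positive") rp >= rObs - 1e-12 else abs(rp) >= abs(rObs) - 1e-12

  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration supported for n <= 7 only")
    perms <- allPermutations(n)
    rp <- apply(perms, 1, function(p) stats::cor(xv, permuteMatrix(y, p)[lower.tri(y)]))
    p <- mean(stat(rp))
    nPerm <- nrow(perms)
  } else {
    exc <- withSeed(seed, {
      sum(vapply(seq_len(nPerm), function(i) {
        pm <- sample.int(n)
        stat(stats::cor(xv, permuteMatrix(y, pm)[lower.tri(y)]))
      }, logical(1)))
    })
    p <- (1 + exc) / (1 + nPerm)
  }
  structure(list(r = rObs, r2 = rObs^2, p = p, nPerm = nPerm, tail = tail,
                 exhaustive = exhaustive),
            class = "MantelResult")
}

#' @export
print.MantelResult <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f (r2 = %.4f), p = %.4g (%s, %d permutations%s)\n",
              x$r, x$r2, x$p, x$tail, x$nPerm, if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' Ordinary least squares on the z-scored unfolded lower triangles of the
#' response and predictor distance matrices; per-coefficient and overall
#' significance from joint row/column permutations of the response,
#' recomputing t and F statistics (`p = (1 + exceedances) / (1 + nPerm)`).
#'
#' @param Y response [DistanceMatrix-class].
#' @param XList named list of predictor matrices over the same labels.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list of class `MMRRResult`: `coefficients` (standardized,
#'   including intercept), `rawCoefficients`, `r.squared`, `tstat`, `pCoef`,
#'   `Fstat`, `pF`, `nPerm`.
#' @export
mmrr <- function(Y, XList, nPerm = 10000, seed = 1) {
  if (!length(XList)) stop("need at least one predictor matrix")
  if (is.null(names(XList))) names(XList) <- paste0("X", seq_along(XList))
  labels <- rownames(if (is(Y, "DistanceMatrix")) Y@values else Y)
  n <- length(labels)
  if (n < 5) stop("need at least 5 labels")
  ymat <- alignTo(Y, labels)
  xmats <- lapply(XList, alignTo, labels = labels)

  lt <- lower.tri(ymat)
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  yv <- ymat[lt]
  Xv <- vapply(xmats, function(m) m[lt], numeric(sum(lt)))
  Xz <- apply(Xv, 2, zscore)
  yz <- zscore(yv)
  X <- cbind(Intercept = 1, Xz)

  XtX <- crossprod(X)
  if (kappa(XtX, exact = TRUE) > 1e8) stop("collinear predictors (condition number > 1e8)")
  XtXinv <- solve(XtX)
  npairs <- length(yv); k <- ncol(Xz)

  fitStats <- function(yvec) {
    b <- XtXinv %*% crossprod(X, yvec)
    res <- yvec - X %*% b
    rss <- sum(res^2)
    tss <- sum((yvec - mean(yvec))^2)
    df <- npairs - k - 1
    sigma2 <- rss / df
    tval <- as.vector(b) / sqrt(pmax(diag(XtXinv) * sigma2, .Machine$double.eps))
    Fval <- if (k > 0) ((tss - rss) / k) / sigma2 else NA_real_
    list(b = as.vector(b), t = tval, F = Fval, r2 = 1 - rss / tss)
  }
  obs <- fitStats(yz)

  excT <- numeric(k + 1); excF <- 0
  withSeed(seed, {
    for (i in seq_len(nPerm)) {
      pm <- sample.int(n)
      yp <- zscore(permuteMatrix(ymat, pm)[lt])
      st <- fitStats(yp)
      excT <- excT + (abs(st$t) >= abs(obs$t) - 1e-12)
      excF <- excF + (st$F >= obs$F - 1e-12)
    }
  })
  pCoef <- (1 + excT) / (1 + nPerm)
  names(obs$b) <- names(pCoef) <- colnames(X)
  # raw-scale coefficients (original distance units)
  sdY <- stats::sd(yv); sdX <- apply(Xv, 2, stats::sd)
  rawB <- obs$b[-1] * sdY / sdX
  structure(list(coefficients = obs$b, rawCoefficients = rawB,
                 r.squared = obs$r2, tstat = obs$t, pCoef = pCoef,
                 Fstat = obs$F, pF = (1 + excF) / (1 + nPerm), nPerm = nPerm),
            class = "MMRRResult")
}

#' @export
print.MMRRResult <- function(x, ...) {
  cat(sprintf("MMRR: R2 = %.4f, F = %.3f (p = %.4g, %d permutations)\n",
              x$r.squared, x$Fstat, x$pF, x$nPerm))
  tab <- data.frame(coefficient = round(x$coefficients, 4),
                    t = round(x$tstat, 3), p = signif(x$pCoef, 4))
  print(tab)
  invisible(x)
}
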