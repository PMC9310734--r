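#' Two-dimensional site frequency spectrum by EM
#'
#' Estimates the joint spectrum of expected site counts over the class
#' space `(d1, d2)` of per-population derived-allele counts, by EM on the
#' outer products of the two populations' per-site allele-frequency
#' likelihood vectors. The E-step and M-step are carried out in matrix form
#' (never materializing per-site outer products), so the per-iteration cost
#' is two `sites x classes` matrix products.
#'
#' @param glA,glB [GenotypeLikelihoodSet-class] objects for the two
#'   populations; sites are matched by ID and must overlap.
#' @param tol stopping tolerance on the maximum absolute change of the
#'   probability-scale joint spectrum.
#' @param maxIter EM iteration cap.
#' @param init `"product"` starts from the normalized cross-product of the
#'   likelihood matrices (one E-step from uniform); `"uniform"` starts flat.
#' @return numeric matrix `(2N1 + 1) x (2N2 + 1)` of expected site counts
#'   summing to the shared-site count, with attributes `converged` and
#'   `loglik`.
#' @export
jointSFS <- function(glA, glB, tol = 1e-6, maxIter = 200, init = c("product", "uniform")) {
  stopifnot(is(glA, "GenotypeLikelihoodSet"), is(glB, "GenotypeLikelihoodSet"))
  init <- match.arg(init)
  shared <- intersect(glA@sites, glB@sites)
  if (length(shared) == 0) stop("the two populations share no sites")
  A <- siteAlleleFrequencyLikelihoods(subsetGL(glA, sites = shared))
  B <- siteAlleleFrequencyLikelihoods(subsetGL(glB, sites = shared))
  S <- nrow(A)
  K1 <- ncol(A); K2 <- ncol(B)
  P <- if (init == "product") {
    M <- crossprod(A, B)
    M / sum(M)
  } else {
    matrix(1 / (K1 * K2), K1, K2)
  }
  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    c_s <- rowSums((A %*% P) * B)
    ll <- c(ll, sum(log(c_s)))
    Pnew <- P * crossprod(A / c_s, B) / S
    delta <- max(abs(Pnew - P))
    P <- Pnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("2D SFS EM did not reach tol ", tol, " within ", maxIter, " iterations")
  out <- P * S
  dimnames(out) <- list(d1 = 0:(K1 - 1), d2 = 0:(K2 - 1))
  attr(out, "converged") <- converged
  attr(out, "loglik") <- ll
  out
}

#' Hudson FST from a joint site frequency spectrum
#'
#' Ratio-of-sums estimator: for each class `(d1, d2)` with sample
#' frequencies `p1 = d1/n1`, `p2 = d2/n2` (haploid sample sizes `n1`, `n2`),
#' the numerator is
#' `alpha = (p1 - p2)^2 - p1(1 - p1)/(n1 - 1) - p2(1 - p2)/(n2 - 1)`
#' and the denominator `p1(1 - p2) + p2(1 - p1)`; both are weighted by the
#' class mass and summed before the ratio is taken. Classes monomorphic in
#' both populations contribute zero. `method = "reynolds"` switches to the
#' Reynolds, Weir and Cockerham (1983) ratio-of-sums.
#'
#' @param sfs2d joint spectrum from [jointSFS()] (expected counts).
#' @param method `"hudson"` (default) or `"reynolds"`.
#' @return list of class `FstResult`: `fst` (weighted ratio of sums),
#'   `numerator`, `denominator`, `jointSFS`, `method`. `fst` is `NA` with an
#'   `undefined` flag when no variation exists.
#' @export
fstFromJointSFS <- function(sfs2d, method = c("hudson", "reynolds")) {
  method <- match.arg(method)
  K1 <- nrow(sfs2d); K2 <- ncol(sfs2d)
  n1 <- K1 - 1; n2 <- K2 - 1
  if (n1 < 2 || n2 < 2) stop("both samples must contain at least 2 haplotypes")
  p1 <- matrix((0:n1) / n1, K1, K2)
  p2 <- matrix((0:n2) / n2, K1, K2, byrow = TRUE)
  if (method == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    # Reynolds-style ANOVA (method-of-moments) estimator on haploid counts:
    # theta = (MSB - MSW) / (MSB + (nc - 1) MSW), ratio of sums over classes
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    MSB <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2            # r - 1 = 1
    MSW <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))               # / (r - 1)
    num <- MSB - MSW
    den <- MSB + (nc - 1) * MSW
  }
  w <- sfs2d / sum(sfs2d)
  sn <- sum(w * num); sd <- sum(w * den)
  fst <- if (sd <= 0) NA_real_ else sn / sd
  structure(list(fst = fst, numerator = sn, denominator = sd,
                 jointSFS = sfs2d, method = method,
                 undefined = sd <= 0),
            class = "FstResult")
}

#' @export
print.FstResult <- function(x, ...) {
  cat(sprintf("FstResult (%s): FST = %s\n", x$method,
              if (x$undefined) "undefined (no variation)" else sprintf("%.4f", x$fst)))
  invisible(x)
}

#' Pairwise FST matrix between localities
#'
#' Splits the genotype-likelihood set by locality, estimates a joint SFS
#' and the Hudson FST for every locality pair, and assembles the symmetric
#' matrix. Negative estimates are clamped to 0 (original values kept in the
#' `"rawFst"` attribute); localities with fewer than 2 individuals are
#' excluded with a warning.
#'
#' @param gl a [GenotypeLikelihoodSet-class] covering all individuals.
#' @param localities a [LocalityTable-class] mapping individuals to
#'   localities.
#' @param method passed to [fstFromJointSFS()].
#' @param tol,maxIter passed to [jointSFS()].
#' @return A [DistanceMatrix-class] of kind `"FST"`.
#' @export
fstMatrix <- function(gl, localities, method = "hudson", tol = 1e-6, maxIter = 200) {
  stopifnot(is(gl, "GenotypeLikelihoodSet"), is(localities, "LocalityTable"))
  sh <- localities@samples
  locs <- unique(sh$locality)
  sizes <- vapply(locs, function(l) sum(sh$locality == l & sh$individual %in% gl@individuals), integer(1))
  drop <- sizes < 2
  if (any(drop)) {
    warning("excluding localities with fewer than 2 genotyped individuals: ",
            paste(locs[drop], collapse = ", "))
    locs <- locs[!drop]
  }
  if (length(locs) < 2) stop("need at least 2 localities with at least 2 individuals")
  glByLoc <- lapply(locs, function(l)
    subsetGL(gl, individuals = intersect(sh$individual[sh$locality == l], gl@individuals)))
  names(glByLoc) <- locs
  k <- length(locs)
  M <- matrix(0, k, k, dimnames = list(locs, locs))
  raw <- M
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fst <- fstFromJointSFS(jointSFS(glByLoc[[i]], glByLoc[[j]], tol = tol, maxIter = maxIter),
                           method = method)$fst
    raw[i, j] <- raw[j, i] <- fst
    M[i, j] <- M[j, i] <- max(fst, 0)
  }
  out <- distanceMatrix(M, kind = "FST")
  attr(out@values, "rawFst") <- raw
  out
}
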