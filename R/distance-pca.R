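# genotype posteriors per site/individual: uniform prior by default, or
# HWE priors from supplied per-site frequencies; returns list of 3
# sites x individuals matrices plus a coverage mask (informative entries)
genotypePosteriors <- function(gl, siteFreqs = NULL) {
  G <- gl@gl
  S <- dim(G)[1]
  P0 <- G[, , 1, drop = TRUE]; P1 <- G[, , 2, drop = TRUE]; P2 <- G[, , 3, drop = TRUE]
  if (S == 1L) { P0 <- rbind(P0); P1 <- rbind(P1); P2 <- rbind(P2) }
  covered <- (pmax(P0, P1, P2) - pmin(P0, P1, P2)) > 1e-12
  if (!is.null(siteFreqs)) {
    p <- siteFreqs; q <- 1 - p
    P0 <- P0 * q^2; P1 <- P1 * 2 * p * q; P2 <- P2 * p^2
  }
  tot <- P0 + P1 + P2
  list(P0 = P0 / tot, P1 = P1 / tot, P2 = P2 / tot, covered = covered)
}

#' Pairwise genetic distances between individuals
#'
#' Expected allele-sharing distance on genotype posteriors: for a pair
#' `(i, j)` the distance is the mean over shared covered sites of
#' `sum_{g,h} P_i(g) P_j(h) k(g, h)` with kernel `k = |g - h| / 2`
#' (dosage scale; flag `kernel = "mismatch"` switches to the 0/1 genotype
#' mismatch kernel). Posteriors use a uniform genotype prior unless
#' per-site frequencies are supplied.
#'
#' @param gl a [GenotypeLikelihoodSet-class] with >= 2 individuals.
#' @param siteFreqs optional per-site minor/derived frequencies for an HWE
#'   prior.
#' @param kernel `"dosage"` (default, `|g - h|/2`) or `"mismatch"` (0/1).
#' @return A [DistanceMatrix-class] (kind `"genetic"`); pairs with no shared
#'   covered site are `NA` and named in the `"missingPairs"` attribute.
#' @export
pairwiseGeneticDistance <- function(gl, siteFreqs = NULL, kernel = c("dosage", "mismatch")) {
  stopifnot(is(gl, "GenotypeLikelihoodSet"))
  kernel <- match.arg(kernel)
  N <- dim(gl@gl)[2]
  if (N < 2) stop("need at least 2 individuals")
  K <- if (kernel == "dosage") {
    matrix(c(0, .5, 1, .5, 0, .5, 1, .5, 0), 3, 3)
  } else {
    1 - diag(3)
  }
  po <- genotypePosteriors(gl, siteFreqs)
  A <- list(po$P0, po$P1, po$P2)
  for (k in 1:3) A[[k]] <- A[[k]] * po$covered       # exclude missing entries
  num <- matrix(0, N, N)
  for (g in 1:3) for (h in 1:3) if (K[g, h] != 0)
    num <- num + K[g, h] * crossprod(A[[g]], A[[h]])
  nShared <- crossprod(po$covered * 1)
  D <- num / nShared
  D[nShared == 0] <- NA_real_
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(gl@individuals, gl@individuals)
  missing <- which(nShared == 0 & upper.tri(nShared), arr.ind = TRUE)
  out <- new("DistanceMatrix", values = D, kind = "genetic")
  attr(out@values, "missingPairs") <- missing
  out
}

#' Genotype-posterior covariance and PCA
#'
#' Computes expected allele dosages from genotype posteriors (uniform prior
#' to obtain initial frequencies, then a single pass with HWE priors at the
#' estimated frequencies), standardizes per site by `2 p (1 - p)`, and
#' eigendecomposes the individual covariance matrix. Sites with estimated
#' frequency outside `(0.01, 0.99)` are excluded; fewer than 10 retained
#' sites is an error.
#'
#' @param gl a [GenotypeLikelihoodSet-class] with >= 3 individuals.
#' @param freqBounds open interval of retained site frequencies.
#' @return list of class `GLPca`: `cov` (N x N), `values` (eigenvalues,
#'   decreasing), `vectors`, `scores` (individuals x components),
#'   `nSitesUsed`, `siteFreqs`.
#' @export
glCovariancePCA <- function(gl, freqBounds = c(0.01, 0.99)) {
  stopifnot(is(gl, "GenotypeLikelihoodSet"))
  N <- dim(gl@gl)[2]
  if (N < 3) stop("need at least 3 individuals")
  po <- genotypePosteriors(gl)
  E <- po$P1 + 2 * po$P2
  p <- rowMeans(E) / 2
  po <- genotypePosteriors(gl, siteFreqs = p)
  E <- po$P1 + 2 * po$P2
  p <- rowMeans(E) / 2
  keep <- p > freqBounds[1] & p < freqBounds[2]
  if (sum(keep) < 10) stop("fewer than 10 sites retained after frequency filtering")
  Ek <- E[keep, , drop = FALSE]
  pk <- p[keep]
  Z <- (Ek - 2 * pk) / sqrt(2 * pk * (1 - pk))
  C <- crossprod(Z) / sum(keep)
  dimnames(C) <- list(gl@individuals, gl@individuals)
  eig <- eigen(C, symmetric = TRUE)
  scores <- eig$vectors * rep(sqrt(pmax(eig$values, 0)), each = N)
  rownames(scores) <- gl@individuals
  structure(list(cov = C, values = eig$values, vectors = eig$vectors,
                 scores = scores, nSitesUsed = sum(keep), siteFreqs = p),
            class = "GLPca")
}

#' @export
print.GLPca <- function(x, ...) {
  cat(sprintf("GLPca: %d individuals, %d sites; leading eigenvalues: %s\n",
              nrow(x$cov), x$nSitesUsed,
              paste(round(utils::head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}
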