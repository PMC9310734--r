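#' Per-site allele-frequency likelihoods
#'
#' For every site, computes `L(d) = P(data | total derived count d)` for
#' `d = 0..2N` by dynamic-programming convolution over individuals: per
#' individual the three genotype likelihoods enter with the combinatorial
#' weights `choose(2, g)`, and the convolution is normalized by
#' `choose(2N, d)` so that fully certain genotypes give an exact indicator
#' at the true total count (hypergeometric sampling without replacement of
#' alleles onto individuals). Rows are returned rescaled to maximum 1.
#'
#' All-missing sites (three equal likelihoods for every individual) yield a
#' uniform row and are flagged in the `"uninformative"` attribute.
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @return numeric matrix `sites x (2N + 1)`, attribute `uninformative`
#'   (logical per site).
#' @export
siteAlleleFrequencyLikelihoods <- function(gl) {
  stopifnot(is(gl, "GenotypeLikelihoodSet"))
  G <- gl@gl
  S <- dim(G)[1]; N <- dim(G)[2]
  z <- matrix(0, S, 2 * N + 1)
  z[, 1] <- 1
  for (i in seq_len(N)) {
    w0 <- G[, i, 1]; w1 <- 2 * G[, i, 2]; w2 <- G[, i, 3]
    old <- 2 * (i - 1) + 1          # current number of filled classes
    zn <- matrix(0, S, old + 2)
    zn[, 1:old] <- z[, 1:old, drop = FALSE] * w0
    zn[, 2:(old + 1)] <- zn[, 2:(old + 1), drop = FALSE] + z[, 1:old, drop = FALSE] * w1
    zn[, 3:(old + 2)] <- zn[, 3:(old + 2), drop = FALSE] + z[, 1:old, drop = FALSE] * w2
    z[, 1:(old + 2)] <- zn
    if (max(z) > 1e250) z <- z / max(z)   # overflow guard; rows renormalized below
  }
  L <- sweep(z, 2, choose(2 * N, 0:(2 * N)), `/`)
  mx <- apply(L, 1, max)
  mx[mx == 0] <- 1
  L <- L / mx
  uninf <- apply(L, 1, function(r) max(r) - min(r) < 1e-12)
  attr(L, "uninformative") <- uninf
  L
}

#' Estimate the site frequency spectrum by EM
#'
#' Maximizes the likelihood of a global SFS prior over the per-site
#' allele-frequency likelihood vectors: the E-step computes posterior class
#' memberships under the current spectrum, the M-step sets the spectrum to
#' the summed posteriors. On fully certain genotypes this converges in one
#' step to the exact histogram of per-site derived counts.
#'
#' @param gl a [GenotypeLikelihoodSet-class], or a precomputed likelihood
#'   matrix from [siteAlleleFrequencyLikelihoods()].
#' @param fold collapse classes `d` and `2N - d` after estimation.
#' @param tol EM stopping tolerance on the maximum absolute change of the
#'   probability-scale spectrum.
#' @param maxIter iteration cap; hitting it sets `converged = FALSE` with a
#'   warning.
#' @return A [SiteFrequencySpectrum-class].
#' @export
estimateSFS <- function(gl, fold = FALSE, tol = 1e-8, maxIter = 500) {
  L <- if (is.matrix(gl)) gl else siteAlleleFrequencyLikelihoods(gl)
  if (!is.matrix(gl) && gl@polarization == "folded") fold <- TRUE
  uninf <- attr(L, "uninformative")
  if (!is.null(uninf) && all(uninf)) stop("no informative site: cannot estimate an SFS")
  S <- nrow(L); K <- ncol(L)
  phi <- rep(1 / K, K)
  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    c_s <- as.vector(L %*% phi)
    ll <- c(ll, sum(log(c_s)))
    phiNew <- phi * colSums(L / c_s) / S
    delta <- max(abs(phiNew - phi))
    phi <- phiNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("SFS EM did not reach tol ", tol, " within ", maxIter, " iterations")
  counts <- phi * S
  sfs <- new("SiteFrequencySpectrum", counts = counts, nSites = S,
             folded = FALSE, converged = converged, loglik = ll)
  if (fold) foldSFS(sfs) else sfs
}

#' Fold a site frequency spectrum
#'
#' Collapses derived-count classes `d` and `2N - d` into minor-allele-count
#' classes `0..N`; total site count is preserved.
#'
#' @param sfs an unfolded [SiteFrequencySpectrum-class].
#' @return the folded spectrum.
#' @export
foldSFS <- function(sfs) {
  stopifnot(is(sfs, "SiteFrequencySpectrum"))
  if (sfs@folded) return(sfs)
  K <- length(sfs@counts)           # 2N + 1
  n <- K - 1                        # haplotypes
  half <- n %/% 2
  counts <- vapply(0:half, function(i) {
    if (i == n - i) sfs@counts[i + 1] else sfs@counts[i + 1] + sfs@counts[n - i + 1]
  }, numeric(1))
  new("SiteFrequencySpectrum", counts = counts, nSites = sfs@nSites,
      folded = TRUE, converged = sfs@converged, loglik = sfs@loglik)
}

setMethod("show", "SiteFrequencySpectrum", function(object) {
  cat(sprintf("SiteFrequencySpectrum (%s): %d classes, %g sites%s\n",
              if (object@folded) "folded" else "unfolded",
              length(object@counts), object@nSites,
              if (object@converged) "" else " [NOT converged]"))
  invisible(object)
})

#' @describeIn foldSFS expected counts per allele-count class.
#' @param x a `SiteFrequencySpectrum`.
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' @export
setMethod("sfsCounts", "SiteFrequencySpectrum", function(x) x@counts)

#' Write / read an SFS as one line of whitespace-separated counts
#'
#' @param sfs a [SiteFrequencySpectrum-class].
#' @param path file path.
#' @param folded polarization flag to attach on read.
#' @return `readSFS` returns a [SiteFrequencySpectrum-class].
#' @export
writeSFS <- function(sfs, path) {
  writeLines(paste(format(sfs@counts, digits = 15, scientific = FALSE, trim = TRUE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname writeSFS
#' @export
readSFS <- function(path, folded = FALSE) {
  counts <- scan(path, quiet = TRUE)
  new("SiteFrequencySpectrum", counts = counts, nSites = sum(counts),
      folded = folded, converged = TRUE, loglik = numeric(0))
}

#' Intersect per-locality site lists
#'
#' @param siteLists list (length >= 2) of character site-ID vectors.
#' @return sorted character vector of shared site IDs; empty intersections
#'   are an error.
#' @export
intersectSites <- function(siteLists) {
  if (!is.list(siteLists) || length(siteLists) < 2) stop("need at least two site lists")
  shared <- Reduce(intersect, siteLists)
  if (length(shared) == 0) stop("the site lists share no sites")
  sort(shared)
}

#' Nucleotide diversity from a site frequency spectrum
#'
#' Expected pairwise differences `theta_pi = sum_i i (n - i) eta_i / choose(n, 2)`
#' over variable classes, with the per-site value dividing by the number of
#' sites. The same class-weight formula applies to folded spectra (class
#' index = minor count; `i (n - i)` is symmetric under `i -> n - i`).
#'
#' @param sfs a [SiteFrequencySpectrum-class] (n = 2N haplotypes >= 2).
#' @return list of class `DiversityEstimate`: `thetaPiTotal`,
#'   `thetaPiPerSite`, `nSites`.
#' @export
thetaPi <- function(sfs) {
  stopifnot(is(sfs, "SiteFrequencySpectrum"))
  K <- length(sfs@counts)
  n <- if (sfs@folded) 2L * (K - 1L) else K - 1L
  # folded spectra from odd haplotype counts are not produced here; 2(K-1)
  # recovers n for even n, which is always the case for diploid samples
  if (n < 2) stop("need at least 2 haplotypes (n = 2N >= 2)")
  i <- 0:(K - 1)
  total <- sum(i * (n - i) * sfs@counts) / choose(n, 2)
  structure(list(thetaPiTotal = total,
                 thetaPiPerSite = total / sfs@nSites,
                 nSites = sfs@nSites),
            class = "DiversityEstimate")
}

#' Per-individual heterozygosity from genotype likelihoods
#'
#' Runs the three-class (0/1/2 copies) SFS EM separately for each diploid
#' and reports the heterozygous class mass divided by the total number of
#' sites. Individuals with no informative site return `NA` and are named in
#' the `"undefined"` attribute.
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @param tol,maxIter EM controls.
#' @return named numeric vector of per-individual heterozygosity.
#' @export
individualHeterozygosity <- function(gl, tol = 1e-8, maxIter = 500) {
  stopifnot(is(gl, "GenotypeLikelihoodSet"))
  G <- gl@gl
  N <- dim(G)[2]
  out <- rep(NA_real_, N)
  names(out) <- gl@individuals
  for (i in seq_len(N)) {
    L <- G[, i, , drop = TRUE]
    if (is.null(dim(L))) L <- matrix(L, ncol = 3)
    informative <- apply(L, 1, function(r) max(r) - min(r) > 1e-12)
    if (!any(informative)) next
    psi <- rep(1 / 3, 3)
    for (it in seq_len(maxIter)) {
      c_s <- as.vector(L %*% psi)
      psiNew <- psi * colSums(L / c_s) / nrow(L)
      if (max(abs(psiNew - psi)) < tol) { psi <- psiNew; break }
      psi <- psiNew
    }
    out[i] <- psi[2]
  }
  attr(out, "undefined") <- gl@individuals[is.na(out)]
  out
}

#' Variable sites under maximum-likelihood allele counts
#'
#' Site list for theta-file style intersection: sites whose most likely
#' total allele count is polymorphic (argmax of the allele-frequency
#' likelihood strictly between 0 and 2N).
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @return character vector of site IDs.
#' @export
variableSites <- function(gl) {
  L <- siteAlleleFrequencyLikelihoods(gl)
  d <- max.col(L, ties.method = "first") - 1L
  gl@sites[d > 0 & d < ncol(L) - 1L & !attr(L, "uninformative")]
}
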