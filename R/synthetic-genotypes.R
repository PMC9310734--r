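#' Ground-truth record of a simulated metapopulation
#'
#' Bundles every parameter needed to regenerate a genotype-likelihood
#' simulation exactly. Population allele frequencies follow the
#' Balding-Nichols model around the ancestral frequency (Beta with mean `p`
#' and variance `F p (1-p)`); alternatively `popCov` imposes a spatial
#' covariance on logit-scale locality deviations so that pairwise
#' differentiation grows with a supplied distance matrix.
#'
#' @param nPops number of populations.
#' @param nIndPerPop diploid individuals per population (scalar or vector).
#' @param fstTarget Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param inbreeding per-individual inbreeding coefficient(s) in `[0, 1]`.
#' @param nSites number of biallelic sites.
#' @param depthMean mean sequencing depth (reads/site, Poisson).
#' @param errorRate per-read base error rate.
#' @param ancestralFreqs optional per-site ancestral frequencies in (0, 1);
#'   drawn uniform on (0.05, 0.95) when `NULL`.
#' @param popCov optional `nPops x nPops` covariance matrix of logit-scale
#'   locality deviations (overrides the star-shaped Balding-Nichols draw;
#'   used to couple differentiation to landscape distances).
#' @param withholdAncestral if `TRUE` allele labels are randomly swapped per
#'   site and the output is marked folded, forcing folded analysis.
#' @param seed integer RNG seed.
#' @return A list of class `MetapopulationTruth`.
#' @export
metapopulationTruth <- function(nPops, nIndPerPop, fstTarget, nSites,
                                inbreeding = 0, depthMean = 8, errorRate = 0.01,
                                ancestralFreqs = NULL, popCov = NULL,
                                withholdAncestral = FALSE, seed = 1) {
  if (fstTarget < 0 || fstTarget >= 1) stop("fstTarget must lie in [0, 1)")
  if (depthMean <= 0) stop("depthMean must be positive")
  nInd <- rep_len(nIndPerPop, nPops)
  structure(list(nPops = nPops, nIndPerPop = nInd,
                 fstTarget = fstTarget,
                 inbreeding = rep_len(inbreeding, sum(nInd)),
                 nSites = nSites, depthMean = depthMean, errorRate = errorRate,
                 ancestralFreqs = ancestralFreqs, popCov = popCov,
                 withholdAncestral = withholdAncestral, seed = seed),
            class = "MetapopulationTruth")
}

#' Simulate genotype likelihoods for a structured metapopulation
#'
#' Per site, population allele frequencies are drawn from the
#' Balding-Nichols distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the
#' ancestral frequency `p` (`F = 0` uses `p` directly; a `popCov` in the
#' truth object switches to the logit-normal spatial model). Genotypes are
#' drawn with per-individual inbreeding (`P(het) = 2pq(1-f)`), read depths
#' are Poisson, alternate-read counts binomial with the error-adjusted
#' allele dosage, and genotype likelihoods are binomial read-sampling
#' likelihoods normalized so the per-site/individual maximum is 1.
#' Zero-depth entries receive three equal likelihoods (missing).
#'
#' @param truth a [metapopulationTruth()] record.
#' @return list with `gl` ([GenotypeLikelihoodSet-class]), `genotypes`
#'   (sites x individuals integer matrix of true derived-allele dosages),
#'   `popFreqs` (sites x pops), `population` (individual -> population index),
#'   `depth` (sites x individuals), and `truth`.
#' @export
simulateGenotypeLikelihoods <- function(truth) {
  stopifnot(inherits(truth, "MetapopulationTruth"))
  S <- truth$nSites
  nInd <- truth$nIndPerPop
  N <- sum(nInd)
  pop <- rep(seq_len(truth$nPops), nInd)
  f <- truth$inbreeding
  e <- truth$errorRate

  withSeed(truth$seed, {
    p <- truth$ancestralFreqs
    if (is.null(p)) p <- stats::runif(S, 0.05, 0.95)

    Fst <- truth$fstTarget
    if (!is.null(truth$popCov)) {
      L <- chol(truth$popCov)
      Z <- matrix(stats::rnorm(S * truth$nPops), S) %*% L
      q <- stats::plogis(stats::qlogis(p) + Z)
    } else if (Fst > 0) {
      a <- p * (1 - Fst) / Fst
      b <- (1 - p) * (1 - Fst) / Fst
      q <- matrix(stats::rbeta(S * truth$nPops, rep(a, truth$nPops), rep(b, truth$nPops)), S)
    } else {
      q <- matrix(p, S, truth$nPops)
    }
    q <- pmin(pmax(q, 1e-9), 1 - 1e-9)

    qi <- q[, pop, drop = FALSE]                       # sites x individuals
    fi <- matrix(f, S, N, byrow = TRUE)
    pHet <- 2 * qi * (1 - qi) * (1 - fi)
    pHomD <- qi^2 + fi * qi * (1 - qi)
    u <- matrix(stats::runif(S * N), S)
    g <- matrix(0L, S, N)
    g[u < pHomD] <- 2L
    g[u >= pHomD & u < pHomD + pHet] <- 1L

    depth <- matrix(stats::rpois(S * N, truth$depthMean), S)
    pAlt <- g / 2 * (1 - e) + (1 - g / 2) * e
    nAlt <- matrix(stats::rbinom(S * N, depth, pAlt), S)

    swap <- if (truth$withholdAncestral) stats::runif(S) < 0.5 else rep(FALSE, S)
  })

  gl <- array(1, dim = c(S, N, 3))
  pErr <- c(e, 0.5, 1 - e)                             # alt-read prob per genotype
  cov <- depth > 0
  for (k in 1:3) {
    m <- matrix(1, S, N)
    m[cov] <- stats::dbinom(nAlt[cov], depth[cov], pErr[k])
    gl[, , k] <- m
  }
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  mx[mx == 0] <- 1
  for (k in 1:3) gl[, , k] <- gl[, , k] / mx

  if (any(swap)) {
    gl[swap, , ] <- gl[swap, , 3:1]
    g[swap, ] <- 2L - g[swap, ]
    q[swap, ] <- 1 - q[swap, ]
  }

  sites <- sprintf("site_%06d", seq_len(S))
  inds <- sprintf("Ind%03d", seq_len(N))
  glset <- new("GenotypeLikelihoodSet",
               gl = gl, sites = sites,
               alleles = matrix(c("0", "1"), S, 2, byrow = TRUE,
                                dimnames = list(sites, c("major", "minor"))),
               individuals = inds,
               polarization = if (truth$withholdAncestral) "folded" else "unfolded")
  dimnames(g) <- list(sites, inds)
  list(gl = glset, genotypes = g, popFreqs = q, population = pop,
       depth = depth, truth = truth)
}

#' Distance-coupled locality covariance for the logit-frequency model
#'
#' Builds the `popCov` matrix for [metapopulationTruth()] such that the
#' variance of logit-frequency differences between two localities grows
#' with their (least-cost or geographic) distance:
#' `Cov(i, j) = sigma^2 * exp(-d_ij / lambda)`.
#'
#' @param d symmetric distance matrix (or [DistanceMatrix-class]).
#' @param sigma logit-scale standard deviation of locality deviations.
#' @param lambda distance scale of decorrelation, in the units of `d`.
#' @return positive-definite covariance matrix.
#' @export
distanceCoupledCov <- function(d, sigma = 0.8, lambda = NULL) {
  if (is(d, "DistanceMatrix")) d <- d@values
  if (is.null(lambda)) lambda <- stats::median(d[lower.tri(d)])
  sigma^2 * exp(-d / lambda) + diag(1e-8, nrow(d))
}
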