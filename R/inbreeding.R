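#' Per-individual inbreeding coefficients by two-stage EM
#'
#' Models each individual's genotype at each site with the
#' inbreeding-adjusted prior
#' `( (1-p)^2 + f p (1-p), 2 p (1-p) (1-f), p^2 + f p (1-p) )`, where `p` is
#' the site's minor/derived allele frequency and `f` the individual's
#' deviation from Hardy-Weinberg equilibrium. Estimation is an exact EM on
#' the latent identity-by-descent indicator `z` (with probability `f` the
#' individual carries two copies of one allele draw): the E-step computes
#' joint posteriors of genotype and `z` from the genotype likelihoods, the
#' M-step sets `f_i` to the mean posterior IBD mass over sites and `p_s`
#' from the expected allele draws (an IBD individual contributes one
#' independent allele, a non-IBD individual two). The log-likelihood is
#' non-decreasing by construction and checked at every iteration.
#'
#' Two stages mirror the usual practice for this EM: a short first run from
#' neutral starting values produces starting coefficients, and a second,
#' deeper run restarts from them with a higher iteration cap.
#'
#' @param gl a [GenotypeLikelihoodSet-class] with at least 2 individuals.
#' @param maxIterStage1 iteration cap of the first stage.
#' @param maxIterStage2 iteration cap of the deeper second stage.
#' @param tol stopping tolerance on the maximum absolute parameter change.
#' @return list of class `InbreedingResult`: `F` (named per-individual
#'   coefficients in `[0, 1]`), `minorFreq` (per-site frequencies), `loglik`
#'   (trace), `iterations`, `converged`.
#' @export
estimateInbreeding <- function(gl, maxIterStage1 = 200, maxIterStage2 = 1500, tol = 1e-6) {
  stopifnot(is(gl, "GenotypeLikelihoodSet"))
  G <- gl@gl
  S <- dim(G)[1]; N <- dim(G)[2]
  if (N < 2) stop("need at least 2 individuals")
  G0 <- G[, , 1, drop = TRUE]; G1 <- G[, , 2, drop = TRUE]; G2 <- G[, , 3, drop = TRUE]
  if (S == 1L) { G0 <- rbind(G0); G1 <- rbind(G1); G2 <- rbind(G2) }

  # neutral initial values: small f, p from likelihood-weighted dosage
  tot <- G0 + G1 + G2
  p <- rowSums((G1 + 2 * G2) / tot) / (2 * N)
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  f <- rep(0.01, N)

  emStage <- function(p, f, maxIter) {
    ll <- numeric(0)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
      it <- it + 1L
      fm <- matrix(f, S, N, byrow = TRUE)
      q <- 1 - p
      # joint weights w(g, z): z = 1 IBD (hom only), z = 0 HWE
      w0z1 <- G0 * (q * fm);        w2z1 <- G2 * (p * fm)
      w0z0 <- G0 * (q^2 * (1 - fm)); w1z0 <- G1 * (2 * p * q * (1 - fm)); w2z0 <- G2 * (p^2 * (1 - fm))
      tot <- w0z1 + w2z1 + w0z0 + w1z0 + w2z0
      llNew <- sum(log(tot))
      if (length(ll) && llNew < ll[length(ll)] - 1e-9 * max(1, abs(llNew)))
        stop("internal error: EM log-likelihood decreased")
      ll <- c(ll, llNew)
      Ez <- (w0z1 + w2z1) / tot
      # M-step f: mean posterior IBD mass per individual
      fNew <- pmin(pmax(colMeans(Ez), 0), 1)
      # M-step p: expected derived draws / expected total draws
      numP <- rowSums(w2z1 / tot + (w1z0 + 2 * w2z0) / tot)
      denP <- rowSums(Ez + 2 * (1 - Ez))
      pNew <- pmin(pmax(numP / denP, 1e-9), 1 - 1e-9)
      delta <- max(max(abs(fNew - f)), max(abs(pNew - p)))
      f <- fNew; p <- pNew
      if (delta < tol) { converged <- TRUE; break }
    }
    list(p = p, f = f, ll = ll, iterations = it, converged = converged)
  }

  s1 <- emStage(p, f, maxIterStage1)
  s2 <- emStage(s1$p, s1$f, maxIterStage2)
  names(s2$f) <- gl@individuals
  structure(list(F = s2$f, minorFreq = s2$p,
                 loglik = c(s1$ll, s2$ll),
                 iterations = c(stage1 = s1$iterations, stage2 = s2$iterations),
                 converged = s2$converged),
            class = "InbreedingResult")
}

#' @export
print.InbreedingResult <- function(x, ...) {
  cat(sprintf("InbreedingResult: %d individuals, mean F = %.4f (%s, %d + %d EM iterations)\n",
              length(x$F), mean(x$F),
              if (x$converged) "converged" else "NOT converged",
              x$iterations[1], x$iterations[2]))
  invisible(x)
}
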