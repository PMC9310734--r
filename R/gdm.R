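#' Order-2 monotone I-spline basis
#'
#' Three integrated (I-) splines of order 2 on knots `(q1, q2, q3)`
#' (defaults: the 0/50/100 percentiles of the observed distances). Each
#' basis function is 0 at `q1`, 1 at `q3`, and non-decreasing, so a
#' non-negative linear combination is a monotone transform:
#' \deqn{I_1 = 1 - ((q_2 - x)/(q_2 - q_1))^2 \textrm{ on } [q_1, q_2],\ 1
#' \textrm{ after};}
#' \deqn{I_2 = (x - q_1)^2 / ((q_3 - q_1)(q_2 - q_1)) \textrm{ on } [q_1, q_2],\
#' 1 - (q_3 - x)^2/((q_3 - q_1)(q_3 - q_2)) \textrm{ on } [q_2, q_3];}
#' \deqn{I_3 = ((x - q_2)/(q_3 - q_2))^2 \textrm{ on } [q_2, q_3],\ 0
#' \textrm{ before}.}
#' Values beyond the knot range are clamped to 0/1.
#'
#' @param x numeric predictor distances.
#' @param knots strictly increasing numeric of length 3; defaults to
#'   `quantile(x, c(0, 0.5, 1))`.
#' @return numeric matrix `length(x) x 3`.
#' @export
isplineBasis <- function(x, knots = NULL) {
  if (is.null(knots)) knots <- stats::quantile(x, c(0, 0.5, 1), names = FALSE)
  if (length(knots) != 3 || any(diff(knots) <= 0))
    stop("knots must be 3 strictly increasing values")
  q1 <- knots[1]; q2 <- knots[2]; q3 <- knots[3]
  xc <- pmin(pmax(x, q1), q3)
  b1 <- ifelse(xc <= q2, 1 - ((q2 - xc) / (q2 - q1))^2, 1)
  b2 <- ifelse(xc <= q2, (xc - q1)^2 / ((q3 - q1) * (q2 - q1)),
               1 - (q3 - xc)^2 / ((q3 - q1) * (q3 - q2)))
  b3 <- ifelse(xc <= q2, 0, ((xc - q2) / (q3 - q2))^2)
  cbind(b1, b2, b3)
}

# GDM binomial deviance of observed dissimilarities y against fitted mu
gdmDeviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# IRLS with a non-negative least squares inner step; X includes the
# intercept column; all coefficients constrained >= 0
gdmIRLS <- function(X, y, tol = 1e-8, maxIter = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- max(-log(1 - min(max(mean(y), 1e-6), 1 - 1e-6)), 1e-6)
  dev <- gdmDeviance(y, 1 - exp(-as.vector(X %*% beta)))
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 - exp(-eta)
    muc <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    dmu <- pmax(exp(-eta), 1e-9)              # d mu / d eta
    z <- eta + (y - mu) / dmu                 # working response
    w <- dmu^2 / (muc * (1 - muc))            # binomial working weights
    sw <- sqrt(w)
    betaNew <- tryCatch(pracma::lsqnonneg(X * sw, z * sw)$x,
                        error = function(e) beta)
    etaN <- as.vector(X %*% betaNew)
    devNew <- gdmDeviance(y, 1 - exp(-etaN))
    # step-halve towards the previous iterate if the deviance worsened
    half <- 0
    while (devNew > dev + 1e-12 && half < 20) {
      betaNew <- (betaNew + beta) / 2
      devNew <- gdmDeviance(y, 1 - exp(-as.vector(X %*% betaNew)))
      half <- half + 1
    }
    done <- abs(dev - devNew) < tol * (abs(dev) + tol)
    beta <- betaNew; dev <- devNew
    if (done) { converged <- TRUE; break }
  }
  list(beta = beta, deviance = dev, converged = converged)
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise dissimilarity as `mu = 1 - exp(-eta)` with
#' `eta = intercept + sum_j sum_k beta_jk I_k(d_j)`, where `I_k` are the
#' three monotone I-spline bases of predictor `j`'s distances and all
#' coefficients (intercept included) are constrained non-negative —
#' guaranteeing predicted dissimilarity is non-decreasing in every
#' predictor. Fitting maximizes the binomial deviance objective by
#' iteratively re-weighted non-negative least squares; the percent deviance
#' explained is reported against the intercept-only null.
#'
#' @param Y response [DistanceMatrix-class] with values in `[0, 1)` (e.g.
#'   pairwise FST).
#' @param predictors named list of predictor matrices over the same labels.
#' @param knots optional named list of 3-knot vectors per predictor.
#' @return A [GDMModel-class].
#' @export
gdmFit <- function(Y, predictors, knots = NULL) {
  if (!length(predictors)) stop("need at least one predictor")
  if (is.null(names(predictors))) names(predictors) <- paste0("X", seq_along(predictors))
  labels <- rownames(if (is(Y, "DistanceMatrix")) Y@values else Y)
  ymat <- alignTo(Y, labels)
  lt <- lower.tri(ymat)
  y <- ymat[lt]
  if (any(y < 0) || any(y >= 1)) stop("response dissimilarities must lie in [0, 1)")

  xv <- lapply(predictors, function(m) alignTo(m, labels)[lt])
  kts <- lapply(seq_along(xv), function(j) {
    k <- if (!is.null(knots)) knots[[names(predictors)[j]]] else NULL
    if (is.null(k)) stats::quantile(xv[[j]], c(0, 0.5, 1), names = FALSE) else k
  })
  names(kts) <- names(predictors)
  bad <- vapply(kts, function(k) any(diff(k) <= 0), logical(1))
  if (any(bad)) stop("constant predictor distances (degenerate knots): ",
                     paste(names(predictors)[bad], collapse = ", "))
  B <- do.call(cbind, lapply(seq_along(xv), function(j) isplineBasis(xv[[j]], kts[[j]])))
  X <- cbind(1, B)

  fit <- gdmIRLS(X, y)
  null <- gdmIRLS(matrix(1, length(y), 1), y)
  devExp <- if (null$deviance <= 1e-12) 0 else 100 * (1 - fit$deviance / null$deviance)
  devExp <- min(max(devExp, 0), 100)
  coefs <- matrix(pmax(fit$beta[-1], 0), nrow = 3,
                  dimnames = list(paste0("spline", 1:3), names(predictors)))
  new("GDMModel", intercept = max(fit$beta[1], 0), coefficients = coefs,
      knots = kts, devianceExplained = devExp,
      importance = data.frame(), history = list(), converged = fit$converged)
}

#' Predict GDM dissimilarities
#'
#' @param model a [GDMModel-class].
#' @param newdata named list of predictor distance vectors (or matrices),
#'   one per model predictor.
#' @return numeric vector of predicted dissimilarities in `[0, 1)`.
#' @export
gdmPredict <- function(model, newdata) {
  preds <- colnames(model@coefficients)
  eta <- model@intercept
  for (j in seq_along(preds)) {
    x <- newdata[[preds[j]]]
    if (is.null(x)) stop("newdata lacks predictor '", preds[j], "'")
    if (is.matrix(x) || is(x, "DistanceMatrix")) {
      x <- if (is(x, "DistanceMatrix")) x@values else x
      x <- x[lower.tri(x)]
    }
    eta <- eta + as.vector(isplineBasis(x, model@knots[[preds[j]]]) %*% model@coefficients[, j])
  }
  1 - exp(-eta)
}

setMethod("show", "GDMModel", function(object) {
  cat(sprintf("GDMModel: %d predictors, %.2f%% deviance explained%s\n",
              ncol(object@coefficients), object@devianceExplained,
              if (object@converged) "" else " [NOT converged]"))
  cat("  intercept:", signif(object@intercept, 4), "\n")
  print(round(object@coefficients, 4))
  if (nrow(object@importance)) {
    cat("  final importance:\n"); print(object@importance)
  }
  invisible(object)
})

#' @describeIn gdmFit percent deviance explained.
#' @param x a `GDMModel`.
#' @export
setGeneric("devianceExplained", function(x) standardGeneric("devianceExplained"))

#' @export
setMethod("devianceExplained", "GDMModel", function(x) x@devianceExplained)

#' Backward elimination of GDM predictors with permutation importance
#'
#' Per round, each predictor's unique contribution is the mean drop in
#' percent deviance explained when that predictor's matrix is jointly
#' row/column permuted (the others held fixed); its p-value is the
#' proportion of permutations in which the permuted-model deviance
#' explained reaches the observed one. If any retained predictor is
#' non-significant, the least-contributing predictor is dropped and the
#' model refitted; elimination stops when all retained predictors are
#' significant at `alpha` or one predictor remains.
#'
#' @param Y response [DistanceMatrix-class] in `[0, 1)`.
#' @param predictors named list of >= 2 predictor matrices.
#' @param nPerm permutations per predictor and round.
#' @param alpha significance level for retention.
#' @param seed integer seed.
#' @return A [GDMModel-class] whose `importance` slot holds the final
#'   per-predictor importance table and `history` the per-round tables.
#' @export
gdmBackwardElimination <- function(Y, predictors, nPerm = 500, alpha = 0.05, seed = 1) {
  if (length(predictors) < 2) stop("need at least 2 predictors to eliminate")
  if (is.null(names(predictors))) names(predictors) <- paste0("X", seq_along(predictors))
  labels <- rownames(if (is(Y, "DistanceMatrix")) Y@values else Y)
  n <- length(labels)
  mats <- lapply(predictors, alignTo, labels = labels)
  seeds <- subSeeds(seed, length(predictors) * nPerm * length(predictors) + 10)

  history <- list()
  keep <- names(predictors)
  round <- 0L
  repeat {
    round <- round + 1L
    full <- gdmFit(Y, mats[keep])
    obs <- full@devianceExplained
    tab <- data.frame(predictor = keep, importance = NA_real_, p = NA_real_)
    permDev <- withSeed(seeds[round], {
      lapply(keep, function(nm) {
        vapply(seq_len(nPerm), function(i) {
          pm <- sample.int(n)
          m2 <- mats[keep]
          m2[[nm]] <- permuteMatrix(m2[[nm]], pm)
          fit <- tryCatch(gdmFit(Y, m2), error = function(e) NULL)
          if (is.null(fit)) NA_real_ else fit@devianceExplained
        }, numeric(1))
      })
    })
    for (j in seq_along(keep)) {
      pd <- permDev[[j]][!is.na(permDev[[j]])]
      tab$importance[j] <- obs - mean(pd)
      tab$p[j] <- mean(pd >= obs - 1e-12)
    }
    history[[round]] <- tab
    if (all(tab$p < alpha) || length(keep) == 1L) break
    dropIdx <- which.min(tab$importance)
    keep <- keep[-dropIdx]
  }
  if (length(keep) == 0L) {
    warning("all predictors eliminated; returning intercept-only model")
    keep <- names(predictors)[1]
  }
  final <- gdmFit(Y, mats[keep])
  final@importance <- history[[length(history)]]
  final@history <- history
  final
}
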