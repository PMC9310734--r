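locFixture <- function(n = 5, seed = 60) {
  withr::with_seed(seed, {
    data.frame(locality = sprintf("P%d", 1:n),
               lon = runif(n, -79, -78), lat = runif(n, -1, 0))
  })
}

test_that("geographic distances use the haversine closed form", {
  df <- data.frame(locality = c("a", "b", "c"), lon = c(0, 0, 10), lat = c(0, 1, 20))
  D <- values(geographicDistanceMatrix(df))
  expect_equal(D["a", "b"], 111.195, tolerance = 1e-4)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_identical(kind(geographicDistanceMatrix(df)), "IBD")
})

test_that("log transform substitutes half the minimum positive distance for zeros", {
  df <- data.frame(individual = c("a", "b", "c"), lon = c(0, 0, 1), lat = c(0, 0, 0))
  expect_warning(D <- geographicDistanceMatrix(df, level = "individual",
                                               logTransform = TRUE),
                 "zero distances replaced")
  half <- haversineKm(0, 0, 1, 0) / 2
  expect_equal(values(D)["a", "b"], log(half), tolerance = 1e-9)
  expect_equal(unname(diag(values(D))), rep(0, 3))
})

test_that("environmental distances are raw Euclidean and order-invariant", {
  env <- data.frame(bio1 = c(1, 2), bio2 = c(2, 2), bio12 = c(3, 3), bio15 = c(4, 4),
                    row.names = c("A", "B"))
  D <- environmentalDistanceMatrix(env)
  expect_equal(values(D)["A", "B"], 1)
  expect_identical(kind(D), "IBE")
  perm <- environmentalDistanceMatrix(env[, c(3, 1, 4, 2)])
  expect_equal(values(perm), values(D))
  env$bio1[2] <- NA
  expect_error(environmentalDistanceMatrix(env), "missing environmental values.*B")
})

test_that("FST normalization is x / (1 - x)", {
  m <- matrix(c(0, 0.5, 0.661, 0.5, 0, 0, 0.661, 0, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  norm <- normalizeFst(distanceMatrix(m, "FST"))
  expect_equal(values(norm)["a", "b"], 1.0)
  expect_equal(values(norm)["a", "c"], 0.661 / (1 - 0.661), tolerance = 1e-4)
  expect_equal(values(norm)["a", "c"], 1.9499, tolerance = 1e-4)
  expect_equal(unname(diag(values(norm))), rep(0, 3))
  m[1, 2] <- m[2, 1] <- 1
  expect_error(normalizeFst(distanceMatrix(m, "FST")), "\\[0, 1\\)")
})

test_that("Mantel r is 1 on self-comparison and scale-invariant", {
  df <- locFixture(6)
  X <- geographicDistanceMatrix(df)
  r1 <- mantelTest(X, X, nPerm = 99, seed = 1)
  expect_equal(r1$r, 1)
  set.seed(2)
  Y <- distanceMatrix(as.matrix(dist(matrix(rnorm(12), 6))), "genetic",
                      labels = rownames(values(X)))
  a <- mantelTest(X, Y, nPerm = 199, seed = 3)
  b <- mantelTest(X, Y, nPerm = 199, standardizeByMean = TRUE, seed = 3)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p)
})

test_that("exhaustive Mantel on 4 labels gives the minimal p of 1/24", {
  df <- locFixture(4, seed = 61)
  X <- geographicDistanceMatrix(df)
  r <- mantelTest(X, X, exhaustive = TRUE)
  expect_equal(r$p, 1 / 24)
  expect_equal(r$nPerm, 24)
})

test_that("matrices are aligned by label, not position", {
  df <- locFixture(5, seed = 62)
  X <- geographicDistanceMatrix(df)
  shuffled <- values(X)[c(3, 1, 5, 2, 4), c(3, 1, 5, 2, 4)]
  r <- mantelTest(X, distanceMatrix(shuffled, "IBD"), nPerm = 49, seed = 1)
  expect_equal(r$r, 1)
})

test_that("sampled Mantel p agrees with vegan and with the exhaustive value", {
  skip_if_not_installed("vegan")
  df <- locFixture(6, seed = 63)
  X <- values(geographicDistanceMatrix(df))
  withr::with_seed(64, {
    pts <- cbind(df$lon, df$lat) + matrix(rnorm(12, 0, 0.1), 6)
  })
  Y <- as.matrix(dist(pts)); dimnames(Y) <- dimnames(X)
  ours <- mantelTest(distanceMatrix(X, "IBD"), distanceMatrix(Y, "genetic"),
                     nPerm = 999, seed = 65)
  veg <- vegan::mantel(X, Y, permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  exh <- mantelTest(distanceMatrix(X, "IBD"), distanceMatrix(Y, "genetic"),
                    exhaustive = TRUE)
  se <- sqrt(exh$p * (1 - exh$p) / 999)
  expect_lt(abs(ours$p - exh$p), 3 * se + 1e-3)
})

test_that("constant matrices are rejected", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  expect_error(mantelTest(distanceMatrix(m), distanceMatrix(m)), "constant")
})

test_that("MMRR recovers exact linear structure and the OLS oracle", {
  df <- locFixture(7, seed = 66)
  X <- geographicDistanceMatrix(df)
  Y <- distanceMatrix(3 * values(X), "genetic")
  fit <- mmrr(Y, list(IBD = X), nPerm = 99, seed = 1)
  expect_equal(unname(fit$coefficients["IBD"]), 1, tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)

  # closed-form least squares on the unfolded z-scored vectors
  set.seed(67)
  Z1 <- as.matrix(dist(matrix(rnorm(14), 7))); dimnames(Z1) <- dimnames(values(X))
  Z2 <- as.matrix(dist(matrix(rnorm(14), 7))); dimnames(Z2) <- dimnames(values(X))
  Yv <- values(X) + 2 * Z1 + matrix(0, 7, 7)
  Y2 <- distanceMatrix(Yv, "genetic")
  fit2 <- mmrr(Y2, list(a = X, b = distanceMatrix(Z1), c = distanceMatrix(Z2)),
               nPerm = 49, seed = 2)
  lt <- lower.tri(Yv)
  zs <- function(v) (v - mean(v)) / sd(v)
  Xmat <- cbind(1, zs(values(X)[lt]), zs(Z1[lt]), zs(Z2[lt]))
  beta <- solve(crossprod(Xmat), crossprod(Xmat, zs(Yv[lt])))
  expect_equal(unname(fit2$coefficients), as.vector(beta), tolerance = 1e-10)

  # collinear predictors rejected
  expect_error(mmrr(Y2, list(a = X, b = distanceMatrix(2 * values(X), "IBD")),
                    nPerm = 9), "collinear")
})

test_that("MMRR type-I error is near nominal under the null", {
  hits <- 0L
  nRuns <- 200
  for (i in seq_len(nRuns)) {
    withr::with_seed(1000 + i, {
      p1 <- matrix(rnorm(16), 8); p2 <- matrix(rnorm(16), 8)
    })
    Y <- as.matrix(dist(p1)); X <- as.matrix(dist(p2))
    dimnames(Y) <- dimnames(X) <- list(letters[1:8], letters[1:8])
    fit <- mmrr(distanceMatrix(Y, "genetic"), list(x = distanceMatrix(X, "IBD")),
                nPerm = 99, seed = 2000 + i)
    hits <- hits + (fit$pCoef["x"] <= 0.05)
  }
  rate <- hits / nRuns
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("I-spline bases are 0 at min, 1 at max and monotone", {
  x <- seq(2, 10, length.out = 400)
  B <- isplineBasis(x, knots = c(2, 5, 10))
  expect_equal(unname(B[1, ]), c(0, 0, 0))
  expect_equal(unname(B[400, ]), c(1, 1, 1))
  expect_true(all(diff(B[, 1]) >= -1e-12))
  expect_true(all(diff(B[, 2]) >= -1e-12))
  expect_true(all(diff(B[, 3]) >= -1e-12))
  expect_true(all(B >= 0 & B <= 1))
  expect_error(isplineBasis(x, knots = c(2, 2, 10)), "strictly increasing")
})
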