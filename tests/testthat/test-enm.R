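test_that("AUC equals brute-force pair counting, including ties", {
  # printed example: presences {0.9, 0.8, 0.4}, background {0.7, 0.3, 0.2}
  expect_equal(aucScore(c(.9, .8, .4), c(.7, .3, .2)), 8 / 9, tolerance = 1e-12)
  set.seed(20)
  for (rep in 1:5) {
    pos <- round(runif(30), 1); neg <- round(runif(40), 1)   # forced ties
    expect_equal(aucScore(pos, neg), oracleAUC(pos, neg), tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC = TSS = 1; identical scores are null", {
  pos <- seq(0.6, 0.9, length.out = 10); neg <- seq(0.1, 0.5, length.out = 10)
  expect_equal(aucScore(pos, neg), 1)
  expect_equal(tssScore(pos, neg)$tss, 1)
  same <- rep(c(0.3, 0.5), 20)
  expect_equal(aucScore(same, same), 0.5)
  expect_lte(tssScore(same, same)$tss, 0.5)
})

test_that("suitability model separates a clustered niche and is deterministic", {
  b <- generateLandscape(32, 32, seed = 30)
  s <- trueSuitability(b)
  # sharpen the niche so presences are separable from background
  sharp <- geoRaster(values(s)^8 / max(values(s)^8), extent(s))
  occ <- generateOccurrences(sharp, 150, seed = 31)
  fit1 <- fitSuitability(occ, b$bioclim, nBackground = 1500, reps = 3, seed = 32)
  fit2 <- fitSuitability(occ, b$bioclim, nBackground = 1500, reps = 3, seed = 32)
  expect_identical(fit1@coefficients, fit2@coefficients)
  expect_gt(mean(meta(fit1)$validationAUC), 0.9)
  pred <- predictSuitability(fit1, b$bioclim)
  expect_true(all(values(pred) >= 0 & values(pred) <= 1))
  expect_identical(values(pred), values(predictSuitability(fit2, b$bioclim)))
  # predicted suitability tracks the generating truth
  expect_gt(cor(as.vector(values(pred)), as.vector(values(sharp))), 0.6)
})

test_that("prediction equals the manual replicate-mean formula cellwise", {
  b <- generateLandscape(16, 16, seed = 33)
  occ <- generateOccurrences(trueSuitability(b), 60, seed = 34)
  fit <- fitSuitability(occ, b$bioclim, nBackground = 300, reps = 4, seed = 35)
  glacial <- b$epochs$glacial
  pred <- predictSuitability(fit, glacial)
  X <- vapply(glacial[fit@layerNames], function(r) as.vector(values(r)),
              numeric(256))
  Z <- sweep(sweep(X, 2, fit@center), 2, fit@scale, `/`)
  FX <- cbind(1, Z, Z^2)
  manual <- rowMeans(1 / (1 + exp(-FX %*% t(fit@coefficients))))
  expect_equal(as.vector(values(pred)), manual, tolerance = 1e-12)
  # averaged prediction lies inside the per-replicate envelope
  perRep <- 1 / (1 + exp(-FX %*% t(fit@coefficients)))
  expect_true(all(values(pred) >= apply(perRep, 1, min) - 1e-12))
  expect_true(all(values(pred) <= apply(perRep, 1, max) + 1e-12))
  expect_error(predictSuitability(fit, glacial[1:3]), "missing layers")
})

test_that("evaluation on separable synthetic data reports high AUC and TSS", {
  b <- generateLandscape(32, 32, seed = 36)
  s <- trueSuitability(b)
  sharp <- geoRaster(values(s)^8 / max(values(s)^8), extent(s))
  occ <- generateOccurrences(sharp, 120, seed = 37)
  fit <- fitSuitability(occ[1:90, ], b$bioclim, nBackground = 1000, reps = 3, seed = 38)
  low <- which(values(sharp) < 0.01, arr.ind = TRUE)
  ctr <- cellCenters(s)
  nbg <- min(200, nrow(low))
  bg <- data.frame(lon = ctr$lon[low][seq_len(nbg)], lat = ctr$lat[low][seq_len(nbg)])
  ev <- evaluateModel(fit, occ[91:120, ], bg, b$bioclim)
  expect_gt(ev$auc, 0.9)
  expect_gt(ev$tss, 0.6)
  expect_error(evaluateModel(fit, occ[1:3, ], bg, b$bioclim), "at least 5")
})

test_that("spatial blocks partition points with the south/west tie rule", {
  set.seed(40)
  pts <- data.frame(lon = runif(400), lat = runif(400))
  cv <- spatialBlockCV(pts, extent = c(0, 1, 0, 1), seed = 41)
  idx <- sort(unlist(lapply(cv$folds, `[[`, "test")))
  expect_identical(idx, 1:400)                      # disjoint and exhaustive
  expect_true(all(table(cv$fold) >= 70 & table(cv$fold) <= 130))
  for (f in cv$folds) expect_identical(sort(c(f$test, f$train)), 1:400)
  # points exactly on internal boundaries belong to the south/west block:
  # (0.5, 0.2), (0.2, 0.5) and (0.5, 0.5) all land with (0.2, 0.2)
  bp <- data.frame(lon = c(0.5, 0.2, 0.5, 0.2, 0.8), lat = c(0.2, 0.5, 0.5, 0.2, 0.8))
  cvb <- spatialBlockCV(bp, extent = c(0, 1, 0, 1), seed = 1)
  expect_equal(cvb$fold[1:3], rep(cvb$fold[4], 3))
  expect_false(cvb$fold[5] == cvb$fold[4])
  expect_error(spatialBlockCV(pts, k = 5), "k = 4")
})

test_that("MESS matches its piecewise definition", {
  ref <- data.frame(v = 1:100)
  target <- function(x) list(v = gridRaster(matrix(x, 8, 8)))
  atVal <- function(x) values(messSurface(ref, target(x)))[1, 1]
  expect_equal(atVal(50.5), 100)          # median: f = 50 -> 2f = 100
  expect_equal(atVal(1), 0)               # reference minimum -> 0
  expect_lt(atVal(0.5), 0)                # below the reference range -> negative
  expect_lt(atVal(150), 0)                # above the range (via 100(max-v)/(max-min))
  expect_equal(atVal(25.5), 50)           # f = 25 -> 2f
  expect_equal(atVal(75.5), 50)           # f = 75 -> 2(100 - f)
  # multivariate: minimum over variables; in-range iff all variables in range
  ref2 <- data.frame(a = 1:100, b = 51:150)
  t2 <- list(a = gridRaster(matrix(60, 8, 8)), b = gridRaster(matrix(40, 8, 8)))
  m <- values(messSurface(ref2, t2))[1, 1]
  expect_lt(m, 0)                         # b is out of range
  expect_warning(messSurface(data.frame(a = 1:10, c = rep(1, 10)),
                             list(a = gridRaster(matrix(5, 8, 8)),
                                  c = gridRaster(matrix(1, 8, 8)))),
                 "constant")
})

test_that("MESS is non-negative exactly when all variables are within range", {
  set.seed(42)
  ref <- data.frame(a = runif(50), b = runif(50, 10, 20))
  va <- runif(64, -0.5, 1.5); vb <- runif(64, 5, 25)
  tl <- list(a = gridRaster(matrix(va, 8, 8)), b = gridRaster(matrix(vb, 8, 8)))
  m <- as.vector(values(messSurface(ref, tl)))
  inRange <- va >= min(ref$a) & va <= max(ref$a) & vb >= min(ref$b) & vb <= max(ref$b)
  expect_identical(m >= 0, inRange)
})

test_that("habitat stability is the epoch mean, order-invariant and enveloped", {
  r1 <- gridRaster(matrix(c(1, 0, 0.9, 0.2), 8, 8))
  r2 <- gridRaster(matrix(c(1, 0, 0.6, 0.5), 8, 8))
  r3 <- gridRaster(matrix(c(1, 0, 0.3, 0.8), 8, 8))
  st <- habitatStability(list(r1, r2, r3))
  expect_equal(values(st)[1, 1], 1)
  expect_equal(values(st)[2, 1], 0)
  expect_equal(values(st)[3, 1], 0.6)
  st2 <- habitatStability(list(r3, r1, r2))
  expect_equal(values(st), values(st2))
  mn <- pmin(values(r1), values(r2), values(r3))
  mx <- pmax(values(r1), values(r2), values(r3))
  expect_true(all(values(st) >= mn - 1e-12 & values(st) <= mx + 1e-12))
  expect_error(habitatStability(list(r1, gridRaster(matrix(0.5, 9, 9)))), "misaligned")
})
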