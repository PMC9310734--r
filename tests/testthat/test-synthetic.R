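test_that("landscape generation is a pure function of its seed", {
  a <- generateLandscape(16, 16, seed = 5)
  b <- generateLandscape(16, 16, seed = 5)
  expect_identical(a$elevation@values, b$elevation@values)
  expect_identical(a$epochs$glacial$bio12@values, b$epochs$glacial$bio12@values)
  c <- generateLandscape(16, 16, seed = 6)
  expect_false(identical(a$elevation@values, c$elevation@values))
})

test_that("roughness 0 gives a flat landscape and zero TRI downstream", {
  b <- generateLandscape(16, 16, roughness = 0, seed = 1)
  expect_equal(diff(range(b$elevation@values)), 0)
  tri <- terrainRuggedness(b$elevation)
  expect_equal(max(tri@values), 0)
})

test_that("temperature layer is strongly anticorrelated with elevation", {
  b <- generateLandscape(64, 64, seed = 3)
  r <- cor(as.vector(b$bioclim$bio1@values), as.vector(b$elevation@values))
  expect_lt(r, -0.8)
})

test_that("landscape rejects invalid shapes and extents", {
  expect_error(generateLandscape(4, 64), "at least 8 x 8")
  expect_error(generateLandscape(16, 16, extent = c(-200, -100, 0, 1)), "extent")
})

test_that("epoch layers are the recorded monotone transforms of current", {
  off <- list(temp = c(current = 0, mid = -2, glacial = -5),
              precip = c(current = 1, mid = 0.9, glacial = 0.7))
  b <- generateLandscape(16, 16, seed = 2, epochOffsets = off)
  expect_equal(b$epochs$glacial$bio1@values, b$bioclim$bio1@values - 5)
  expect_equal(b$epochs$mid$bio12@values, b$bioclim$bio12@values * 0.9)
})

test_that("occurrences respect count, bounds and the suitability law", {
  b <- generateLandscape(24, 24, seed = 9)
  s <- trueSuitability(b)
  occ <- generateOccurrences(s, 200, seed = 4)
  expect_equal(nrow(occ), 200)
  e <- s@extent
  expect_true(all(occ$lon >= e[1] & occ$lon <= e[2] & occ$lat >= e[3] & occ$lat <= e[4]))
  expect_identical(occ, generateOccurrences(s, 200, seed = 4))

  # degenerate: a single nonzero cell receives every point
  m <- matrix(0, 8, 8); m[3, 5] <- 1
  one <- gridRaster(m)
  o1 <- generateOccurrences(one, 50, seed = 1)
  rc <- cellFromLonLat(one, o1$lon, o1$lat)
  expect_true(all(rc[, "row"] == 3 & rc[, "col"] == 5))
  expect_error(generateOccurrences(gridRaster(matrix(0, 8, 8)), 10), "zero everywhere")

  # two-level suitability: 0.9 vs 0.1 over equal areas -> 9:1 cell counts
  m2 <- matrix(0.1, 20, 20); m2[, 1:10] <- 0.9
  r2 <- gridRaster(m2)
  o2 <- generateOccurrences(r2, 2000, seed = 8)
  rc2 <- cellFromLonLat(r2, o2$lon, o2$lat)
  nHigh <- sum(rc2[, "col"] <= 10)
  gof <- suppressWarnings(chisq.test(c(nHigh, 2000 - nHigh), p = c(0.9, 0.1)))
  expect_gt(gof$p.value, 0.001)
})

test_that("locality layout has exactly one close pair and exact centroids", {
  b <- generateLandscape(48, 48, seed = 7)
  loc <- placeLocalities(b$elevation, 5, 13, minSepKm = 20, nearPairKm = 12, seed = 3)
  D <- values(geographicDistanceMatrix(loc))
  off <- D[lower.tri(D)]
  expect_equal(sum(off < 12), 1L)
  expect_true(all(off[off >= 12] > 20))
  ctr <- centroids(loc); sh <- samples(loc)
  for (k in seq_len(nrow(ctr))) {
    mem <- sh[sh$locality == ctr$locality[k], ]
    expect_lt(abs(mean(mem$lon) - ctr$lon[k]), 1e-9)
    expect_lt(abs(mean(mem$lat) - ctr$lat[k]), 1e-9)
    # members within ~1 km of the locality center
    expect_lt(max(haversineKm(mem$lon, mem$lat, ctr$lon[k], ctr$lat[k])), 1.2)
  }
  expect_identical(samples(placeLocalities(b$elevation, 5, 13, seed = 3)), sh)
  expect_error(placeLocalities(b$elevation, 2, 5), "at least 3")
})

test_that("certain-genotype limit: huge depth recovers truth at every covered site", {
  tr <- metapopulationTruth(1, 6, fstTarget = 0, nSites = 300, depthMean = 1e4,
                            errorRate = 0, seed = 2)
  sim <- simulateGenotypeLikelihoods(tr)
  gl <- sim$gl@gl
  called <- apply(gl, c(1, 2), which.max) - 1L
  covered <- sim$depth > 0
  expect_equal(called[covered], unname(sim$genotypes[covered]))
})

test_that("inbreeding controls the heterozygote fraction (2pq(1-f))", {
  tr <- metapopulationTruth(1, 30, fstTarget = 0, nSites = 4000, inbreeding = 0.5,
                            ancestralFreqs = rep(0.5, 4000), seed = 3)
  sim <- simulateGenotypeLikelihoods(tr)
  hetFrac <- mean(sim$genotypes == 1)
  expect_equal(hetFrac, 0.25, tolerance = 0.03)
})

test_that("Balding-Nichols frequencies have variance F p (1 - p)", {
  p0 <- 0.4; Fst <- 0.2
  tr <- metapopulationTruth(200, 1, fstTarget = Fst, nSites = 500,
                            ancestralFreqs = rep(p0, 500), seed = 5)
  sim <- simulateGenotypeLikelihoods(tr)
  v <- mean(apply(sim$popFreqs, 1, var))
  expect_equal(v, Fst * p0 * (1 - p0), tolerance = 0.15 * Fst * p0 * (1 - p0))
})

test_that("Hudson FST on true genotypes recovers the Balding-Nichols target", {
  tr <- metapopulationTruth(2, 20, fstTarget = 0.2, nSites = 50000, seed = 6)
  sim <- simulateGenotypeLikelihoods(tr)
  fst <- oracleHudsonFst(sim$genotypes[, 1:20], sim$genotypes[, 21:40])
  expect_equal(fst, 0.2, tolerance = 0.1)  # 0.2 +- 0.02
})

test_that("likelihood-weighted dosage converges to truth as depth grows", {
  mad <- vapply(c(2, 100), function(dep) {
    tr <- metapopulationTruth(1, 10, fstTarget = 0, nSites = 2000, depthMean = dep, seed = 8)
    sim <- simulateGenotypeLikelihoods(tr)
    gl <- sim$gl@gl
    tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
    eDos <- (gl[, , 2] + 2 * gl[, , 3]) / tot
    mean(abs(eDos - sim$genotypes))
  }, numeric(1))
  expect_lt(mad[2], mad[1] / 4)
  expect_lt(mad[2], 0.02)
})

test_that("withheld ancestral labels mark the set folded and flip dosages consistently", {
  tr <- metapopulationTruth(1, 5, fstTarget = 0, nSites = 500, depthMean = 1e4,
                            errorRate = 0, withholdAncestral = TRUE, seed = 9)
  sim <- simulateGenotypeLikelihoods(tr)
  expect_identical(sim$gl@polarization, "folded")
  called <- apply(sim$gl@gl, c(1, 2), which.max) - 1L
  covered <- sim$depth > 0
  expect_equal(called[covered], unname(sim$genotypes[covered]))
})

test_that("truth JSON round trip regenerates the identical dataset", {
  tr <- metapopulationTruth(2, 4, fstTarget = 0.1, nSites = 200, seed = 11)
  p <- tempfile(fileext = ".json")
  writeTruthJson(tr, p)
  tr2 <- readTruthJson(p)
  s1 <- simulateGenotypeLikelihoods(tr)
  s2 <- simulateGenotypeLikelihoods(tr2)
  expect_identical(s1$gl@gl, s2$gl@gl)
  expect_identical(s1$genotypes, s2$genotypes)
})
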