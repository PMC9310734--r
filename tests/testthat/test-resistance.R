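test_that("TRI is zero on flat terrain and matches the hand-computed case", {
  expect_equal(max(values(terrainRuggedness(flatRaster(8, 100)))), 0)
  m <- matrix(10, 5, 5)
  m[2, 3] <- 13                          # one neighbour of (3,3) raised by 3 m
  tri <- terrainRuggedness(gridRaster(m))
  expect_equal(values(tri)[3, 3], 3)     # sqrt(3^2)
  # translation invariance
  tri2 <- terrainRuggedness(gridRaster(m + 500))
  expect_equal(values(tri), values(tri2))
  expect_error(terrainRuggedness(gridRaster(matrix(NA_real_, 4, 4))), "nodata")
  expect_error(terrainRuggedness(gridRaster(matrix(1, 2, 2))), "3 x 3")
})

test_that("TRI equals the direct 8-neighbour definition on random terrain", {
  set.seed(50)
  m <- matrix(rnorm(49, 100, 30), 7, 7)
  tri <- values(terrainRuggedness(gridRaster(m)))
  for (i in c(1, 4, 7)) for (j in c(1, 4, 7)) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (i + dr >= 1 && i + dr <= 7 && j + dc >= 1 && j + dc <= 7)
        nb <- c(nb, m[i + dr, j + dc])
    }
    expect_equal(tri[i, j], sqrt(sum((nb - m[i, j])^2)), tolerance = 1e-12)
  }
})

test_that("elevation mask applies the hull buffer and the +-100 m rule", {
  set.seed(51)
  elev <- matrix(runif(900, 0, 3000), 30, 30)
  r <- gridRaster(elev, cell = 0.05)
  occ <- data.frame(lon = c(0.3, 1.2, 0.7, 0.4, 1.1),
                    lat = c(0.3, 0.35, 1.2, 0.9, 0.8),
                    elev = c(500, 800, 2000, 1200, 1500))
  masked <- elevationMask(r, occ, hullBufferDeg = 0.2, elevMarginM = 100)
  v <- values(masked)
  kept <- which(!is.na(v), arr.ind = TRUE)
  expect_true(all(elev[kept] >= 400 & elev[kept] <= 2100))
  # a far-away cell is masked regardless of its elevation
  ctr <- cellCenters(r)
  # the NE corner cell is ~0.39 degrees from the nearest occurrence,
  # beyond the 0.2-degree buffer, so it must be masked whatever its elevation
  expect_true(is.na(extractAt(masked, ctr$lon[1, 30], ctr$lat[1, 30])))
  # maskBelow = FALSE keeps low cells
  m2 <- elevationMask(r, occ, hullBufferDeg = 0.2, elevMarginM = 100, maskBelow = FALSE)
  expect_gte(sum(!is.na(values(m2))), sum(!is.na(v)))
  low <- which(!is.na(values(m2)), arr.ind = TRUE)
  expect_true(all(elev[low] <= 2100))
  expect_error(elevationMask(r, occ[1:2, ]), "at least 3")
})

test_that("tier costs follow the occurrence quantile scheme (brute-force check)", {
  occTRI <- 1:100
  probe <- seq(-20, 160, length.out = 1000)
  r <- gridRaster(matrix(rep(probe, length.out = 1024), 32, 32))
  cost <- triCostSurface(r, occTRI)
  expect_identical(cost@provenance, "terrain-tier")
  v <- as.vector(values(cost))
  x <- as.vector(values(r))
  q <- quantile(occTRI, c(0, .05, .1, .15, .85, .9, .95, 1), names = FALSE)
  oracle <- ifelse(x < q[1] | x > q[8], 16,
            ifelse(x < q[2] | x > q[7], 8,
            ifelse(x < q[3] | x > q[6], 4,
            ifelse(x < q[4] | x > q[5], 2, 1))))
  expect_equal(v, oracle)
  expect_true(all(v %in% c(1, 2, 4, 8, 16)))
  # printed anchor cases
  at <- function(val) values(triCostSurface(gridRaster(matrix(val, 8, 8)), occTRI))[1, 1]
  expect_equal(at(50), 1)
  expect_equal(at(97), 8)
  expect_equal(at(150), 16)
  # occurrence cells themselves: ~70/10/10/10 tier frequencies
  occCost <- ifelse(occTRI < q[1] | occTRI > q[8], 16,
             ifelse(occTRI < q[2] | occTRI > q[7], 8,
             ifelse(occTRI < q[3] | occTRI > q[6], 4,
             ifelse(occTRI < q[4] | occTRI > q[5], 2, 1))))
  expect_equal(unname(table(occCost)["1"]) / 100, 0.70, tolerance = 0.03)
  # degenerate constant reference
  expect_warning(cd <- triCostSurface(gridRaster(matrix(c(5, 7), 8, 8)), rep(5, 25)),
                 "constant")
  expect_equal(sort(unique(as.vector(values(cd)))), c(1, 16))
})

test_that("suitability cost surface is 1 - suitability and involutive", {
  s <- gridRaster(matrix(seq(0, 1, length.out = 64), 8, 8))
  cost <- suitabilityCostSurface(s)
  expect_equal(values(cost), 1 - values(s))
  expect_equal(values(suitabilityCostSurface(geoRaster(values(cost), s@extent))),
               values(s), tolerance = 1e-12)
  expect_error(suitabilityCostSurface(gridRaster(matrix(2, 8, 8))), "\\[0, 1\\]")
})

test_that("transition graph has 16-degree interior, 5-degree corner nodes", {
  cost <- new("CostSurface", flatRaster(8, 1), provenance = "terrain-tier",
              tiers = data.frame())
  tg <- buildTransitionGraph(cost)
  deg <- igraph::degree(tg$graph)
  interior <- tg$nodeOfCell[4, 4]
  corner <- tg$nodeOfCell[1, 1]
  expect_equal(unname(deg[interior]), 16)
  expect_equal(unname(deg[corner]), 5)
  # doubling costs doubles all edge weights
  cost2 <- new("CostSurface", geoRaster(values(cost) * 2, cost@extent),
               provenance = "terrain-tier", tiers = data.frame())
  tg2 <- buildTransitionGraph(cost2)
  expect_equal(igraph::E(tg2$graph)$weight, 2 * igraph::E(tg$graph)$weight,
               tolerance = 1e-12)
})

test_that("straight corridor distance equals the haversine closed form", {
  m <- matrix(1, 1, 3)
  # 1x3 strip of 0.01-degree cells on the equator
  cost <- new("CostSurface", geoRaster(m, c(0, 0.03, -0.005, 0.005)),
              provenance = "terrain-tier", tiers = data.frame())
  tg <- buildTransitionGraph(cost)
  loc <- data.frame(locality = c("a", "b"), lon = c(0.005, 0.025), lat = 0)
  D <- values(leastCostDistances(tg, loc))
  expect_equal(D["a", "b"], 2 * haversineKm(0, 0, 0.01, 0), tolerance = 1e-9)
  expect_equal(D["a", "a"], 0)
})

test_that("least-cost distances equal the reference shortest-path oracle", {
  set.seed(52)
  for (rep in 1:4) {
    m <- matrix(sample(c(1, 2, 4, 8), 36, replace = TRUE), 6, 6)
    if (rep >= 3) { m[3, 1:4] <- NA }      # barrier row with one gap
    cost <- new("CostSurface", gridRaster(m), provenance = "terrain-tier",
                tiers = data.frame())
    tg <- buildTransitionGraph(cost)
    el <- igraph::as_edgelist(tg$graph)
    edges <- cbind(el, igraph::E(tg$graph)$weight)
    pass <- which(!is.na(tg$nodeOfCell))
    src <- tg$nodeOfCell[6, 1]
    ref <- oracleShortestPath(edges, igraph::vcount(tg$graph), src)
    got <- igraph::distances(tg$graph, v = src, to = igraph::V(tg$graph))
    expect_equal(as.vector(got), ref, tolerance = 1e-12)
  }
})

test_that("masking cells never decreases least-cost distances", {
  set.seed(53)
  m <- matrix(sample(c(1, 2, 4), 36, replace = TRUE), 6, 6)
  mkD <- function(mat) {
    cost <- new("CostSurface", gridRaster(mat), provenance = "terrain-tier",
                tiers = data.frame())
    tg <- buildTransitionGraph(cost)
    loc <- data.frame(locality = c("a", "b", "c"),
                      lon = c(0.005, 0.055, 0.035), lat = c(0.055, 0.005, 0.035))
    values(leastCostDistances(tg, loc))
  }
  D0 <- mkD(m)
  m2 <- m; m2[2:4, 3] <- NA
  D1 <- suppressWarnings(mkD(m2))
  expect_true(all(D1 - D0 >= -1e-9))
  # lower bound: distance >= great-circle x minimum cost
  gc <- values(geographicDistanceMatrix(data.frame(
    locality = c("a", "b", "c"),
    lon = c(0.005, 0.055, 0.035), lat = c(0.055, 0.005, 0.035))))
  expect_true(all(D0 >= gc * min(m) - 1e-9))
})

test_that("snapping rejects localities far from passable terrain", {
  m <- matrix(NA_real_, 8, 8); m[1, 1] <- 1; m[1, 2] <- 1
  cost <- new("CostSurface", gridRaster(m), provenance = "terrain-tier",
              tiers = data.frame())
  tg <- buildTransitionGraph(cost)
  far <- data.frame(locality = "far", lon = 0.075, lat = 0.005)   # SE corner
  expect_error(leastCostDistances(tg, far), "locality 'far'.*snap radius")
  near <- data.frame(locality = c("p", "q"), lon = c(0.005, 0.025), lat = 0.075)
  D <- values(leastCostDistances(tg, near))                        # snaps to row 1
  expect_gt(D["p", "q"], 0)
})
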