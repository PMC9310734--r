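#' Terrain ruggedness index
#'
#' `TRI(cell) = sqrt(sum over the 8 neighbours of (elev_n - elev_cell)^2)`
#' (sum-of-squared-differences form). Edge cells use their available
#' neighbours; nodata cells stay nodata and are skipped as neighbours.
#' `variant = "mean-abs"` switches to the mean absolute elevation
#' difference.
#'
#' @param elevation a [GeoRaster-class] of at least 3 x 3 cells.
#' @param variant `"riley"` (default, root of summed squares) or
#'   `"mean-abs"`.
#' @return A [GeoRaster-class] of TRI values.
#' @export
terrainRuggedness <- function(elevation, variant = c("riley", "mean-abs")) {
  stopifnot(is(elevation, "GeoRaster"))
  variant <- match.arg(variant)
  v <- elevation@values
  if (nrow(v) < 3 || ncol(v) < 3) stop("need at least a 3 x 3 grid")
  if (all(is.na(v))) stop("all cells are nodata")
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(0, nr, nc)
  nnb <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)      # destination rows
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    nb[rs, cs] <- v[rs - dr, cs - dc]
    d <- nb - v
    ok <- !is.na(d)
    if (variant == "riley") acc[ok] <- acc[ok] + d[ok]^2
    else acc[ok] <- acc[ok] + abs(d[ok])
    nnb[ok] <- nnb[ok] + 1
  }
  out <- if (variant == "riley") sqrt(acc) else acc / pmax(nnb, 1)
  out[is.na(v) | nnb == 0] <- NA_real_
  geoRaster(out, elevation@extent)
}

# planar point-in-convex-hull / distance-to-hull helpers (degree space)
hullContains <- function(hx, hy, px, py) {
  n <- length(hx)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & cross >= -1e-12
  }
  inside
}

distToSegments <- function(hx, hy, px, py) {
  n <- length(hx)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vx <- hx[j] - hx[i]; vy <- hy[j] - hy[i]
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(px)) else pmin(pmax(((px - hx[i]) * vx + (py - hy[i]) * vy) / len2, 0), 1)
    d2 <- pmin(d2, (px - (hx[i] + t * vx))^2 + (py - (hy[i] + t * vy))^2)
  }
  sqrt(d2)
}

#' Mask a raster to the buffered occurrence hull and elevation range
#'
#' Cells outside the convex hull of the occurrences buffered by
#' `hullBufferDeg` (closed hull: boundary cells are inside) are masked, as
#' are cells whose elevation falls more than `elevMarginM` below the lowest
#' or above the highest occurrence elevation. For stability (glacial-epoch)
#' surfaces the lower restriction is dropped (`maskBelow = FALSE`), since
#' elevation zones may have shifted downward.
#'
#' @param raster the [GeoRaster-class] to mask.
#' @param occurrences data.frame with `lon`, `lat` and optionally `elev`
#'   (extracted from `elevation` when absent); >= 3 non-collinear points.
#' @param elevation [GeoRaster-class] supplying cell and occurrence
#'   elevations (defaults to `raster`).
#' @param hullBufferDeg buffer around the convex hull, degrees.
#' @param elevMarginM elevation margin beyond the occurrence range, metres.
#' @param maskBelow apply the lower elevation restriction.
#' @return the masked [GeoRaster-class].
#' @export
elevationMask <- function(raster, occurrences, elevation = raster,
                          hullBufferDeg = 0.4, elevMarginM = 100, maskBelow = TRUE) {
  stopifnot(is(raster, "GeoRaster"))
  if (nrow(occurrences) < 3) stop("need at least 3 occurrences")
  hull <- grDevices::chull(occurrences$lon, occurrences$lat)
  if (length(hull) < 3) stop("occurrences are collinear; the hull is degenerate")
  hx <- occurrences$lon[hull]; hy <- occurrences$lat[hull]
  # chull returns clockwise order; hullContains expects counter-clockwise
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }

  ctr <- cellCenters(raster)
  px <- as.vector(ctr$lon); py <- as.vector(ctr$lat)
  inHull <- hullContains(hx, hy, px, py)
  near <- !inHull & distToSegments(hx, hy, px, py) <= hullBufferDeg + 1e-12
  keep <- matrix(inHull | near, nrow(raster@values), ncol(raster@values))

  occElev <- if ("elev" %in% names(occurrences)) occurrences$elev
             else extractAt(elevation, occurrences$lon, occurrences$lat)
  occElev <- occElev[!is.na(occElev)]
  if (!length(occElev)) stop("no occurrence has a defined elevation")
  ev <- elevation@values
  keep <- keep & !is.na(ev) & ev <= max(occElev) + elevMarginM
  if (maskBelow) keep <- keep & ev >= min(occElev) - elevMarginM

  out <- raster@values
  out[!keep] <- NA_real_
  if (all(is.na(out))) stop("masking removed every cell")
  geoRaster(out, raster@extent)
}

#' Tiered terrain cost surface from occurrence TRI quantiles
#'
#' Assigns resistance costs from the empirical (linear-interpolation)
#' quantiles of the TRI values at occurrence cells: cost 1 for the central
#' 70% (`[q15, q85]`), 2 for the adjacent 5% bands, 4 for the next 5%
#' bands, 8 for the outermost occupied bands (`[q0, q5)` and `(q95, q100]`),
#' and 16 outside the occupied TRI range entirely. Boundary ties resolve to
#' the cheaper tier. A constant occurrence TRI collapses all thresholds:
#' cells at that value cost 1 and all others 16 (warned).
#'
#' @param tri TRI [GeoRaster-class].
#' @param occurrenceTRI numeric TRI values at >= 20 occurrence cells.
#' @return A [CostSurface-class] (provenance `"terrain-tier"`) whose `tiers`
#'   slot records the thresholds.
#' @export
triCostSurface <- function(tri, occurrenceTRI) {
  stopifnot(is(tri, "GeoRaster"))
  occurrenceTRI <- occurrenceTRI[!is.na(occurrenceTRI)]
  if (length(occurrenceTRI) < 20) stop("need TRI values for at least 20 occurrences")
  q <- stats::quantile(occurrenceTRI, c(0, .05, .10, .15, .85, .90, .95, 1),
                       names = FALSE, type = 7)
  if (q[1] == q[8]) warning("occurrence TRI is constant; degenerate tier rule in effect")
  t <- tri@values
  cost <- matrix(16, nrow(t), ncol(t))
  cost[t >= q[1] & t <= q[8]] <- 8
  cost[t >= q[2] & t <= q[7]] <- 4
  cost[t >= q[3] & t <= q[6]] <- 2
  cost[t >= q[4] & t <= q[5]] <- 1
  cost[is.na(t)] <- NA_real_
  new("CostSurface", geoRaster(cost, tri@extent), provenance = "terrain-tier",
      tiers = data.frame(quantile = c(0, 5, 10, 15, 85, 90, 95, 100), tri = q))
}

#' Cost surface from a suitability or stability raster
#'
#' `cost = 1 - value`, so fully suitable (or stable) cells have zero
#' resistance and unsuitable cells resistance 1.
#'
#' @param suitability [GeoRaster-class] with values in `[0, 1]`.
#' @param provenance `"one-minus-suitability"` or `"one-minus-stability"`.
#' @return A [CostSurface-class].
#' @export
suitabilityCostSurface <- function(suitability, provenance = "one-minus-suitability") {
  stopifnot(is(suitability, "GeoRaster"))
  v <- suitability@values
  rng <- range(v, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) stop("suitability values must lie in [0, 1]")
  new("CostSurface", geoRaster(1 - v, suitability@extent),
      provenance = provenance, tiers = data.frame())
}

# the 16 knight-and-one-cell-queen moves; the first 8 rows form the
# non-redundant half used to enumerate each undirected edge once
moveOffsets <- function() {
  q <- cbind(dr = c(0, 1, 1, 1), dc = c(1, -1, 0, 1))
  k <- cbind(dr = c(1, 1, 2, 2), dc = c(-2, 2, -1, 1))
  rbind(q, k)
}

#' Build the 16-direction transition graph of a cost surface
#'
#' Nodes are passable (non-nodata) cells; edges connect the 8 queen and 8
#' knight ("knight and one-cell queen move") neighbours. Each edge weight is
#' the great-circle distance between the two cell centers (haversine,
#' Earth radius 6371 km) times the mean resistance of the two cells
#' (arithmetic by default; `edgeCost = "harmonic"` composes mean
#' conductance instead), floored at `epsilon` so zero-cost terrain yields
#' near-zero but positive weights.
#'
#' @param cost a [CostSurface-class] (or any non-negative [GeoRaster-class]).
#' @param epsilon lower floor of the mean edge resistance.
#' @param edgeCost `"mean"` (arithmetic mean resistance) or `"harmonic"`.
#' @return list of class `TransitionGraph`: `graph` (igraph, undirected,
#'   weighted, in km x resistance), `nodeOfCell` (matrix mapping cells to
#'   vertex ids, `NA` if impassable), `raster` (the cost surface).
#' @export
buildTransitionGraph <- function(cost, epsilon = 1e-6, edgeCost = c("mean", "harmonic")) {
  stopifnot(is(cost, "GeoRaster"))
  edgeCost <- match.arg(edgeCost)
  v <- cost@values
  nr <- nrow(v); nc <- ncol(v)
  pass <- !is.na(v)
  if (!any(pass)) stop("no passable cell")
  nodeOfCell <- matrix(NA_integer_, nr, nc)
  nodeOfCell[pass] <- seq_len(sum(pass))
  ctr <- cellCenters(cost)

  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (m in seq_len(8)) {
    dr <- moveOffsets()[m, 1]; dc <- moveOffsets()[m, 2]
    if (max(1, 1 - dr) > min(nr, nr - dr) || max(1, 1 - dc) > min(nc, nc - dc)) next
    rsrc <- max(1, 1 - dr):min(nr, nr - dr)
    csrc <- max(1, 1 - dc):min(nc, nc - dc)
    a <- as.vector(outer(rsrc, (csrc - 1) * nr, `+`))            # source cell index
    b <- a + dr + dc * nr                                        # destination cell index
    ok <- pass[a] & pass[b]
    a <- a[ok]; b <- b[ok]
    if (!length(a)) next
    dist <- haversineKm(ctr$lon[a], ctr$lat[a], ctr$lon[b], ctr$lat[b])
    res <- if (edgeCost == "mean") (v[a] + v[b]) / 2
           else 2 / (1 / pmax(v[a], epsilon) + 1 / pmax(v[b], epsilon))
    from <- c(from, nodeOfCell[a]); to <- c(to, nodeOfCell[b])
    w <- c(w, dist * pmax(res, epsilon))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, sum(pass) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  structure(list(graph = g, nodeOfCell = nodeOfCell, raster = cost,
                 epsilon = epsilon, edgeCost = edgeCost),
            class = "TransitionGraph")
}

#' @export
print.TransitionGraph <- function(x, ...) {
  cat(sprintf("TransitionGraph: %d passable cells, %d edges (16-direction, %s resistance)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$edgeCost))
  invisible(x)
}

# snap lon/lat points to the nearest passable cell within `radius` cells
# (measured in cell diagonals); errors naming the offending point
snapToPassable <- function(tg, lon, lat, labels, snapRadiusCells = 2) {
  r <- tg$raster
  rc <- cellFromLonLat(r, lon, lat)
  nr <- nrow(r@values); nc <- ncol(r@values)
  ctr <- cellCenters(r)
  out <- integer(length(lon))
  for (i in seq_along(lon)) {
    if (is.na(rc[i, 1])) stop("locality '", labels[i], "' lies outside the raster extent")
    row <- rc[i, 1]; col <- rc[i, 2]
    if (!is.na(tg$nodeOfCell[row, col])) { out[i] <- tg$nodeOfCell[row, col]; next }
    win <- ceiling(snapRadiusCells * sqrt(2))
    rows <- max(1, row - win):min(nr, row + win)
    cols <- max(1, col - win):min(nc, col + win)
    sub <- tg$nodeOfCell[rows, cols, drop = FALSE]
    cand <- which(!is.na(sub), arr.ind = TRUE)
    if (nrow(cand) == 0)
      stop("locality '", labels[i], "' is farther than the snap radius from any passable cell")
    dd <- (cand[, 1] + rows[1] - 1 - row)^2 + (cand[, 2] + cols[1] - 1 - col)^2
    best <- cand[which.min(dd), , drop = FALSE]
    if (min(dd) > (snapRadiusCells * sqrt(2))^2)
      stop("locality '", labels[i], "' is farther than the snap radius from any passable cell")
    out[i] <- sub[best]
  }
  out
}

#' Least-cost distances between localities
#'
#' Shortest-path (non-negative weights) distances on the transition graph
#' between the passable cells nearest to each locality centroid (snap
#' radius: `snapRadiusCells` cell diagonals). Unreachable pairs are
#' `Inf` and flagged.
#'
#' @param tg a [buildTransitionGraph()] result.
#' @param localities a [LocalityTable-class] or data.frame with `locality`,
#'   `lon`, `lat`.
#' @param kind kind tag of the returned matrix.
#' @param snapRadiusCells snapping radius in cell diagonals.
#' @return A [DistanceMatrix-class] (km x resistance units).
#' @export
leastCostDistances <- function(tg, localities, kind = "IBR_Terrain", snapRadiusCells = 2) {
  ctr <- if (is(localities, "LocalityTable")) localities@centroids else as.data.frame(localities)
  nodes <- snapToPassable(tg, ctr$lon, ctr$lat, ctr$locality, snapRadiusCells)
  D <- igraph::distances(tg$graph, v = nodes, to = nodes,
                         weights = igraph::E(tg$graph)$weight, algorithm = "dijkstra")
  dimnames(D) <- list(ctr$locality, ctr$locality)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (any(is.infinite(D)))
    warning("some locality pairs are unreachable (infinite least-cost distance)")
  distanceMatrix(D, kind = kind)
}
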