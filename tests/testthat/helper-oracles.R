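# independent oracles used across the suite; none of these call the package
# code paths they are checking

# histogram of per-site derived counts from certain genotypes
oracleSFSCounts <- function(g) {
  n <- 2 * ncol(g)
  tabulate(rowSums(g) + 1L, nbins = n + 1L)
}

# mean pairwise per-site differences over all haplotype pairs: a site with
# derived count d contributes d (n - d) differing pairs regardless of phase
oracleThetaPi <- function(g) {
  n <- 2 * ncol(g)
  d <- rowSums(g)
  sum(d * (n - d)) / choose(n, 2)
}

# exhaustive allele-frequency likelihood: enumerate all genotype
# configurations, weight by hypergeometric allele-assignment probabilities
oracleSiteAFLikelihood <- function(glTriples) {
  N <- nrow(glTriples)          # one row per individual: L(g=0), L(1), L(2)
  configs <- as.matrix(expand.grid(rep(list(0:2), N)))
  L <- numeric(2 * N + 1)
  for (r in seq_len(nrow(configs))) {
    gg <- configs[r, ]
    d <- sum(gg)
    w <- prod(choose(2, gg)) / choose(2 * N, d)
    lik <- prod(glTriples[cbind(seq_len(N), gg + 1)])
    L[d + 1] <- L[d + 1] + w * lik
  }
  L / max(L)
}

# reference single-source shortest paths by Bellman-Ford edge relaxation
oracleShortestPath <- function(edges, nVertices, source) {
  dist <- rep(Inf, nVertices)
  dist[source] <- 0
  for (iter in seq_len(nVertices)) {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]; w <- edges[r, 3]
      if (dist[a] + w < dist[b]) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a]) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# brute-force AUC: proportion of correctly ordered pairs, ties half
oracleAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Hudson FST directly from true genotype dosages of two populations
oracleHudsonFst <- function(g1, g2) {
  n1 <- 2 * ncol(g1); n2 <- 2 * ncol(g2)
  p1 <- rowSums(g1) / n1; p2 <- rowSums(g2) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# tiny deterministic raster helpers
flatRaster <- function(n = 8, value = 0, extent = c(0, n * 0.01, 0, n * 0.01)) {
  geoRaster(matrix(value, n, n), extent)
}

lowerTriOf <- function(dm) {
  v <- values(dm)
  v[lower.tri(v)]
}

gridRaster <- function(m, cell = 0.01, origin = c(0, 0)) {
  geoRaster(m, c(origin[1], origin[1] + ncol(m) * cell,
                 origin[2], origin[2] + nrow(m) * cell))
}
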