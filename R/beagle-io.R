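#' Write genotype likelihoods in beagle text format
#'
#' One row per site with header
#' `marker allele1 allele2 Ind0 Ind0 Ind0 Ind1 ...`; the three columns per
#' individual are the normalized likelihoods of 0, 1 and 2 copies of
#' `allele2`. Tab-separated.
#'
#' @param gl a [GenotypeLikelihoodSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBeagle <- function(gl, path) {
  stopifnot(is(gl, "GenotypeLikelihoodSet"))
  S <- length(gl@sites); N <- length(gl@individuals)
  m <- matrix(aperm(gl@gl, c(3, 2, 1)), nrow = S, ncol = 3 * N, byrow = TRUE)
  df <- data.table::data.table(marker = gl@sites,
                               allele1 = gl@alleles[, 1], allele2 = gl@alleles[, 2])
  glDT <- data.table::as.data.table(m)
  names(glDT) <- paste0(rep(gl@individuals, each = 3))
  out <- cbind(df, glDT)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a beagle genotype-likelihood file
#'
#' Accepts plain or gzip-compressed beagle text. Individual labels are taken
#' from the header (each appears three times); per-entry triples are
#' renormalized to maximum 1.
#'
#' @param path beagle file path (`.gz` allowed).
#' @param polarization `"unfolded"` or `"folded"` tag for downstream analyses.
#' @return A [GenotypeLikelihoodSet-class].
#' @export
readBeagle <- function(path, polarization = "unfolded") {
  dt <- if (grepl("\\.gz$", path)) {
    utils::read.table(gzfile(path), header = TRUE, sep = "\t", check.names = FALSE)
  } else {
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, check.names = FALSE))
  }
  if (ncol(dt) < 6 || (ncol(dt) - 3) %% 3 != 0)
    stop("malformed beagle file '", path, "': expected marker, allele1, allele2 + 3 columns per individual")
  sites <- as.character(dt[[1]])
  alleles <- cbind(as.character(dt[[2]]), as.character(dt[[3]]))
  dimnames(alleles) <- list(sites, c("major", "minor"))
  m <- as.matrix(dt[, -(1:3), drop = FALSE])
  storage.mode(m) <- "double"
  N <- ncol(m) / 3
  inds <- colnames(m)[seq(1, ncol(m), by = 3)]
  if (is.null(inds) || anyNA(inds)) inds <- sprintf("Ind%03d", seq_len(N))
  S <- nrow(m)
  gl <- array(0, dim = c(S, N, 3))
  for (k in 1:3) gl[, , k] <- m[, seq(k, ncol(m), by = 3), drop = FALSE]
  mx <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
  mx[mx == 0] <- 1
  for (k in 1:3) gl[, , k] <- gl[, , k] / mx
  new("GenotypeLikelihoodSet", gl = gl, sites = sites, alleles = alleles,
      individuals = inds, polarization = polarization)
}

#' Accessors for GenotypeLikelihoodSet
#'
#' @param x a `GenotypeLikelihoodSet`.
#' @name gl-accessors
NULL

#' @rdname gl-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setMethod("nSites", "GenotypeLikelihoodSet", function(x) length(x@sites))

#' @rdname gl-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @export
setMethod("nIndividuals", "GenotypeLikelihoodSet", function(x) length(x@individuals))

#' @rdname gl-accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @export
setMethod("individuals", "GenotypeLikelihoodSet", function(x) x@individuals)

#' @rdname gl-accessors
#' @export
setGeneric("siteIDs", function(x) standardGeneric("siteIDs"))

#' @export
setMethod("siteIDs", "GenotypeLikelihoodSet", function(x) x@sites)

#' @rdname gl-accessors
#' @export
setGeneric("genotypeLikelihoods", function(x) standardGeneric("genotypeLikelihoods"))

#' @export
setMethod("genotypeLikelihoods", "GenotypeLikelihoodSet", function(x) x@gl)

setMethod("show", "GenotypeLikelihoodSet", function(object) {
  cat(sprintf("GenotypeLikelihoodSet: %d sites x %d individuals (%s)\n",
              length(object@sites), length(object@individuals), object@polarization))
  invisible(object)
})

#' Subset a GenotypeLikelihoodSet
#'
#' @param x a `GenotypeLikelihoodSet`.
#' @param sites site IDs or indices to keep (`NULL` keeps all).
#' @param individuals individual labels or indices to keep (`NULL` keeps all).
#' @return A [GenotypeLikelihoodSet-class].
#' @export
subsetGL <- function(x, sites = NULL, individuals = NULL) {
  si <- if (is.null(sites)) seq_along(x@sites) else
    if (is.character(sites)) match(sites, x@sites) else sites
  ii <- if (is.null(individuals)) seq_along(x@individuals) else
    if (is.character(individuals)) match(individuals, x@individuals) else individuals
  if (anyNA(si)) stop("unknown site IDs")
  if (anyNA(ii)) stop("unknown individuals")
  new("GenotypeLikelihoodSet", gl = x@gl[si, ii, , drop = FALSE],
      sites = x@sites[si], alleles = x@alleles[si, , drop = FALSE],
      individuals = x@individuals[ii], polarization = x@polarization)
}

#' Build a GenotypeLikelihoodSet from called genotypes
#'
#' Certainty limit: every likelihood triple is an indicator of the given
#' genotype. Handy for exact oracles.
#'
#' @param g sites x individuals matrix of dosages (0/1/2; `NA` = missing).
#' @param polarization `"unfolded"` or `"folded"`.
#' @return A [GenotypeLikelihoodSet-class].
#' @export
glFromGenotypes <- function(g, polarization = "unfolded") {
  g <- as.matrix(g)
  S <- nrow(g); N <- ncol(g)
  gl <- array(0, dim = c(S, N, 3))
  for (k in 1:3) gl[, , k] <- ifelse(is.na(g), 1, as.numeric(g == (k - 1)))
  sites <- rownames(g); inds <- colnames(g)
  if (is.null(sites)) sites <- sprintf("site_%06d", seq_len(S))
  if (is.null(inds)) inds <- sprintf("Ind%03d", seq_len(N))
  new("GenotypeLikelihoodSet", gl = gl, sites = sites,
      alleles = matrix(c("0", "1"), S, 2, byrow = TRUE,
                       dimnames = list(sites, c("major", "minor"))),
      individuals = inds, polarization = polarization)
}

#' Write / read a simulation truth record as JSON
#'
#' @param truth a [metapopulationTruth()] record.
#' @param path file path.
#' @return `readTruthJson` returns the `MetapopulationTruth` list.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$popCov)) x$popCov <- as.matrix(x$popCov)
  structure(x, class = "MetapopulationTruth")
}
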