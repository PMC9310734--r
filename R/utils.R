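# internal helpers shared across modules

# evaluate `code` under a local RNG state seeded with `seed`
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a stream of sub-seeds from one master seed (kept below 2^31)
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# lower-triangle vector of a square matrix (column-major, excluding diagonal)
lowerTri <- function(m) {
  if (is(m, "DistanceMatrix")) m <- m@values
  m[lower.tri(m)]
}

# align a DistanceMatrix (or labelled square matrix) to the given labels
alignTo <- function(m, labels) {
  v <- if (is(m, "DistanceMatrix")) m@values else m
  if (is.null(rownames(v))) {
    if (nrow(v) != length(labels)) stop("unlabelled matrix of wrong size")
    return(v)
  }
  if (!all(labels %in% rownames(v))) stop("matrix labels do not cover: ",
                                          paste(setdiff(labels, rownames(v)), collapse = ", "))
  v[labels, labels, drop = FALSE]
}

# all permutations of 1..n as a matrix (n! rows); used for exhaustive
# permutation tests on small label sets
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- nrow(sub)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * r + seq_len(r)
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow = r)
  }
  out
}

# kind-checked DistanceMatrix constructor
#' Create a labelled distance matrix
#'
#' @param values square symmetric numeric matrix with zero diagonal; row
#'   names are used as labels (or supply `labels`).
#' @param kind tag: `"IBD"`, `"IBR_Terrain"`, `"IBR_Habitat"`, `"IBI"`,
#'   `"IBE"`, `"FST"` or `"genetic"`.
#' @param labels optional character labels.
#' @return A [DistanceMatrix-class].
#' @export
distanceMatrix <- function(values, kind = "genetic", labels = NULL) {
  values <- as.matrix(values)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  if (is.null(rownames(values))) {
    labels <- paste0("L", seq_len(nrow(values)))
    dimnames(values) <- list(labels, labels)
  }
  new("DistanceMatrix", values = values, kind = kind)
}

#' @describeIn distanceMatrix the underlying labelled matrix.
#' @param x a `DistanceMatrix`.
#' @export
setMethod("values", "DistanceMatrix", function(x) x@values)

#' @describeIn distanceMatrix the kind tag.
#' @export
setGeneric("kind", function(x) standardGeneric("kind"))

#' @export
setMethod("kind", "DistanceMatrix", function(x) x@kind)

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s), %d labels\n", object@kind, nrow(object@values)))
  print(round(object@values, 4))
  invisible(object)
})

#' Write / read a labelled distance matrix as CSV
#'
#' The CSV stores labels in the first column and header; reading aligns by
#' label so column order in the file is immaterial.
#'
#' @param x a `DistanceMatrix`.
#' @param path file path.
#' @param kind kind tag to attach on read.
#' @return `readDistanceMatrixCsv` returns a [DistanceMatrix-class].
#' @export
writeDistanceMatrixCsv <- function(x, path) {
  stopifnot(is(x, "DistanceMatrix"))
  utils::write.csv(as.data.frame(x@values), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeDistanceMatrixCsv
#' @export
readDistanceMatrixCsv <- function(path, kind = "genetic") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(rownames(m) %in% colnames(m)))
    stop("malformed matrix CSV '", path, "': row and column labels differ")
  m <- m[, rownames(m), drop = FALSE]  # align columns to row-label order
  m <- (m + t(m)) / 2                  # remove round-trip rounding asymmetry
  diag(m) <- 0
  distanceMatrix(m, kind = kind)
}
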