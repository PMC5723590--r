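#' Spatial eigenfunction basis (PCNM / Moran eigenvector maps)
#'
#' Eigenvectors of the Gower-centered, truncated inter-site distance
#' matrix.  Columns are centered, mutually orthogonal and unit-norm, and
#' form a basis of spatial patterns ordered from broad (first vectors) to
#' fine scale.  Only eigenvectors with a positive-definite share of the
#' spectrum and positive spatial autocorrelation (Moran's I above its
#' null expectation \eqn{-1/(n-1)}) are retained, so the basis models
#' positively autocorrelated spatial structure such as dispersal
#' limitation.
#'
#' @slot vectors n-by-m matrix of retained eigenvectors.
#' @slot eigenvalues eigenvalues of the retained vectors (descending).
#' @slot moran Moran's I of each retained vector under binary
#'   within-truncation connectivity.
#' @slot truncation the truncation distance t in metres.
#' @slot n number of sites.
#' @seealso [pcnm()], [moransI()]
#' @export
setClass("MEMBasis",
  slots = c(vectors = "matrix", eigenvalues = "numeric", moran = "numeric",
            truncation = "numeric", n = "integer"))

setValidity("MEMBasis", function(object) {
  if (ncol(object@vectors) != length(object@eigenvalues))
    return("one eigenvalue per vector required")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be sorted descending")
  if (any(object@moran <= -1 / (object@n - 1)))
    return("retained vectors must have Moran's I above -1/(n-1)")
  TRUE
})

setMethod("show", "MEMBasis", function(object) {
  cat(sprintf("MEMBasis: %d spatial eigenvectors over %d sites (truncation %.4g m)\n",
              ncol(object@vectors), object@n, object@truncation))
  cat(sprintf("  eigenvalues [%.4g .. %.4g], Moran's I [%.3g .. %.3g]\n",
              max(object@eigenvalues), min(object@eigenvalues),
              max(object@moran), min(object@moran)))
})

#' @describeIn MEMBasis retained eigenvector matrix.
#' @param x an \code{MEMBasis}.
#' @export
setMethod("eigenvectors", "MEMBasis", function(x) x@vectors)

#' @describeIn MEMBasis retained eigenvalues.
#' @export
setMethod("eigenvalues", "MEMBasis", function(x) x@eigenvalues)

#' @describeIn MEMBasis Moran's I of each retained vector.
#' @export
setMethod("moran", "MEMBasis", function(x) x@moran)

#' @describeIn MEMBasis truncation distance used (m).
#' @export
setMethod("truncationDistance", "MEMBasis", function(x) x@truncation)

# Longest edge of the minimum spanning tree (Prim) of a distance matrix.
mstLongestEdge <- function(D) {
  n <- nrow(D)
  inTree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  longest <- 0
  for (i in seq_len(n - 1)) {
    cand <- which(!inTree)
    j <- cand[which.min(best[cand])]
    longest <- max(longest, best[j])
    inTree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  longest
}

#' Binary connectivity weights from a truncation distance
#'
#' \eqn{w_{ih} = 1} when \eqn{0 < d_{ih} \le t}, else 0: the neighbour
#' graph used for the Moran's I screening of spatial eigenvectors.
#'
#' @param centroids two-column matrix/data.frame of site coordinates.
#' @param t truncation distance (> 0) in the coordinate units.
#' @return Symmetric binary weight matrix with zero diagonal.
#' @export
connectivityFromTruncation <- function(centroids, t) {
  xy <- as.matrix(centroids)
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stopf("truncation distance must be a single positive number")
  D <- as.matrix(dist(xy))
  W <- 1 * (D > 0 & D <= t)
  if (sum(W) == 0)
    stopf("truncation distance %g is below the minimum inter-point distance (%g): empty graph",
          t, min(D[D > 0]))
  W
}

#' Moran's I spatial autocorrelation
#'
#' \eqn{I = (n/W) \cdot \sum_{ih} w_{ih} z_i z_h / \sum_i z_i^2} with
#' \eqn{z} the centered values and \eqn{W} the total weight.  The null
#' expectation under random permutation of values is \eqn{-1/(n-1)}.
#'
#' @param values numeric vector (length >= 2, non-constant).
#' @param weights symmetric nonnegative weight matrix with zero diagonal
#'   and positive total.
#' @return Moran's I (scalar).
#' @examples
#' W <- connectivityFromTruncation(cbind(1:4, 0), 1)
#' moransI(c(1, 2, 3, 4), W)  # 1/3
#' @export
moransI <- function(values, weights) {
  z <- as.numeric(values) - mean(values)
  n <- length(z)
  if (n < 2) stopf("Moran's I needs at least 2 values")
  W <- as.matrix(weights)
  if (!isTRUE(all.equal(W, t(W))) || any(W < 0) || any(diag(W) != 0))
    stopf("weights must be symmetric, nonnegative, with zero diagonal")
  sw <- sum(W)
  if (sw <= 0) stopf("weight total must be positive")
  sz <- sum(z^2)
  if (sz == 0) stopf("Moran's I undefined for zero-variance values")
  (n / sw) * as.numeric(t(z) %*% W %*% z) / sz
}

#' Principal coordinates of neighbour matrices
#'
#' Builds the PCNM spatial eigenfunction basis from site coordinates:
#' (1) Euclidean distance matrix D; (2) truncation distance t, defaulting
#' to the longest edge of the minimum spanning tree of the sites (the
#' smallest t keeping the neighbour graph connected); (3) distances above
#' t replaced by 4t; (4) Gower centering of \eqn{-\frac{1}{2} D^{*2}};
#' (5) eigendecomposition; (6) retention of eigenvectors whose eigenvalue
#' exceeds \code{1e-8 * max(lambda)} and whose Moran's I (binary
#' within-t weights) exceeds \eqn{-1/(n-1)}.  Eigenvector signs are fixed
#' by making the largest-magnitude loading positive, so output is stable
#' across linear-algebra backends.
#'
#' @param centroids two-column matrix/data.frame of site coordinates (>=
#'   3 distinct sites).
#' @param truncation optional truncation distance in metres; default the
#'   longest minimum-spanning-tree edge.
#' @return An [MEMBasis-class].
#' @export
pcnm <- function(centroids, truncation = NULL) {
  xy <- as.matrix(centroids)
  if (!is.numeric(xy) || ncol(xy) != 2)
    stopf("centroids must be a two-column numeric matrix")
  n <- nrow(xy)
  if (n < 3) stopf("PCNM needs at least 3 sites")
  D <- as.matrix(dist(xy))
  if (min(D[upper.tri(D)]) == 0) stopf("duplicate centroids are not allowed")
  t <- truncation %||% mstLongestEdge(D)
  if (t <= 0) stopf("truncation must be positive")
  Dstar <- D
  Dstar[D > t] <- 4 * t
  A <- -0.5 * Dstar^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > 1e-8 * max(e$values))
  if (!length(pos)) stopf("no positive eigenvalues: degenerate configuration")
  V <- e$vectors[, pos, drop = FALSE]
  lambda <- e$values[pos]
  # unit norm (eigen() already returns unit vectors) and deterministic sign
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  W <- connectivityFromTruncation(xy, t)
  mor <- apply(V, 2, moransI, weights = W)
  keep <- mor > -1 / (n - 1)
  if (!any(keep))
    stopf("no eigenvector passes the Moran's I screen (n = %d, t = %g)", n, t)
  V <- V[, keep, drop = FALSE]
  colnames(V) <- paste0("PCNM", seq_len(ncol(V)))
  new("MEMBasis", vectors = V, eigenvalues = lambda[keep], moran = mor[keep],
      truncation = t, n = as.integer(n))
}
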