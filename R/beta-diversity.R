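#' Beta diversity as the total variance of the community table
#'
#' Container for the variance decomposition of a (Hellinger-transformed)
#' grains-by-species table Y: the total sum of squares
#' \eqn{SS_{Total} = \sum_i \sum_j (y_{ij} - \bar y_j)^2}, beta diversity
#' \eqn{BD_{Total} = SS_{Total}/(n-1)} (the unbiased total variance,
#' bounded by \eqn{[0, 1]} for Hellinger data), the per-grain sums of
#' squares \eqn{SS_i}, and the local contributions to beta diversity
#' \eqn{LCBD_i = SS_i / SS_{Total}}, which sum to 1 and measure each
#' grain's compositional uniqueness.
#'
#' @slot ssTotal total sum of squares.
#' @slot bdTotal total beta diversity, \code{ssTotal / (n - 1)}.
#' @slot ssI per-grain sums of squares (named by grain).
#' @slot lcbd per-grain local contributions (named, sums to 1).
#' @seealso [betaDiversity()]
#' @include grain-community.R
#' @export
setClass("BetaDiversityResult",
  slots = c(ssTotal = "numeric", bdTotal = "numeric",
            ssI = "numeric", lcbd = "numeric"))

setValidity("BetaDiversityResult", function(object) {
  if (abs(sum(object@lcbd) - 1) > 1e-8) return("LCBD must sum to 1")
  if (abs(sum(object@ssI) - object@ssTotal) > 1e-8 * max(1, object@ssTotal))
    return("per-grain SS must sum to SS_Total")
  TRUE
})

setMethod("show", "BetaDiversityResult", function(object) {
  cat(sprintf("BetaDiversityResult: n = %d grains, SS_Total = %.5g, BD_Total = %.5g\n",
              length(object@lcbd), object@ssTotal, object@bdTotal))
  cat(sprintf("  LCBD range [%.4g, %.4g]\n",
              min(object@lcbd), max(object@lcbd)))
})

.checkCommunityMatrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stopf("community table must be numeric")
  if (any(X < 0)) stopf("negative abundances are not allowed")
  X
}

#' Hellinger transformation
#'
#' Converts the abundance table \eqn{X} to
#' \eqn{y_{ij} = \sqrt{x_{ij} / \sum_k x_{ik}}}: the square root of
#' within-grain relative abundances.  Euclidean distance on the
#' transformed table is the Hellinger distance, an ecologically
#' well-behaved dissimilarity that makes the table suitable for
#' variance-based beta diversity and linear (RDA) ordination.
#'
#' For a \code{GrainCommunity} the transform is stored as a
#' \code{"hellinger"} assay; empty grains are dropped first (see
#' [dropEmptyGrains()]).
#'
#' @param x grains-by-species numeric matrix, or a [GrainCommunity-class].
#' @param zeroRows for the matrix method: \code{"error"} (default) on
#'   all-zero rows, \code{"drop"} to remove them, \code{"keep"} to map
#'   them to zero rows.
#' @param ... passed to methods.
#' @return A matrix of the same shape (rows with positive abundance have
#'   unit sum of squares), or the augmented \code{GrainCommunity}.
#' @examples
#' hellingerTransform(rbind(c(1, 3), c(4, 0)))
#' @export
setMethod("hellingerTransform", "matrix", function(x, zeroRows = c("error", "drop", "keep")) {
  zeroRows <- match.arg(zeroRows)
  X <- .checkCommunityMatrix(x)
  rs <- rowSums(X)
  if (any(rs == 0)) {
    if (zeroRows == "error")
      stopf("row(s) %s have zero total abundance; the Hellinger transform is undefined",
            paste(which(rs == 0), collapse = ", "))
    if (zeroRows == "drop") { X <- X[rs > 0, , drop = FALSE]; rs <- rs[rs > 0] }
  }
  Y <- sqrt(sweep(X, 1, pmax(rs, 1), "/"))
  Y[rs == 0, ] <- 0
  Y
})

#' @rdname hellingerTransform
#' @export
setMethod("hellingerTransform", "GrainCommunity", function(x, ...) {
  x <- dropEmptyGrains(x)
  X <- communityMatrix(x)
  Y <- hellingerTransform(X, zeroRows = "error")
  assays(x)$hellinger <- t(Y)
  x
})

#' Total sum of squares of a community table
#'
#' \eqn{SS_{Total} = \sum_i \sum_j (y_{ij} - \bar y_j)^2}, the total
#' variance of community composition (up to the \eqn{n-1} divisor).  It
#' is computed both by column centering and through the equivalent
#' pairwise-distance identity
#' \eqn{SS_{Total} = \frac{1}{n}\sum_{i<h} D_{ih}^2} over Euclidean
#' distances between rows; the two are asserted to agree, which guards
#' the implementation against centering mistakes.
#'
#' @param x numeric matrix (rows = grains) with \code{n >= 2} rows, or a
#'   [GrainCommunity-class] (its Hellinger assay is used, computed if
#'   absent).
#' @param ... passed to methods.
#' @return The total sum of squares (scalar).
#' @export
setMethod("ssTotal", "matrix", function(x) {
  Y <- as.matrix(x)
  n <- nrow(Y)
  if (n < 2) stopf("SS_Total requires at least 2 rows")
  Yc <- sweep(Y, 2, colMeans(Y))
  s1 <- sum(Yc^2)
  s2 <- sum(dist(Y)^2) / n
  if (abs(s1 - s2) > 1e-8 * max(1, s1))
    stopf("internal inconsistency: centering (%.12g) and pairwise-distance (%.12g) formulas disagree",
          s1, s2)
  s1
})

#' @rdname ssTotal
#' @export
setMethod("ssTotal", "GrainCommunity",
          function(x) ssTotal(.hellingerOf(x)))

.hellingerOf <- function(x) {
  if (!"hellinger" %in% names(assays(x))) x <- hellingerTransform(x)
  communityMatrix(x, "hellinger")
}

#' Total beta diversity and local contributions
#'
#' \code{betaDiversity()} computes \eqn{BD_{Total} = SS_{Total}/(n-1)}
#' together with the per-grain decomposition
#' \eqn{LCBD_i = SS_i / SS_{Total}}; \code{bdTotal()} and \code{lcbd()}
#' return the individual pieces.  On Hellinger-transformed data
#' \eqn{BD_{Total} \in [0, 1]}, reaching 1 only when all grains are
#' pairwise maximally dissimilar (no shared species).
#'
#' @param x a grains-by-species matrix of Hellinger-transformed (or
#'   otherwise pre-transformed) data, or a [GrainCommunity-class] whose
#'   counts are Hellinger-transformed internally.
#' @param ... passed to methods.
#' @return \code{betaDiversity()} returns a
#'   [BetaDiversityResult-class]; \code{bdTotal()} a scalar; \code{lcbd()}
#'   a named numeric vector summing to 1.
#' @examples
#' Y <- hellingerTransform(rbind(g1 = c(5, 0), g2 = c(0, 3)))
#' bdTotal(Y)   # 1: two fully distinct single-species grains
#' lcbd(Y)      # 0.5 0.5
#' @export
setMethod("betaDiversity", "matrix", function(x) {
  Y <- as.matrix(x)
  n <- nrow(Y)
  if (n < 2) stopf("beta diversity requires at least 2 grains")
  Yc <- sweep(Y, 2, colMeans(Y))
  ssi <- rowSums(Yc^2)
  ss <- ssTotal(Y)
  if (ss <= 0)
    stopf("SS_Total is zero (all grains identical); LCBD is undefined")
  names(ssi) <- rownames(Y) %||% paste0("g", seq_len(n))
  new("BetaDiversityResult", ssTotal = ss, bdTotal = ss / (n - 1),
      ssI = ssi, lcbd = ssi / ss)
})

#' @rdname betaDiversity
#' @export
setMethod("betaDiversity", "GrainCommunity",
          function(x) betaDiversity(.hellingerOf(x)))

#' @rdname betaDiversity
#' @export
setMethod("bdTotal", "matrix", function(x) {
  n <- nrow(x)
  if (n < 2) stopf("BD_Total requires at least 2 rows")
  ssTotal(x) / (n - 1)
})

#' @rdname betaDiversity
#' @export
setMethod("bdTotal", "GrainCommunity", function(x) bdTotal(.hellingerOf(x)))

#' @rdname betaDiversity
#' @export
setMethod("bdTotal", "BetaDiversityResult", function(x) x@bdTotal)

#' @rdname betaDiversity
#' @export
setMethod("lcbd", "matrix", function(x) betaDiversity(x)@lcbd)

#' @rdname betaDiversity
#' @export
setMethod("lcbd", "GrainCommunity", function(x) betaDiversity(x)@lcbd)

#' @rdname betaDiversity
#' @export
setMethod("lcbd", "BetaDiversityResult", function(x) x@lcbd)

#' @rdname betaDiversity
#' @export
setMethod("ssTotal", "BetaDiversityResult", function(x) x@ssTotal)
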