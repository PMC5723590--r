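#' Variation partitioning of community composition
#'
#' Adjusted-R2 decomposition of the variance of a community table into
#' four fractions: pure environment [a], spatially structured
#' environment [b], pure space [c], and unexplained [d].  By
#' construction \eqn{a + b + c + d = 1}.  The environmental effect is
#' read as fraction [a+b] and the spatial (dispersal) effect as the pure
#' fraction [c].  Fraction [b] is an overlap, not an independently
#' testable component, and can be negative on the adjusted scale; it is
#' reported as computed, never clipped.
#'
#' @slot adjusted named numeric: fractions a, b, c, d and the composites
#'   ab (= adjR2 of the environmental model), bc (spatial model), abc
#'   (joint model).
#' @slot unadjusted same quantities on the raw R2 scale.
#' @slot tests data.frame of permutation tests (fraction, F, p, code)
#'   for the testable components: [a+b], [c] (partial), [a] (partial)
#'   and the joint model [a+b+c].
#' @slot mE,mS number of environmental / spatial predictors.
#' @slot n number of grains.
#' @slot nPerm permutations used.
#' @seealso [varpart()]
#' @export
setClass("VariationPartition",
  slots = c(adjusted = "numeric", unadjusted = "numeric",
            tests = "data.frame", mE = "integer", mS = "integer",
            n = "integer", nPerm = "integer"))

setValidity("VariationPartition", function(object) {
  f <- object@adjusted
  need <- c("a", "b", "c", "d", "ab", "bc", "abc")
  if (!all(need %in% names(f))) return("missing fraction names")
  if (abs(f["a"] + f["b"] + f["c"] + f["d"] - 1) > 1e-12)
    return("fractions a + b + c + d must equal 1")
  TRUE
})

setMethod("show", "VariationPartition", function(object) {
  f <- object@adjusted
  cat(sprintf("VariationPartition (adjusted R2, n = %d, mE = %d, mS = %d):\n",
              object@n, object@mE, object@mS))
  cat(sprintf("  [a] pure environment      %8.4f\n", f["a"]))
  cat(sprintf("  [b] spatially structured  %8.4f\n", f["b"]))
  cat(sprintf("  [c] pure space            %8.4f\n", f["c"]))
  cat(sprintf("  [d] unexplained           %8.4f\n", f["d"]))
  cat(sprintf("  environment [a+b] = %.4f, space [c] = %.4f\n", f["ab"], f["c"]))
  if (nrow(object@tests)) {
    cat("  permutation tests:\n")
    print(object@tests, digits = 4, row.names = FALSE)
  }
})

#' @describeIn VariationPartition the fraction vector.
#' @param x a \code{VariationPartition}.
#' @param adjusted return adjusted (default) or raw fractions.
#' @export
setMethod("fractions", "VariationPartition",
          function(x, adjusted = TRUE) if (adjusted) x@adjusted else x@unadjusted)

.emptyPredictors <- function(X) is.null(X) || NCOL(X) == 0 || ncol(.prepPredictors(X)) == 0

#' Partition community variance into environmental and spatial fractions
#'
#' Given a Hellinger-transformed community table Y, a matrix E of
#' (selected) environmental covariates and a matrix S of (selected)
#' spatial eigenvectors, computes three RDA models — Y~E, Y~S, Y~E+S —
#' and derives the four fractions on the adjusted-R2 scale:
#' \deqn{ab = adjR2(E),\; bc = adjR2(S),\; abc = adjR2(E \cup S)}
#' \deqn{a = abc - bc,\; c = abc - ab,\; b = ab + bc - abc,\; d = 1 - abc.}
#' Significance is assessed by permutation: [a+b] by permuting community
#' rows against E, [c] by permuting residuals of Y on E against S, [a]
#' symmetrically, and the joint model against all predictors.
#'
#' @param Y sites-by-species matrix.
#' @param E environmental predictor matrix (may be NULL/empty).
#' @param S spatial predictor matrix (may be NULL/empty); not both empty.
#' @param nPerm permutations for the tests (default 999); 0 skips
#'   testing.
#' @param seed optional RNG seed.
#' @param standardizeE z-score the environmental columns (default TRUE).
#' @return A [VariationPartition-class].
#' @export
varpart <- function(Y, E, S, nPerm = 999, seed = NULL, standardizeE = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  eEmpty <- .emptyPredictors(E)
  sEmpty <- .emptyPredictors(S)
  if (eEmpty && sEmpty) stopf("E and S cannot both be empty")
  Ep <- if (eEmpty) NULL else .prepPredictors(E, standardizeE)
  Sp <- if (sEmpty) NULL else .prepPredictors(S, standardize = FALSE)
  mE <- if (eEmpty) 0L else ncol(Ep)
  mS <- if (sEmpty) 0L else ncol(Sp)
  r2of <- function(X) if (is.null(X)) list(r2 = 0, adj = 0) else {
    f <- rdaR2(Y, X, standardize = FALSE)
    list(r2 = f@r2, adj = f@adjR2)
  }
  ES <- if (eEmpty) Sp else if (sEmpty) Ep else cbind(Ep, Sp)
  fE <- r2of(Ep); fS <- r2of(Sp); fES <- r2of(ES)
  frac <- function(v) {
    ab <- v["E"]; bc <- v["S"]; abc <- v["ES"]
    c(a = unname(abc - bc), b = unname(ab + bc - abc),
      c = unname(abc - ab), d = unname(1 - abc),
      ab = unname(ab), bc = unname(bc), abc = unname(abc))
  }
  adj <- frac(c(E = fE$adj, S = fS$adj, ES = fES$adj))
  raw <- frac(c(E = fE$r2, S = fS$r2, ES = fES$r2))
  tests <- data.frame(fraction = character(), F = numeric(), p = numeric(),
                      code = character(), stringsAsFactors = FALSE)
  if (nPerm >= 1) withSeed(seed, {
    addTest <- function(label, X, W = NULL) {
      t <- permutationTest(Y, X, W = W, nPerm = nPerm, standardize = FALSE)
      tests[nrow(tests) + 1L, ] <<- list(label, t@statistic, t@pValue,
                                         signifCode(t@pValue))
    }
    if (!eEmpty) addTest("[a+b]", Ep)
    if (!sEmpty && !eEmpty) addTest("[c]", Sp, W = Ep)
    if (!eEmpty && !sEmpty) addTest("[a]", Ep, W = Sp)
    if (!sEmpty && eEmpty) addTest("[c]", Sp)   # degenerate: no E side
    addTest("[a+b+c]", ES)
  })
  new("VariationPartition", adjusted = adj, unadjusted = raw, tests = tests,
      mE = as.integer(mE), mS = as.integer(mS), n = as.integer(n),
      nPerm = as.integer(max(0, nPerm)))
}
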