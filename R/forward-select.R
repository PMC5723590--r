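#' Forward selection with the double stopping criterion
#'
#' Result of permutation-based forward selection of predictors for RDA.
#'
#' @slot selected names of the selected columns, in selection order.
#' @slot steps data.frame with one row per accepted step: variable,
#'   added R2, cumulative R2, cumulative adjusted R2, F, p.
#' @slot globalP p-value of the global test of all candidates.
#' @slot globalAdjR2 adjusted R2 of the all-candidate model (the
#'   stopping ceiling).
#' @seealso [forwardSelect()]
#' @export
setClass("ForwardSelection",
  slots = c(selected = "character", steps = "data.frame",
            globalP = "numeric", globalAdjR2 = "numeric"))

setMethod("show", "ForwardSelection", function(object) {
  cat(sprintf("ForwardSelection: %d variable(s) selected (global p = %.4g, adjR2 ceiling = %.4f)\n",
              length(object@selected), object@globalP, object@globalAdjR2))
  if (nrow(object@steps)) print(object@steps, digits = 4)
})

#' @describeIn ForwardSelection names of the selected variables.
#' @param x a \code{ForwardSelection}.
#' @export
setMethod("selectedVars", "ForwardSelection", function(x) x@selected)

#' Permutation-based forward selection of RDA predictors
#'
#' Selects a parsimonious predictor subset by the double stopping
#' criterion of Blanchet-style forward selection: (0) a global
#' permutation test of the full candidate set gates the procedure — if
#' it is not significant at \code{alpha} the empty set is returned — and
#' the adjusted R2 of the full model becomes a ceiling; (1) at each step
#' the candidate adding the largest R2 is tested by permutation of
#' residuals under the current model and added if \eqn{p \le alpha};
#' (2) selection stops when a candidate fails the test or when adding it
#' would push the model's adjusted R2 above the global ceiling (the
#' offending candidate is rejected).
#'
#' Environmental candidates should be passed as raw covariates (they are
#' z-scored internally); PCNM vectors are already centered and unit-norm
#' and are used as produced.  Ties in added R2 are broken by candidate
#' input order.
#'
#' @param Y sites-by-species matrix (Hellinger-transformed).
#' @param candidates matrix / data.frame of candidate predictors.
#' @param alpha significance level of the permutation tests (default
#'   0.05).
#' @param nPerm permutations per test (default 999).
#' @param seed optional RNG seed.
#' @param adjR2Ceiling apply the global adjusted-R2 ceiling rule
#'   (default TRUE).
#' @param standardize z-score candidates (default TRUE).
#' @return A [ForwardSelection-class].
#' @export
forwardSelect <- function(Y, candidates, alpha = 0.05, nPerm = 999,
                          seed = NULL, adjR2Ceiling = TRUE,
                          standardize = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- .prepPredictors(candidates, standardize)
  if (!ncol(X)) stopf("no non-constant candidate predictor")
  emptySteps <- data.frame(variable = character(), r2Add = numeric(),
                           r2Cum = numeric(), adjR2Cum = numeric(),
                           F = numeric(), p = numeric())
  withSeed(seed, {
    if (ncol(X) > n - 2) {
      # more candidates than the design can jointly estimate: the global
      # model is unfittable, so proceed stepwise without gate or ceiling
      warning(sprintf("%d candidates for %d sites: global test and adjusted-R2 ceiling unavailable",
                      ncol(X), n), call. = FALSE)
      globalP <- NA_real_
      ceiling <- Inf
    } else {
      global <- permutationTest(Y, X, nPerm = nPerm, standardize = FALSE)
      globalP <- global@pValue
      ceiling <- global@adjR2
      if (globalP > alpha)
        return(new("ForwardSelection", selected = character(),
                   steps = emptySteps, globalP = globalP,
                   globalAdjR2 = ceiling))
    }
    Yc <- sweep(Y, 2, colMeans(Y))
    sst <- sum(Yc^2)
    Xc <- sweep(X, 2, colMeans(X))
    remaining <- colnames(X)
    selected <- character()
    Qsel <- matrix(numeric(0), n, 0)
    ssSel <- 0
    steps <- emptySteps
    repeat {
      if (!length(remaining) || length(selected) >= n - 2) break
      # added SS of each remaining candidate given the selected basis
      addSS <- vapply(remaining, function(v) {
        r <- Xc[, v]
        if (ncol(Qsel)) r <- r - Qsel %*% crossprod(Qsel, r)
        nr2 <- sum(r^2)
        if (nr2 < 1e-10) return(-Inf)   # collinear with selected set
        sum((crossprod(r, Yc))^2) / nr2
      }, numeric(1))
      best <- remaining[which.max(addSS)]
      if (!is.finite(max(addSS))) break
      tst <- permutationTest(Y, X[, best, drop = FALSE],
                             W = if (length(selected)) X[, selected, drop = FALSE] else NULL,
                             nPerm = nPerm, standardize = FALSE)
      if (tst@pValue > alpha) break
      newSel <- c(selected, best)
      fullR2 <- (ssSel + addSS[best]) / sst
      newAdj <- adjustedR2(fullR2, n, length(newSel))
      if (adjR2Ceiling && newAdj > ceiling + 1e-12) break
      selected <- newSel
      ssSel <- ssSel + addSS[best]
      r <- Xc[, best]
      if (ncol(Qsel)) r <- r - Qsel %*% crossprod(Qsel, r)
      Qsel <- cbind(Qsel, r / sqrt(sum(r^2)))
      remaining <- setdiff(remaining, best)
      steps <- rbind(steps, data.frame(
        variable = best, r2Add = addSS[best] / sst, r2Cum = fullR2,
        adjR2Cum = newAdj, F = tst@statistic, p = tst@pValue))
    }
    new("ForwardSelection", selected = selected, steps = steps,
        globalP = globalP, globalAdjR2 = ceiling)
  })
}
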