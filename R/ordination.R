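#' Redundancy-analysis fit summary
#'
#' Result of regressing a (column-centered) multivariate community table
#' Y on a predictor matrix X by multivariate least squares: the fraction
#' of the total community variance captured by the fitted values
#' (\eqn{R^2}), its Ezekiel adjustment \eqn{R^2_{adj}} (unbiased under
#' the number of predictors; may be negative), the pseudo-F statistic and
#' — when produced by [permutationTest()] — a permutation p-value.
#'
#' @slot r2 unadjusted fraction of SS_Total explained.
#' @slot adjR2 Ezekiel-adjusted R-squared.
#' @slot statistic pseudo-F statistic.
#' @slot pValue permutation p-value (NA unless a test was run).
#' @slot m number of (independent) predictors; for a partial fit, the
#'   number of added predictors.
#' @slot n number of sites.
#' @slot nPerm number of permutations behind \code{pValue} (0 if none).
#' @slot degenerate TRUE when the residual variance was (numerically)
#'   zero and the p-value was reported as \code{1/(1+nPerm)}.
#' @slot terms predictor column names used.
#' @slot residuals residual matrix of the fit.
#' @export
setClass("OrdinationFit",
  slots = c(r2 = "numeric", adjR2 = "numeric", statistic = "numeric",
            pValue = "numeric", m = "integer", n = "integer",
            nPerm = "integer", degenerate = "logical",
            terms = "character", residuals = "matrix"))

setMethod("show", "OrdinationFit", function(object) {
  cat(sprintf("OrdinationFit: n = %d, m = %d predictor(s)\n", object@n, object@m))
  cat(sprintf("  R2 = %.4f, adjR2 = %.4f, F = %.4g", object@r2,
              object@adjR2, object@statistic))
  if (!is.na(object@pValue))
    cat(sprintf(", p = %.4g (%d permutations)%s", object@pValue,
                object@nPerm, if (object@degenerate) " [degenerate]" else ""))
  cat("\n")
})

# Coerce predictors to a numeric matrix, optionally z-scoring columns;
# constant columns are dropped (they carry no information beyond the
# intercept).
.prepPredictors <- function(X, standardize = TRUE) {
  if (is.null(X)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2, function(v) sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  if (standardize && ncol(X))
    X <- scale(X)[, , drop = FALSE]
  X
}

# Orthonormal basis of the column space of the centered predictors;
# errors on rank deficiency, naming the offending columns.
.orthoBasis <- function(X) {
  if (ncol(X) == 0) return(matrix(numeric(0), nrow = nrow(X), ncol = 0))
  Xc <- sweep(X, 2, colMeans(X))
  q <- qr(Xc)
  if (q$rank < ncol(Xc)) {
    bad <- colnames(Xc)[q$pivot[(q$rank + 1):ncol(Xc)]]
    stopf("predictor matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  qr.Q(q)
}

#' Ezekiel-adjusted R-squared
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - m - 1)}: the
#' explained-variance fraction corrected for the number of predictors
#' \code{m}.  Unlike \eqn{R^2} it is unbiased under pure-noise predictors
#' and can be negative.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of sites.
#' @param m number of predictors (0 gives \code{r2} back).
#' @return Adjusted R-squared (scalar).
#' @examples
#' adjustedR2(0.5, 30, 5)
#' @export
adjustedR2 <- function(r2, n, m) {
  if (n <= m + 1) stopf("adjusted R2 requires n > m + 1 (n = %d, m = %d)", n, m)
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Redundancy analysis: explained community variance
#'
#' Fits multivariate least squares of the column-centered community
#' table \code{Y} on the predictors \code{X} (z-scored by default, with
#' intercept) and measures \eqn{R^2 = SS_{fit}/SS_{Total}} against the
#' total community variance, together with the pseudo-F statistic
#' \eqn{F = (SS_{fit}/m) / (SS_{res}/(n - m - 1))}.  With
#' Hellinger-transformed \code{Y} this is transformation-based RDA.
#'
#' @param Y sites-by-species numeric matrix (e.g. a Hellinger-transformed
#'   community table).
#' @param X predictor matrix / data.frame; constant columns are dropped,
#'   collinear columns raise an error.
#' @param standardize z-score the predictor columns (default TRUE;
#'   spatial eigenvectors are already centered and unit-norm and may be
#'   passed with \code{standardize = FALSE}).
#' @return An [OrdinationFit-class] (no p-value; see
#'   [permutationTest()]).
#' @export
rdaR2 <- function(Y, X, standardize = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- .prepPredictors(X, standardize)
  if (ncol(X) && nrow(X) != n) stopf("Y and X must have the same number of rows")
  m <- ncol(X)
  if (n <= m + 1)
    stopf("too few sites: n = %d must exceed m + 1 = %d", n, m + 1)
  Yc <- sweep(Y, 2, colMeans(Y))
  sst <- sum(Yc^2)
  if (sst == 0) stopf("Y has zero total variance")
  Q <- .orthoBasis(X)
  fit <- if (m) Q %*% crossprod(Q, Yc) else matrix(0, n, ncol(Yc))
  ssf <- sum(fit^2)
  r2 <- ssf / sst
  ssr <- sst - ssf
  Fstat <- if (m) (ssf / m) / (ssr / (n - m - 1)) else NA_real_
  new("OrdinationFit", r2 = r2, adjR2 = adjustedR2(r2, n, m),
      statistic = Fstat, pValue = NA_real_, m = as.integer(m),
      n = as.integer(n), nPerm = 0L, degenerate = FALSE,
      terms = colnames(X) %||% character(), residuals = Yc - fit)
}

# Partial pseudo-F of the predictors spanned by Qx, given the
# conditioning space Qw, for a centered response Yc.  Returns the F
# statistic and the component sums of squares.
.partialF <- function(Yc, Qw, Qx) {
  n <- nrow(Yc)
  sst <- sum(Yc^2)
  ssw <- if (ncol(Qw)) sum(crossprod(Qw, Yc)^2) else 0
  Qwx <- cbind(Qw, Qx)
  sswx <- sum(crossprod(Qwx, Yc)^2)
  mAdd <- ncol(Qx)
  mFull <- ncol(Qwx)
  ssres <- sst - sswx
  list(F = ((sswx - ssw) / mAdd) / (ssres / (n - mFull - 1)),
       ssAdd = sswx - ssw, ssRes = ssres, sst = sst)
}

#' Permutation F-test for (partial) RDA
#'
#' Tests the community variance explained by \code{X}, optionally after
#' conditioning on \code{W}.  Without conditioning, rows of the centered
#' community table are permuted.  With conditioning, the residuals of Y
#' on W are permuted and added back to the fitted values (permutation of
#' residuals under the reduced model), and the partial F of X given W is
#' recomputed each time.  The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{F^* \ge F_{obs}\}) / (1 + n_{perm})}.
#'
#' @param Y sites-by-species matrix.
#' @param X predictors under test.
#' @param W optional conditioning predictors.
#' @param nPerm number of permutations (default 999).
#' @param seed optional RNG seed for the permutation stream.
#' @param standardize z-score X and W columns (default TRUE).
#' @return An [OrdinationFit-class] with the p-value filled in; for a
#'   conditioned test the R2 slots hold the semi-partial R2 of X given W
#'   (share of total variance added by X).
#' @export
permutationTest <- function(Y, X, W = NULL, nPerm = 999, seed = NULL,
                            standardize = TRUE) {
  if (nPerm < 1) stopf("nPerm must be >= 1")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Xp <- .prepPredictors(X, standardize)
  Wp <- .prepPredictors(W, standardize)
  if (!ncol(Xp)) stopf("X has no non-constant predictor")
  Qw <- if (ncol(Wp)) .orthoBasis(Wp) else matrix(numeric(0), n, 0)
  # residualize X on W so Qx spans only the added directions
  Xc <- sweep(Xp, 2, colMeans(Xp))
  if (ncol(Qw)) Xc <- Xc - Qw %*% crossprod(Qw, Xc)
  q <- qr(Xc)
  if (q$rank < ncol(Xc)) {
    bad <- colnames(Xc)[q$pivot[(q$rank + 1):ncol(Xc)]]
    stopf("predictors collinear with the conditioning set or each other: %s",
          paste(bad, collapse = ", "))
  }
  Qx <- qr.Q(q)
  mFull <- ncol(Qw) + ncol(Qx)
  if (n <= mFull + 1)
    stopf("too few sites for the test: n = %d, predictors = %d", n, mFull)
  obs <- .partialF(Yc, Qw, Qx)
  degenerate <- obs$ssRes <= 1e-12 * obs$sst
  withSeed(seed, {
    if (degenerate) {
      p <- 1 / (1 + nPerm)
      exceed <- 0L
    } else if (ncol(Qw) == 0) {
      exceed <- 0L
      for (b in seq_len(nPerm)) {
        Fp <- .partialF(Yc[sample.int(n), , drop = FALSE], Qw, Qx)$F
        if (Fp >= obs$F) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (1 + nPerm)
    } else {
      Yfit <- Qw %*% crossprod(Qw, Yc)
      Yres <- Yc - Yfit
      exceed <- 0L
      for (b in seq_len(nPerm)) {
        Ystar <- Yfit + Yres[sample.int(n), , drop = FALSE]
        Ystar <- sweep(Ystar, 2, colMeans(Ystar))
        Fp <- .partialF(Ystar, Qw, Qx)$F
        if (Fp >= obs$F) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (1 + nPerm)
    }
  })
  r2 <- obs$ssAdd / obs$sst
  adj <- tryCatch(adjustedR2(r2, n, ncol(Qx)), error = function(e) NA_real_)
  new("OrdinationFit", r2 = r2, adjR2 = adj, statistic = obs$F,
      pValue = p, m = as.integer(ncol(Qx)), n = as.integer(n),
      nPerm = as.integer(nPerm), degenerate = degenerate,
      terms = colnames(Xp) %||% character(),
      residuals = matrix(numeric(0), 0, 0))
}
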