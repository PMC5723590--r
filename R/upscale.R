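#' Carry base-grain soil samples to a coarser grain design
#'
#' Produces one value per target grain and soil variable from the
#' base-design (20 x 20 m) samples.  At the native scale the samples
#' are returned unchanged.  Two upscaling paths are available:
#' \describe{
#'   \item{\code{block_mean}}{mean of the base-grain samples whose
#'     centres fall inside the target grain footprint (half-open
#'     intervals).  Conserves the global mean whenever the target design
#'     nests the base design exactly.}
#'   \item{\code{kriging}}{trend surface plus ordinary kriging of the
#'     residuals: a first-order polynomial trend in the sample
#'     coordinates is removed, an exponential semivariogram with nugget
#'     is fitted to the empirical semivariogram by weighted least
#'     squares (Cressie weights), residuals are kriged to the target
#'     grain centres, and the trend is added back.}
#' }
#'
#' @param samples an [EnvSampleTable-class] on the base design.
#' @param design target [GrainDesign-class] (same plot).
#' @param method \code{"block_mean"} (default) or \code{"kriging"}.
#' @return data.frame with columns \code{grain} and the six soil
#'   variables, one row per target grain, no missing values.
#' @export
upscaleEnvironment <- function(samples, design,
                               method = c("block_mean", "kriging")) {
  method <- match.arg(method)
  stopifnot(is(samples, "EnvSampleTable"), is(design, "GrainDesign"))
  if (!isTRUE(all.equal(plotDim(samples), plotDim(design))))
    stopf("sample table and design disagree on plot dimensions")
  s <- samples@samples
  base <- makeGrainDesign(samples@plotWidth, samples@plotHeight,
                          samples@baseGrain)
  if (design@grainSize == samples@baseGrain &&
      nGrains(design) == nGrains(base)) {
    out <- data.frame(grain = seq_len(nrow(s)), s[, .soilVars, drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  ce <- grainCentroids(design)
  if (method == "block_mean") {
    gid <- grainIndex(design, s$cx, s$cy)
    out <- data.frame(grain = ce$grain)
    for (v in .soilVars)
      out[[v]] <- as.numeric(tapply(s[[v]], factor(gid, levels = ce$grain),
                                    mean))
    miss <- which(apply(out[.soilVars], 1, function(r) any(is.na(r))))
    if (length(miss))
      stopf("target grain(s) %s contain no base sample centre",
            paste(miss, collapse = ", "))
  } else {
    if (nrow(s) < 10)
      stopf("kriging requires at least 10 samples to fit a variogram (have %d)",
            nrow(s))
    out <- data.frame(grain = ce$grain)
    for (v in .soilVars)
      out[[v]] <- krigeVariable(s$cx, s$cy, s[[v]], ce$cx, ce$cy)
  }
  out
}

# Empirical semivariogram of (x, y, z) in distance bins.
empiricalVariogram <- function(x, y, z, nBins = 12, maxDist = NULL) {
  D <- as.matrix(dist(cbind(x, y)))
  dz2 <- 0.5 * outer(z, z, "-")^2
  ut <- upper.tri(D)
  d <- D[ut]; g <- dz2[ut]
  maxDist <- maxDist %||% (max(d) / 2)
  keep <- d <= maxDist
  d <- d[keep]; g <- g[keep]
  bins <- cut(d, breaks = seq(0, maxDist, length.out = nBins + 1),
              include.lowest = TRUE)
  data.frame(dist = as.numeric(tapply(d, bins, mean)),
             gamma = as.numeric(tapply(g, bins, mean)),
             n = as.numeric(table(bins)))[!is.na(tapply(d, bins, mean)), ]
}

# WLS fit of an exponential semivariogram gamma(h) = nugget +
# psill * (1 - exp(-h / range)); Cressie weights n_k / gamma_model^2.
fitExponentialVariogram <- function(vg) {
  init <- c(nugget = max(1e-8, 0.1 * max(vg$gamma)),
            psill = max(1e-8, 0.9 * max(vg$gamma)),
            range = max(vg$dist) / 3)
  obj <- function(par) {
    par <- exp(par)
    gm <- par[1] + par[2] * (1 - exp(-vg$dist / par[3]))
    sum(vg$n * (vg$gamma - gm)^2 / pmax(gm, 1e-12)^2)
  }
  fit <- optim(log(init), obj, method = "Nelder-Mead",
               control = list(maxit = 2000))
  p <- exp(fit$par)
  list(nugget = p[1], psill = p[2], range = p[3])
}

# First-order trend + ordinary kriging of residuals.
krigeVariable <- function(x, y, z, px, py) {
  tr <- lm(z ~ x + y)
  res <- residuals(tr)
  if (sd(res) < 1e-12) {   # (near-)deterministic surface: trend only
    return(as.numeric(predict(tr, data.frame(x = px, y = py))))
  }
  vg <- empiricalVariogram(x, y, res)
  vm <- fitExponentialVariogram(vg)
  gammaOf <- function(h) vm$nugget + vm$psill * (1 - exp(-h / vm$range))
  n <- length(x)
  G <- gammaOf(as.matrix(dist(cbind(x, y))))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d <- sqrt(outer(px, x, "-")^2 + outer(py, y, "-")^2)
  B <- rbind(t(gammaOf(d)), 1)
  wts <- solve(A, B)
  pred <- as.numeric(t(wts[seq_len(n), , drop = FALSE]) %*% res)
  pred + as.numeric(predict(tr, data.frame(x = px, y = py)))
}
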