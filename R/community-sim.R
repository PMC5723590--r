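#' Parameters of the synthetic community generator
#'
#' Controls how stems are placed over the plot.  Each species responds
#' to the environment through a linear-Gaussian niche (coefficients
#' drawn once per seed on the standardized surfaces, log-intensity
#' scaled to \code{nicheStrength}) and/or recruits in clusters around
#' Poisson parent points with a Gaussian dispersal kernel (a Thomas
#' process).  The mixture weight sets the share of each: \code{mixtureWeight
#' = 0} places stems by environment only (pure environmental filtering);
#' \code{mixtureWeight = 1} by clustering only (pure dispersal
#' limitation); \code{nicheStrength = 0} with \code{mixtureWeight = 0}
#' gives complete spatial randomness.
#'
#' @slot nSpecies number of species in the pool.
#' @slot nStems total number of stems placed.
#' @slot nicheStrength sd of the species log-intensity response to the
#'   standardized environment (unitless, >= 0).
#' @slot clusterRate Thomas-process parent intensity per m^2 (per
#'   species).
#' @slot clusterSD dispersal kernel sd in metres.
#' @slot mixtureWeight in [0, 1]: share of placement intensity from
#'   clustering vs. environment.
#' @slot seed RNG seed for the community draw.
#' @seealso [generateCommunity()], [scenario()]
#' @export
setClass("CommunityParams",
  slots = c(nSpecies = "integer", nStems = "integer",
            nicheStrength = "numeric", clusterRate = "numeric",
            clusterSD = "numeric", mixtureWeight = "numeric",
            seed = "integer"))

setValidity("CommunityParams", function(object) {
  if (object@nSpecies < 1) return("at least one species is required")
  if (object@nStems < 0) return("nStems must be nonnegative")
  if (object@nicheStrength < 0) return("nicheStrength must be >= 0")
  if (object@clusterRate <= 0) return("clusterRate must be positive")
  if (object@clusterSD <= 0) return("clusterSD must be positive")
  if (object@mixtureWeight < 0 || object@mixtureWeight > 1)
    return("mixtureWeight must lie in [0, 1]")
  TRUE
})

#' @rdname CommunityParams-class
#' @param nSpecies,nStems,nicheStrength,clusterRate,clusterSD,mixtureWeight,seed
#'   see the class slots.  Defaults emulate a fully mapped 5.2-ha
#'   temperate plot: 40 species, 16,000 stems.
#' @export
CommunityParams <- function(nSpecies = 40, nStems = 16000,
                            nicheStrength = 1, clusterRate = 5e-4,
                            clusterSD = 12, mixtureWeight = 0.5,
                            seed = 1) {
  new("CommunityParams", nSpecies = as.integer(nSpecies),
      nStems = as.integer(nStems), nicheStrength = as.numeric(nicheStrength),
      clusterRate = as.numeric(clusterRate), clusterSD = as.numeric(clusterSD),
      mixtureWeight = as.numeric(mixtureWeight), seed = as.integer(seed))
}

setMethod("show", "CommunityParams", function(object) {
  cat(sprintf("CommunityParams: %d species, %d stems, niche %.3g, w = %.2f (clusterRate %.2g /m2, sd %.3g m), seed %d\n",
              object@nSpecies, object@nStems, object@nicheStrength,
              object@mixtureWeight, object@clusterRate, object@clusterSD,
              object@seed))
})

#' Generate a synthetic stem map
#'
#' Places \code{nStems} stems over the plot covered by \code{env}.  For
#' each species the placement intensity over a fine cell grid is the
#' mixture \eqn{(1 - w)\,\lambda_{env} + w\,\lambda_{clust}} of a
#' normalized environmental intensity \eqn{\lambda_{env} \propto
#' \exp(\eta)} (with \eqn{\eta} the species' linear niche response to the
#' standardized surfaces, scaled to sd \code{nicheStrength}) and a
#' normalized Thomas cluster density (Gaussian kernels around
#' species-specific Poisson parents).  Species total abundances follow a
#' lognormal rank-abundance draw; cells are sampled per species and
#' stems jittered uniformly within cells, so \code{nicheStrength = 0,
#' mixtureWeight = 0} is exact complete spatial randomness.  dbh values
#' are drawn from an exponential of mean 7 cm shifted to the 1 cm census
#' minimum; dbh is carried but unused by the abundance-based analysis.
#'
#' @param env an [EnvField-class] covering the plot.
#' @param params a [CommunityParams-class].
#' @param cellRes sampling-grid cell size in metres (default 5).
#' @return A [StemMap-class] with exactly \code{nStems} stems.
#' @export
generateCommunity <- function(env, params, cellRes = 5) {
  stopifnot(is(env, "EnvField"), is(params, "CommunityParams"))
  W <- env@plotWidth; H <- env@plotHeight
  nSp <- params@nSpecies
  if (params@nStems == 0)
    return(StemMap(plotWidth = W, plotHeight = H))
  nxc <- max(1L, as.integer(floor(W / cellRes)))
  nyc <- max(1L, as.integer(floor(H / cellRes)))
  cw <- W / nxc; ch <- H / nyc
  cx <- (rep(seq_len(nxc), times = nyc) - 0.5) * cw
  cy <- (rep(seq_len(nyc), each = nxc) - 0.5) * ch
  vars <- names(env@grids)
  Z <- vapply(vars, function(v) evalField(env, v, cx, cy), numeric(length(cx)))
  Z <- scale(Z)
  Z[is.nan(Z)] <- 0
  w <- params@mixtureWeight
  s <- params@nicheStrength
  withSeed(params@seed, {
    abund <- exp(rnorm(nSp, 0, 1))   # lognormal rank-abundance
    counts <- as.integer(rmultinom(1, params@nStems, abund / sum(abund)))
    out <- vector("list", nSp)
    for (j in seq_len(nSp)) {
      nj <- counts[j]
      if (nj == 0) next
      prob <- rep(1 / length(cx), length(cx))
      if (w < 1 && s > 0) {
        beta <- rnorm(ncol(Z))
        eta <- as.numeric(Z %*% beta)
        if (sd(eta) > 0) eta <- s * eta / sd(eta)
        pe <- exp(eta - max(eta))
        pe <- pe / sum(pe)
      } else {
        if (w < 1 && s == 0) beta <- rnorm(ncol(Z)) # keep stream aligned across s
        pe <- rep(1 / length(cx), length(cx))
      }
      if (w > 0) {
        nPar <- max(1L, rpois(1, params@clusterRate * W * H))
        px <- runif(nPar, 0, W); py <- runif(nPar, 0, H)
        dens <- rowSums(exp(-(outer(cx, px, "-")^2 + outer(cy, py, "-")^2) /
                              (2 * params@clusterSD^2)))
        pc <- if (sum(dens) > 0) dens / sum(dens) else rep(1 / length(cx), length(cx))
      } else pc <- 0
      prob <- (1 - w) * pe + w * pc
      cell <- sample.int(length(cx), nj, replace = TRUE, prob = prob)
      x <- cx[cell] + runif(nj, -cw / 2, cw / 2)
      y <- cy[cell] + runif(nj, -ch / 2, ch / 2)
      out[[j]] <- data.frame(x = pmin(pmax(x, 0), W - 1e-9),
                             y = pmin(pmax(y, 0), H - 1e-9),
                             species = sprintf("sp%02d", j),
                             dbh = 1 + rexp(nj, 1 / 7),
                             stringsAsFactors = FALSE)
    }
    stems <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(stems) <- NULL
    new("StemMap", plotWidth = W, plotHeight = H, stems = stems)
  })
}

#' Canonical simulation scenarios
#'
#' Fixed parameterizations of the generator used throughout the test
#' suite and documentation, on the standard 260 x 200 m plot:
#' \describe{
#'   \item{\code{random}}{complete spatial randomness
#'     (\code{nicheStrength = 0}, \code{mixtureWeight = 0}).}
#'   \item{\code{pure_env}}{environmental filtering only
#'     (\code{nicheStrength = 2}, \code{mixtureWeight = 0}).}
#'   \item{\code{pure_dispersal}}{dispersal limitation only
#'     (\code{nicheStrength = 0}, \code{mixtureWeight = 1},
#'     \code{clusterSD = 12} m).}
#'   \item{\code{mixed}}{both processes
#'     (\code{nicheStrength = 1.2}, \code{mixtureWeight = 0.5}).}
#' }
#'
#' @param name scenario name.
#' @param seed master seed; the environment and community draws use
#'   decoupled sub-seeds.
#' @param nSpecies,nStems community size (defaults 40 species, 16,000
#'   stems, the order of magnitude of a fully censused 5.2-ha temperate
#'   plot).
#' @param plotWidth,plotHeight plot dimensions (m).
#' @return A list with elements \code{env} ([EnvField-class]),
#'   \code{stems} ([StemMap-class]) and \code{params}
#'   ([CommunityParams-class]).
#' @examples
#' sc <- scenario("random", seed = 1, nStems = 500)
#' nStems(sc$stems)
#' @export
scenario <- function(name = c("pure_env", "pure_dispersal", "mixed", "random"),
                     seed = 1, nSpecies = 40, nStems = 16000,
                     plotWidth = 260, plotHeight = 200) {
  name <- match.arg(name)
  pars <- switch(name,
    random         = list(nicheStrength = 0,   mixtureWeight = 0),
    pure_env       = list(nicheStrength = 2,   mixtureWeight = 0),
    pure_dispersal = list(nicheStrength = 0,   mixtureWeight = 1),
    mixed          = list(nicheStrength = 1.2, mixtureWeight = 0.5))
  env <- generateEnvironment(plotWidth, plotHeight, seed = subSeed(seed, 1L))
  cp <- CommunityParams(nSpecies = nSpecies, nStems = nStems,
                        nicheStrength = pars$nicheStrength,
                        mixtureWeight = pars$mixtureWeight,
                        seed = subSeed(seed, 2L))
  list(env = env, stems = generateCommunity(env, cp), params = cp)
}
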