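#' Continuous synthetic environmental surfaces
#'
#' A set of smooth random surfaces over the plot — six soil-like
#' variables (organic matter, pH, total N, P, K, rootable depth) plus an
#' elevation surface — each a stationary Gaussian random field with
#' exponential spatial correlation \eqn{C(d) = \exp(-d / \phi)} (range
#' parameter \eqn{\phi} in metres) and a chosen marginal mean and sd.
#' Fields are simulated by Cholesky factorization on a regular grid and
#' evaluated anywhere in the plot by bilinear interpolation, so a field
#' is a deterministic function of (seed, parameters).  Rootable depth is
#' clamped to the physically meaningful 10–130 cm band; elevation may
#' carry a deterministic linear trend so slopes and aspects are
#' non-degenerate.
#'
#' @slot plotWidth,plotHeight plot dimensions (m).
#' @slot gridRes simulation grid resolution (m).
#' @slot grids named list of node-value matrices (one per variable).
#' @slot params the per-variable parameter list used.
#' @slot seed the seed the field was generated from.
#' @seealso [generateEnvironment()], [evalField()], [sampleEnvTable()]
#' @export
setClass("EnvField",
  slots = c(plotWidth = "numeric", plotHeight = "numeric",
            gridRes = "numeric", grids = "list", params = "list",
            seed = "integer"))

setMethod("show", "EnvField", function(object) {
  cat(sprintf("EnvField: %s over %g x %g m (grid %g m, seed %d)\n",
              paste(names(object@grids), collapse = ", "),
              object@plotWidth, object@plotHeight, object@gridRes,
              object@seed))
})

#' @describeIn EnvField plot dimensions \code{c(width, height)}.
#' @param x an \code{EnvField}.
#' @export
setMethod("plotDim", "EnvField", function(x) c(x@plotWidth, x@plotHeight))

# Default per-variable field parameters: mean, sd and exponential
# correlation range (m), with plausible temperate-forest soil values.
defaultEnvParams <- function() list(
  om    = list(mean = 8,    sd = 2.5,  range = 60),
  ph    = list(mean = 5.5,  sd = 0.4,  range = 60),
  tn    = list(mean = 3000, sd = 800,  range = 50),
  p     = list(mean = 30,   sd = 10,   range = 50),
  k     = list(mean = 150,  sd = 40,   range = 50),
  depth = list(mean = 70,   sd = 25,   range = 80, clamp = c(10, 130)),
  elev  = list(mean = 800,  sd = 8,    range = 100, trend = c(0.04, 0.02))
)

#' Generate synthetic environmental surfaces
#'
#' Simulates the [EnvField-class] surfaces on a regular grid: one draw
#' of a unit-variance Gaussian random field with exponential correlation
#' per variable, scaled to the requested mean/sd, plus any linear trend
#' (elevation) and clamping (rootable depth).
#'
#' @param plotWidth,plotHeight plot dimensions in metres.
#' @param params named list of per-variable parameter lists
#'   (\code{mean}, \code{sd}, \code{range}, optional \code{trend},
#'   \code{clamp}); defaults cover om, ph, tn, p, k, depth, elev.
#'   Supplied entries are merged over the defaults.
#' @param gridRes simulation grid resolution in metres (default 10).
#' @param seed RNG seed; same seed, same surfaces.
#' @return An [EnvField-class].
#' @examples
#' env <- generateEnvironment(100, 100, seed = 1)
#' evalField(env, "ph", 50, 50)
#' @export
generateEnvironment <- function(plotWidth = 260, plotHeight = 200,
                                params = list(), gridRes = 10, seed = 1) {
  pars <- defaultEnvParams()
  for (nm in names(params)) pars[[nm]] <- modifyList(pars[[nm]] %||% list(), params[[nm]])
  for (nm in names(pars))
    if (!is.finite(pars[[nm]]$range) || pars[[nm]]$range <= 0)
      stopf("correlation range for '%s' must be positive", nm)
  xs <- seq(0, by = gridRes, length.out = ceiling(plotWidth / gridRes) + 1L)
  ys <- seq(0, by = gridRes, length.out = ceiling(plotHeight / gridRes) + 1L)
  nodes <- expand.grid(x = xs, y = ys)
  D <- as.matrix(dist(nodes))
  grids <- withSeed(seed, {
    cholCache <- list()
    lapply(pars, function(p) {
      key <- as.character(p$range)
      if (is.null(cholCache[[key]])) {
        Sigma <- exp(-D / p$range)
        diag(Sigma) <- diag(Sigma) + 1e-8
        cholCache[[key]] <<- chol(Sigma)
      }
      z <- as.numeric(crossprod(cholCache[[key]], rnorm(nrow(nodes))))
      v <- p$mean + p$sd * z
      if (!is.null(p$trend)) v <- v + p$trend[1] * nodes$x + p$trend[2] * nodes$y
      if (!is.null(p$clamp)) v <- pmin(pmax(v, p$clamp[1]), p$clamp[2])
      matrix(v, nrow = length(xs), ncol = length(ys))
    })
  })
  new("EnvField", plotWidth = as.numeric(plotWidth),
      plotHeight = as.numeric(plotHeight), gridRes = as.numeric(gridRes),
      grids = grids, params = pars, seed = as.integer(seed))
}

#' Evaluate a synthetic surface
#'
#' Bilinear interpolation of one [EnvField-class] variable at arbitrary
#' plot coordinates.
#'
#' @param field an [EnvField-class].
#' @param variable one of \code{names(field@grids)}.
#' @param x,y coordinates in metres (vectors of equal length).
#' @return Numeric vector of surface values.
#' @export
evalField <- function(field, variable, x, y) {
  g <- field@grids[[variable]]
  if (is.null(g)) stopf("unknown variable '%s'", variable)
  res <- field@gridRes
  nx <- nrow(g); ny <- ncol(g)
  fx <- pmin(pmax(x / res, 0), nx - 1 - 1e-9)
  fy <- pmin(pmax(y / res, 0), ny - 1 - 1e-9)
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L
  g[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    g[cbind(i0 + 1L, j0)] * tx * (1 - ty) +
    g[cbind(i0, j0 + 1L)] * (1 - tx) * ty +
    g[cbind(i0 + 1L, j0 + 1L)] * tx * ty
}

#' Sample an environmental field at the base-grain design
#'
#' Evaluates the six soil surfaces at the centres of the base
#' (\code{baseGrain} x \code{baseGrain} m) grains and the elevation
#' surface at every base-grain vertex, producing the sample table a
#' field campaign would deliver.
#'
#' @param field an [EnvField-class].
#' @param baseGrain base grain size in metres (default 20).
#' @return An [EnvSampleTable-class].
#' @export
sampleEnvTable <- function(field, baseGrain = 20) {
  design <- makeGrainDesign(field@plotWidth, field@plotHeight, baseGrain)
  ce <- grainCentroids(design)
  soil <- data.frame(cx = ce$cx, cy = ce$cy)
  for (v in c("om", "ph", "tn", "p", "k", "depth"))
    soil[[v]] <- evalField(field, v, ce$cx, ce$cy)
  vx <- seq(0, design@nX) * baseGrain
  vy <- seq(0, design@nY) * baseGrain
  vert <- expand.grid(vx = vx, vy = vy)
  # vertices on the far plot edge may lie outside the interpolation grid
  # support only when the plot is not grid-aligned; evalField clamps.
  vert$elev <- evalField(field, "elev", vert$vx, vert$vy)
  EnvSampleTable(soil, vert, plotWidth = field@plotWidth,
                 plotHeight = field@plotHeight, baseGrain = baseGrain)
}
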