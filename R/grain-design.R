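#' Square-grain tiling of a rectangular plot
#'
#' Divides a \code{plotWidth} x \code{plotHeight} plot into disjoint
#' square grains of side \code{grainSize}, anchored at the plot origin
#' (lower-left corner).  When the grain width does not divide the plot
#' width exactly, the remainder strips along the high-x and high-y edges
#' are excluded from the design, so the covered area can be smaller than
#' the plot area.  Grain membership follows the half-open convention
#' \eqn{[x_0, x_0+g) \times [y_0, y_0+g)}: every stem inside the covered
#' region belongs to exactly one grain.
#'
#' Grains are indexed row-major from the origin: grain id \code{1} is the
#' lower-left grain, ids increase along x first, then y.
#'
#' @slot grainSize grain side length in metres.
#' @slot nX,nY number of grains along each axis.
#' @slot plotWidth,plotHeight plot dimensions in metres.
#' @seealso [makeGrainDesign()]
#' @export
setClass("GrainDesign",
  slots = c(grainSize = "numeric", nX = "integer", nY = "integer",
            plotWidth = "numeric", plotHeight = "numeric"))

setValidity("GrainDesign", function(object) {
  g <- object@grainSize
  if (length(g) != 1L || !is.finite(g) || g <= 0)
    return("grainSize must be a positive number")
  if (g > min(object@plotWidth, object@plotHeight))
    return("grainSize exceeds a plot dimension")
  if (object@nX != floor(object@plotWidth / g) ||
      object@nY != floor(object@plotHeight / g))
    return("grain counts inconsistent with plot dimensions")
  TRUE
})

#' Create a grain design
#'
#' @param plotWidth,plotHeight plot dimensions in metres.
#' @param grainSize grain side length in metres; must not exceed either
#'   plot dimension.
#' @return A [GrainDesign-class].
#' @examples
#' d <- makeGrainDesign(260, 200, 20)
#' nGrains(d)       # 130
#' coveredArea(d)   # 5.2 ha
#' @export
makeGrainDesign <- function(plotWidth, plotHeight, grainSize) {
  if (!is.numeric(grainSize) || length(grainSize) != 1L ||
      !is.finite(grainSize) || grainSize <= 0)
    stopf("grainSize must be a single positive number")
  if (grainSize > min(plotWidth, plotHeight))
    stopf("grainSize (%g m) exceeds a plot dimension (%g x %g m)",
          grainSize, plotWidth, plotHeight)
  new("GrainDesign", grainSize = as.numeric(grainSize),
      nX = as.integer(floor(plotWidth / grainSize)),
      nY = as.integer(floor(plotHeight / grainSize)),
      plotWidth = as.numeric(plotWidth), plotHeight = as.numeric(plotHeight))
}

#' @describeIn GrainDesign grain side length (m).
#' @param x a \code{GrainDesign}.
#' @export
setMethod("grainSize", "GrainDesign", function(x) x@grainSize)

#' @describeIn GrainDesign number of grains in the design.
#' @export
setMethod("nGrains", "GrainDesign", function(x) as.integer(x@nX * x@nY))

#' @describeIn GrainDesign covered area in hectares
#'   (\code{nGrains * grainSize^2 / 1e4}).
#' @export
setMethod("coveredArea", "GrainDesign",
          function(x) nGrains(x) * x@grainSize^2 / 1e4)

#' @describeIn GrainDesign plot dimensions \code{c(width, height)}.
#' @export
setMethod("plotDim", "GrainDesign", function(x) c(x@plotWidth, x@plotHeight))

#' @describeIn GrainDesign data.frame of grain ids and lower-left corners
#'   \code{(x0, y0)} in metres.
#' @export
setMethod("grainCorners", "GrainDesign", function(x) {
  ix <- rep(seq_len(x@nX) - 1L, times = x@nY)
  iy <- rep(seq_len(x@nY) - 1L, each = x@nX)
  data.frame(grain = seq_len(x@nX * x@nY),
             x0 = ix * x@grainSize, y0 = iy * x@grainSize)
})

#' @describeIn GrainDesign data.frame of grain ids and centroids
#'   \code{(cx, cy)} in metres.
#' @export
setMethod("grainCentroids", "GrainDesign", function(x) {
  cc <- grainCorners(x)
  data.frame(grain = cc$grain, cx = cc$x0 + x@grainSize / 2,
             cy = cc$y0 + x@grainSize / 2)
})

setMethod("show", "GrainDesign", function(object) {
  cat(sprintf("GrainDesign: %g x %g m grains, %d x %d = %d grains, %.4g ha covered (plot %g x %g m)\n",
              object@grainSize, object@grainSize, object@nX, object@nY,
              nGrains(object), coveredArea(object),
              object@plotWidth, object@plotHeight))
})

# Map stem coordinates to grain ids; NA for stems in the excluded
# remainder strips.
grainIndex <- function(design, x, y) {
  g <- design@grainSize
  ix <- floor(x / g); iy <- floor(y / g)
  id <- iy * design@nX + ix + 1
  id[ix < 0 | ix >= design@nX | iy < 0 | iy >= design@nY] <- NA_integer_
  as.integer(id)
}
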