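#' Topographic metrics per grain
#'
#' Computes the four standard large-plot topographic variables for each
#' grain of a design from grain-vertex elevations, following the
#' conventions of forest dynamics plot networks:
#' \describe{
#'   \item{mean elevation}{mean of the grain's four vertex elevations
#'     (m).}
#'   \item{slope}{mean of the slopes of the four triangular planes
#'     obtained by dropping each vertex in turn (degrees).}
#'   \item{aspect}{downslope bearing of the least-squares plane through
#'     the four vertices, in degrees clockwise from north (+y).  Flat
#'     grains get aspect 0 and \code{flat = TRUE}.}
#'   \item{convexity}{grain mean elevation minus the mean of the mean
#'     elevations of its (up to 8) neighbouring grains (m); edge grains
#'     use the available neighbours.}
#' }
#' Elevations are taken from the base-design vertex table; vertices of
#' coarser designs that do not coincide with measured base vertices are
#' bilinearly interpolated from the base vertex grid.
#'
#' @param samples an [EnvSampleTable-class] carrying base-grain vertex
#'   elevations.
#' @param design target [GrainDesign-class].
#' @return data.frame with columns \code{grain}, \code{meanElev},
#'   \code{slope}, \code{aspect}, \code{convexity}, \code{flat}.
#' @export
topoMetrics <- function(samples, design) {
  stopifnot(is(samples, "EnvSampleTable"), is(design, "GrainDesign"))
  vert <- samples@vertices
  b <- samples@baseGrain
  vx <- sort(unique(vert$vx)); vy <- sort(unique(vert$vy))
  Zm <- matrix(NA_real_, length(vx), length(vy))
  Zm[cbind(match(vert$vx, vx), match(vert$vy, vy))] <- vert$elev
  if (anyNA(Zm)) stopf("base vertex elevation grid is incomplete")
  elevAt <- function(x, y) {
    # bilinear interpolation on the (regular) base vertex grid
    fx <- pmin(pmax(x / b, 0), length(vx) - 1 - 1e-9)
    fy <- pmin(pmax(y / b, 0), length(vy) - 1 - 1e-9)
    i0 <- as.integer(floor(fx)); j0 <- as.integer(floor(fy))
    tx <- fx - i0; ty <- fy - j0
    i0 <- i0 + 1L; j0 <- j0 + 1L
    Zm[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
      Zm[cbind(i0 + 1L, j0)] * tx * (1 - ty) +
      Zm[cbind(i0, j0 + 1L)] * (1 - tx) * ty +
      Zm[cbind(i0 + 1L, j0 + 1L)] * tx * ty
  }
  g <- design@grainSize
  cc <- grainCorners(design)
  z00 <- elevAt(cc$x0,     cc$y0)
  z10 <- elevAt(cc$x0 + g, cc$y0)
  z01 <- elevAt(cc$x0,     cc$y0 + g)
  z11 <- elevAt(cc$x0 + g, cc$y0 + g)
  meanElev <- (z00 + z10 + z01 + z11) / 4
  # slope: mean over the four triangles formed by omitting one vertex
  triSlope <- function(p1, p2, p3) {
    # plane through three (x, y, z) points; slope = atan(|grad|)
    u <- p2 - p1; v <- p3 - p1
    nx <- u[2] * v[3] - u[3] * v[2]
    ny <- u[3] * v[1] - u[1] * v[3]
    nz <- u[1] * v[2] - u[2] * v[1]
    atan2(sqrt(nx^2 + ny^2), abs(nz)) * 180 / pi
  }
  slope <- vapply(seq_len(nrow(cc)), function(i) {
    P <- list(c(0, 0, z00[i]), c(g, 0, z10[i]), c(0, g, z01[i]), c(g, g, z11[i]))
    mean(vapply(seq_len(4), function(drop)
      do.call(triSlope, P[-drop]), numeric(1)))
  }, numeric(1))
  # aspect from the least-squares plane z = a + bx + cy over the 4 corners
  gb <- ((z10 + z11) - (z00 + z01)) / (2 * g)
  gc_ <- ((z01 + z11) - (z00 + z10)) / (2 * g)
  flat <- sqrt(gb^2 + gc_^2) < 1e-10
  aspect <- (atan2(-gb, -gc_) * 180 / pi) %% 360
  aspect[flat] <- 0
  # convexity against the 8-neighbour mean elevation
  nX <- design@nX; nY <- design@nY
  M <- matrix(meanElev, nX, nY)
  conv <- matrix(NA_real_, nX, nY)
  for (ix in seq_len(nX)) for (iy in seq_len(nY)) {
    nb <- expand.grid(dx = -1:1, dy = -1:1)
    nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
    jx <- ix + nb$dx; jy <- iy + nb$dy
    ok <- jx >= 1 & jx <= nX & jy >= 1 & jy <= nY
    conv[ix, iy] <- M[ix, iy] - mean(M[cbind(jx[ok], jy[ok])])
  }
  data.frame(grain = cc$grain, meanElev = meanElev, slope = slope,
             aspect = aspect, convexity = as.numeric(conv), flat = flat)
}

#' Full per-grain environmental covariate table
#'
#' Combines the six upscaled soil variables with the four topographic
#' metrics into the grains-by-covariates matrix used as environmental
#' predictors in ordination.
#'
#' @inheritParams upscaleEnvironment
#' @return data.frame: \code{grain}, six soil columns, \code{meanElev},
#'   \code{slope}, \code{aspect}, \code{convexity}; no missing values.
#' @export
envMatrix <- function(samples, design, method = c("block_mean", "kriging")) {
  soil <- upscaleEnvironment(samples, design, method)
  topo <- topoMetrics(samples, design)
  out <- merge(soil, topo[, c("grain", "meanElev", "slope", "aspect",
                              "convexity")], by = "grain", sort = TRUE)
  out[order(out$grain), , drop = FALSE]
}
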