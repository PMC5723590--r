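#' Per-grain environmental samples
#'
#' Field-campaign style environmental data on the base grain design: one
#' averaged soil record per base grain (organic matter %, pH, total N,
#' P and K in p.p.m., rootable depth in cm) keyed by the grain centre,
#' plus elevation (m) measured at every base-grain vertex.  Exactly one
#' record per base grain is required; duplicates and missing grains are
#' rejected at construction.
#'
#' @slot samples data.frame with columns \code{cx}, \code{cy} (grain
#'   centre, m), \code{om}, \code{ph}, \code{tn}, \code{p}, \code{k},
#'   \code{depth}.
#' @slot vertices data.frame with columns \code{vx}, \code{vy},
#'   \code{elev}: elevations at base-grain vertices.
#' @slot plotWidth,plotHeight plot dimensions (m).
#' @slot baseGrain base grain size (m), conventionally 20.
#' @seealso [readEnvSamples()], [upscaleEnvironment()], [topoMetrics()]
#' @export
setClass("EnvSampleTable",
  slots = c(samples = "data.frame", vertices = "data.frame",
            plotWidth = "numeric", plotHeight = "numeric",
            baseGrain = "numeric"))

.soilVars <- c("om", "ph", "tn", "p", "k", "depth")

setValidity("EnvSampleTable", function(object) {
  s <- object@samples
  need <- c("cx", "cy", .soilVars)
  missing <- setdiff(need, names(s))
  if (length(missing))
    return(sprintf("samples missing column(s): %s", paste(missing, collapse = ", ")))
  for (v in need) if (!is.numeric(s[[v]]))
    return(sprintf("column '%s' must be numeric", v))
  key <- paste(s$cx, s$cy)
  if (anyDuplicated(key))
    return(sprintf("duplicate grain centre(s): %s",
                   paste(unique(key[duplicated(key)]), collapse = "; ")))
  design <- makeGrainDesign(object@plotWidth, object@plotHeight, object@baseGrain)
  ce <- grainCentroids(design)
  expected <- paste(ce$cx, ce$cy)
  absent <- setdiff(expected, key)
  if (length(absent))
    return(sprintf("incomplete: missing record(s) for grain centre(s) %s",
                   paste(head(absent, 5L), collapse = "; ")))
  extra <- setdiff(key, expected)
  if (length(extra))
    return(sprintf("record(s) at non-grain-centre coordinates: %s",
                   paste(head(extra, 5L), collapse = "; ")))
  if (any(s$ph < 0)) return("negative pH is not a valid soil measurement")
  if (any(s$depth <= 0)) return("rootable depth must be positive")
  v <- object@vertices
  if (!all(c("vx", "vy", "elev") %in% names(v)))
    return("vertices must have columns vx, vy, elev")
  TRUE
})

#' Construct an environmental sample table
#'
#' @param samples data.frame of per-grain soil records (see
#'   [EnvSampleTable-class]); rows are reordered to base-design grain
#'   order.
#' @param vertices data.frame of vertex elevations.
#' @param plotWidth,plotHeight plot dimensions (m).
#' @param baseGrain base grain size (m), default 20.
#' @return An [EnvSampleTable-class].
#' @export
EnvSampleTable <- function(samples, vertices, plotWidth, plotHeight,
                           baseGrain = 20) {
  obj <- new("EnvSampleTable", samples = as.data.frame(samples),
             vertices = as.data.frame(vertices),
             plotWidth = as.numeric(plotWidth),
             plotHeight = as.numeric(plotHeight),
             baseGrain = as.numeric(baseGrain))
  # canonical row order: base-design grain order
  design <- makeGrainDesign(plotWidth, plotHeight, baseGrain)
  ce <- grainCentroids(design)
  idx <- match(paste(ce$cx, ce$cy), paste(obj@samples$cx, obj@samples$cy))
  obj@samples <- obj@samples[idx, , drop = FALSE]
  rownames(obj@samples) <- NULL
  obj
}

setMethod("show", "EnvSampleTable", function(object) {
  cat(sprintf("EnvSampleTable: %d soil records (%g m base grain), %d vertex elevations, %g x %g m plot\n",
              nrow(object@samples), object@baseGrain, nrow(object@vertices),
              object@plotWidth, object@plotHeight))
})

#' @describeIn EnvSampleTable plot dimensions \code{c(width, height)}.
#' @param x an \code{EnvSampleTable}.
#' @export
setMethod("plotDim", "EnvSampleTable", function(x) c(x@plotWidth, x@plotHeight))
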