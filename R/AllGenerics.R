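#' @export
setGeneric("plotDim", function(x) standardGeneric("plotDim"))

#' @export
setGeneric("stems", function(x) standardGeneric("stems"))

#' @export
setGeneric("nStems", function(x) standardGeneric("nStems"))

#' @export
setGeneric("grainSize", function(x) standardGeneric("grainSize"))

#' @export
setGeneric("nGrains", function(x) standardGeneric("nGrains"))

#' @export
setGeneric("coveredArea", function(x) standardGeneric("coveredArea"))

#' @export
setGeneric("grainCorners", function(x) standardGeneric("grainCorners"))

#' @export
setGeneric("grainCentroids", function(x) standardGeneric("grainCentroids"))

#' @export
setGeneric("communityMatrix", function(x, ...) standardGeneric("communityMatrix"))

#' @export
setGeneric("hellingerTransform", function(x, ...) standardGeneric("hellingerTransform"))

#' @export
setGeneric("betaDiversity", function(x, ...) standardGeneric("betaDiversity"))

#' @export
setGeneric("bdTotal", function(x, ...) standardGeneric("bdTotal"))

#' @export
setGeneric("lcbd", function(x, ...) standardGeneric("lcbd"))

#' @export
setGeneric("ssTotal", function(x, ...) standardGeneric("ssTotal"))

#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @export
setGeneric("moran", function(x) standardGeneric("moran"))

#' @export
setGeneric("truncationDistance", function(x) standardGeneric("truncationDistance"))

#' @export
setGeneric("fractions", function(x, ...) standardGeneric("fractions"))

#' @export
setGeneric("selectedVars", function(x) standardGeneric("selectedVars"))
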