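#' Grains-by-species community table
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the abundance
#' table of one grain design: the \code{"counts"} assay is species (rows)
#' by grains (columns), with \code{colData} carrying each grain's id,
#' lower-left corner and centroid (and, once attached, environmental
#' covariates).  The originating [GrainDesign-class] is stored in
#' \code{metadata(x)$design}.  The analysis-facing orientation — the
#' grains-by-species matrix \eqn{X = [x_{ij}]} with \eqn{x_{ij}} the
#' number of living stems of species \eqn{j} in grain \eqn{i} — is
#' returned by [communityMatrix()].
#'
#' @seealso [aggregateCommunity()], [hellingerTransform()],
#'   [betaDiversity()]
#' @export
setClass("GrainCommunity", contains = "SummarizedExperiment")

setValidity("GrainCommunity", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("GrainCommunity requires a 'counts' assay")
  m <- assay(object, "counts")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be nonnegative integers")
  if (!all(c("grain", "cx", "cy") %in% names(colData(object))))
    return("colData must contain grain, cx, cy")
  TRUE
})

#' Aggregate a stem map into a grains-by-species abundance table
#'
#' Counts the number of living stems of every species falling inside each
#' grain of \code{design}.  Stems lying in the remainder strips excluded
#' by the design are dropped; species with zero total abundance inside
#' the covered area are dropped from the table.
#'
#' @param stemMap a [StemMap-class].
#' @param design a [GrainDesign-class] with the same plot dimensions.
#' @return A [GrainCommunity-class] with one column per grain (including
#'   empty grains) and one row per species observed in the covered area.
#' @examples
#' sm <- StemMap(x = 5, y = 5, species = "A", dbh = 3,
#'               plotWidth = 40, plotHeight = 40)
#' gc <- aggregateCommunity(sm, makeGrainDesign(40, 40, 20))
#' communityMatrix(gc)
#' @export
aggregateCommunity <- function(stemMap, design) {
  stopifnot(is(stemMap, "StemMap"), is(design, "GrainDesign"))
  if (!isTRUE(all.equal(plotDim(stemMap), plotDim(design))))
    stopf("stem map (%g x %g m) and grain design (%g x %g m) disagree on plot dimensions",
          stemMap@plotWidth, stemMap@plotHeight,
          design@plotWidth, design@plotHeight)
  s <- stems(stemMap)
  gid <- grainIndex(design, s$x, s$y)
  keep <- !is.na(gid)
  n <- nGrains(design)
  sp <- sort(unique(s$species[keep]))
  X <- matrix(0L, nrow = length(sp), ncol = n,
              dimnames = list(sp, paste0("g", seq_len(n))))
  if (any(keep)) {
    tab <- table(factor(s$species[keep], levels = sp),
                 factor(gid[keep], levels = seq_len(n)))
    X[] <- as.integer(tab)
  }
  cc <- grainCorners(design)
  ce <- grainCentroids(design)
  cd <- DataFrame(grain = cc$grain, x0 = cc$x0, y0 = cc$y0,
                  cx = ce$cx, cy = ce$cy, row.names = colnames(X))
  se <- SummarizedExperiment(assays = list(counts = X), colData = cd)
  out <- new("GrainCommunity", se)
  metadata(out)$design <- design
  out
}

#' @describeIn aggregateCommunity the grains-by-species abundance matrix
#'   \eqn{X} (grains as rows).
#' @param x a \code{GrainCommunity}.
#' @param assayName which assay to return, default \code{"counts"}.
#' @export
setMethod("communityMatrix", "GrainCommunity",
          function(x, assayName = "counts") t(assay(x, assayName)))

#' @describeIn aggregateCommunity the grain design the table was built on.
#' @export
setMethod("grainSize", "GrainCommunity",
          function(x) grainSize(metadata(x)$design))

#' @describeIn aggregateCommunity number of grains (columns).
#' @export
setMethod("nGrains", "GrainCommunity", function(x) ncol(x))

#' @describeIn aggregateCommunity grain centroids from \code{colData}.
#' @export
setMethod("grainCentroids", "GrainCommunity", function(x) {
  data.frame(grain = colData(x)$grain, cx = colData(x)$cx, cy = colData(x)$cy)
})

#' Drop grains with zero stems
#'
#' The Hellinger transform is undefined on empty grains (zero row sums).
#' Field plots of the densities considered here essentially never produce
#' empty 20-m grains, but sparse synthetic communities can; such grains
#' are removed with a warning before transformation.
#'
#' @param x a [GrainCommunity-class].
#' @param action \code{"drop"} (default) removes empty grains with a
#'   warning; \code{"error"} aborts instead.
#' @return \code{x} without empty-grain columns.
#' @export
dropEmptyGrains <- function(x, action = c("drop", "error")) {
  action <- match.arg(action)
  tot <- colSums(assay(x, "counts"))
  empty <- which(tot == 0)
  if (!length(empty)) return(x)
  if (action == "error")
    stopf("%d empty grain(s): %s", length(empty),
          paste(colData(x)$grain[empty], collapse = ", "))
  warning(sprintf("dropping %d empty grain(s): %s", length(empty),
                  paste(colData(x)$grain[empty], collapse = ", ")),
          call. = FALSE)
  x[, -empty]
}
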