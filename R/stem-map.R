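#' Stem map of a rectangular forest plot
#'
#' A point pattern of trees inside a \code{plotWidth} x \code{plotHeight}
#' metre rectangle with the plot origin at the lower-left corner.  Each
#' stem carries continuous coordinates (half-open convention: \code{0 <= x
#' < plotWidth}), a species label and a diameter at breast height (dbh)
#' in centimetres.  Only stems with dbh >= 1 cm belong in a stem map,
#' mirroring the census rule of large forest-dynamics plots.
#'
#' @slot plotWidth,plotHeight plot dimensions in metres.
#' @slot stems \code{data.frame} with columns \code{x}, \code{y} (metres),
#'   \code{species} (character, nonempty) and \code{dbh} (cm, >= 1).
#'
#' @seealso [StemMap()] to construct, [readStemMap()] / [writeStemMap()]
#'   for on-disk TSV, [aggregateCommunity()] to count stems per grain.
#' @export
setClass("StemMap",
  slots = c(plotWidth = "numeric", plotHeight = "numeric",
            stems = "data.frame"))

setValidity("StemMap", function(object) {
  w <- object@plotWidth; h <- object@plotHeight
  s <- object@stems
  msg <- character()
  if (length(w) != 1L || !is.finite(w) || w <= 0) msg <- c(msg, "plotWidth must be a positive number")
  if (length(h) != 1L || !is.finite(h) || h <= 0) msg <- c(msg, "plotHeight must be a positive number")
  need <- c("x", "y", "species", "dbh")
  missing <- setdiff(need, names(s))
  if (length(missing))
    return(sprintf("stems is missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(s)) {
    bad <- which(s$x < 0 | s$x >= w | s$y < 0 | s$y >= h)
    if (length(bad))
      msg <- c(msg, sprintf("stem row(s) %s outside the plot [0,%g) x [0,%g)",
                            paste(head(bad, 5L), collapse = ", "), w, h))
    baddbh <- which(!is.finite(s$dbh) | s$dbh < 1)
    if (length(baddbh))
      msg <- c(msg, sprintf("stem row(s) %s have dbh < 1 cm",
                            paste(head(baddbh, 5L), collapse = ", ")))
    if (any(!nzchar(as.character(s$species))) || anyNA(s$species))
      msg <- c(msg, "species labels must be nonempty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a stem map
#'
#' @param x,y stem coordinates in metres, origin at the plot lower-left
#'   corner; must satisfy \code{0 <= x < plotWidth}, \code{0 <= y <
#'   plotHeight}.
#' @param species character vector of species labels.
#' @param dbh diameters at breast height in cm (>= 1).
#' @param plotWidth,plotHeight plot dimensions in metres.
#' @return A [StemMap-class] object.
#' @examples
#' sm <- StemMap(x = c(1, 5), y = c(2, 3), species = c("A", "B"),
#'               dbh = c(10, 2), plotWidth = 20, plotHeight = 20)
#' nStems(sm)
#' @export
StemMap <- function(x = numeric(), y = numeric(), species = character(),
                    dbh = numeric(), plotWidth, plotHeight) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   species = as.character(species), dbh = as.numeric(dbh),
                   stringsAsFactors = FALSE)
  new("StemMap", plotWidth = as.numeric(plotWidth),
      plotHeight = as.numeric(plotHeight), stems = df)
}

#' @describeIn StemMap plot dimensions \code{c(width, height)} in metres.
#' @param x a \code{StemMap}.
#' @export
setMethod("plotDim", "StemMap", function(x) c(x@plotWidth, x@plotHeight))

#' @describeIn StemMap the stem table.
#' @export
setMethod("stems", "StemMap", function(x) x@stems)

#' @describeIn StemMap number of stems.
#' @export
setMethod("nStems", "StemMap", function(x) nrow(x@stems))

setMethod("show", "StemMap", function(object) {
  cat(sprintf("StemMap: %d stems, %d species, %g x %g m plot\n",
              nrow(object@stems), length(unique(object@stems$species)),
              object@plotWidth, object@plotHeight))
})
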