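# Tabular I/O: tab-separated, decimal point, UTF-8 throughout.  Writers
# put the plot dimensions in a '# plot <width> <height>' comment so the
# paired reader is self-contained; every rejected row is reported with
# its row number.

.readPlotComment <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) return(NULL)
  m <- regmatches(first, regexec("plot[ =]+([0-9.]+)[ x]+([0-9.]+)", first))[[1]]
  if (length(m) == 3) as.numeric(m[2:3]) else NULL
}

.readTSV <- function(path, columns) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stopf("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Read / write a stem map as TSV
#'
#' Columns \code{x}, \code{y}, \code{species}, \code{dbh}; the plot
#' dimensions travel in a leading \code{# plot <w> <h>} comment (or can
#' be given explicitly, overriding the comment).  Rows are validated:
#' out-of-plot coordinates, dbh below the 1-cm census minimum, or empty
#' species labels are reported with their row numbers.
#'
#' @param path TSV file path.
#' @param plotWidth,plotHeight optional plot dimensions (m), required
#'   when the file carries no plot comment.
#' @return A [StemMap-class]; the writer returns \code{path} invisibly.
#' @export
readStemMap <- function(path, plotWidth = NULL, plotHeight = NULL) {
  dims <- .readPlotComment(path)
  plotWidth <- plotWidth %||% dims[1]
  plotHeight <- plotHeight %||% dims[2]
  if (is.null(plotWidth) || is.na(plotWidth))
    stopf("%s: plot dimensions not found (no '# plot' comment and none supplied)", path)
  df <- .readTSV(path, c("x", "y", "species", "dbh"))
  for (v in c("x", "y", "dbh")) if (!is.numeric(df[[v]]))
    stopf("%s: column '%s' is not numeric", path, v)
  bad <- which(df$x < 0 | df$x >= plotWidth | df$y < 0 | df$y >= plotHeight)
  if (length(bad))
    stopf("%s: row(s) %s outside the plot [0,%g) x [0,%g)", path,
          paste(head(bad, 10L), collapse = ", "), plotWidth, plotHeight)
  StemMap(df$x, df$y, df$species, df$dbh, plotWidth, plotHeight)
}

#' @rdname readStemMap
#' @param stemMap a [StemMap-class].
#' @export
writeStemMap <- function(stemMap, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# plot %g %g", stemMap@plotWidth, stemMap@plotHeight), con)
  write.table(stems(stemMap), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write environmental samples as TSV
#'
#' Soil records use columns \code{cx}, \code{cy}, \code{om}, \code{ph},
#' \code{tn}, \code{p}, \code{k}, \code{depth} (one row per base grain);
#' vertex elevations use \code{vx}, \code{vy}, \code{elev}.  Duplicate
#' grain centres, missing grains, non-numeric soil values and negative
#' pH are rejected with diagnostics.
#'
#' @param path soil-record TSV path.
#' @param verticesPath vertex-elevation TSV path.
#' @param plotWidth,plotHeight optional plot dimensions (m), read from
#'   the \code{# plot} comment when omitted.
#' @param baseGrain base grain size (m), default 20.
#' @return An [EnvSampleTable-class]; the writer returns \code{path}
#'   invisibly.
#' @export
readEnvSamples <- function(path, verticesPath, plotWidth = NULL,
                           plotHeight = NULL, baseGrain = 20) {
  dims <- .readPlotComment(path)
  plotWidth <- plotWidth %||% dims[1]
  plotHeight <- plotHeight %||% dims[2]
  if (is.null(plotWidth) || is.na(plotWidth))
    stopf("%s: plot dimensions not found", path)
  soil <- .readTSV(path, c("cx", "cy", .soilVars))
  for (v in c("cx", "cy", .soilVars)) if (!is.numeric(soil[[v]]))
    stopf("%s: column '%s' is not numeric", path, v)
  vert <- .readTSV(verticesPath, c("vx", "vy", "elev"))
  EnvSampleTable(soil, vert, plotWidth, plotHeight, baseGrain)
}

#' @rdname readEnvSamples
#' @param samples an [EnvSampleTable-class].
#' @export
writeEnvSamples <- function(samples, path, verticesPath) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(sprintf("# plot %g %g", samples@plotWidth, samples@plotHeight), con)
  write.table(samples@samples, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  write.table(samples@vertices, verticesPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a result table
#'
#' Deterministic tab-separated output for downstream result tables:
#' column order as supplied, floating-point values at a fixed precision
#' (ten significant digits), re-readable by [readResultTable()].
#'
#' @param table a data.frame.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 10).
#' @return \code{path} invisibly.
#' @export
writeResultTable <- function(table, path, digits = 10) {
  out <- as.data.frame(table)
  for (v in names(out)) if (is.double(out[[v]]))
    out[[v]] <- signif(out[[v]], digits)
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8"),
    error = function(e) stopf("cannot write '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
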