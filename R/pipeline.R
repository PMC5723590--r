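#' End-to-end study report
#'
#' Everything one run of the pipeline produces: the beta-diversity by
#' grain-size table, per-grain LCBD tables, the variation-partitioning
#' table and objects, the selected predictors, and the configuration the
#' run is reproducible from.
#'
#' @slot bdTable data.frame: grain_size, n_grains, covered_area_ha,
#'   n_species, ss_total, bd_total.
#' @slot lcbdTables named list (one per grain size) of data.frames:
#'   grain, cx, cy, lcbd.
#' @slot partitionTable long data.frame from [scaleSeriesVarpart()].
#' @slot partitions named list of [VariationPartition-class] (or NULL
#'   where nothing was selected).
#' @slot selections per grain size, the selected environmental and
#'   spatial predictors.
#' @slot config the [RunConfig-class] used.
#' @seealso [runAll()], [renderFigures()]
#' @include run-config.R
#' @export
setClass("StudyReport",
  slots = c(bdTable = "data.frame", lcbdTables = "list",
            partitionTable = "data.frame", partitions = "list",
            selections = "list", config = "RunConfig"))

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  cat("  beta diversity by grain size:\n")
  print(object@bdTable, digits = 4, row.names = FALSE)
  env <- subset(object@partitionTable, fraction == "ab")
  spc <- subset(object@partitionTable, fraction == "c")
  cat("  environment [a+b] vs space [c] (adjusted R2):\n")
  print(data.frame(grain_size = env$grain_size, env_ab = env$adjR2,
                   space_c = spc$adjR2), digits = 4, row.names = FALSE)
})

#' Run the full scale-dependent beta-diversity analysis
#'
#' Executes the whole study design for every configured grain size:
#' obtain the stem map and environmental samples (from a simulation
#' scenario or from TSV files), aggregate, compute beta diversity and
#' LCBD, build spatial and environmental predictors, forward-select, and
#' partition the variation.  When \code{config@outDir} is set, all
#' result tables are written there as TSV together with an echo of the
#' configuration.
#'
#' @param config a [RunConfig-class].
#' @return A [StudyReport-class].
#' @examples
#' \donttest{
#' rep <- runAll(runConfig(scenario = "mixed", nPerm = 99, seed = 7))
#' rep@bdTable
#' }
#' @export
runAll <- function(config) {
  stopifnot(is(config, "RunConfig"))
  if (nzchar(config@scenario)) {
    sc <- scenario(config@scenario, seed = config@seed,
                   plotWidth = config@plotWidth,
                   plotHeight = config@plotHeight)
    stemMap <- sc$stems
    envSamples <- sampleEnvTable(sc$env)
  } else {
    stemMap <- readStemMap(config@stemMapPath, config@plotWidth,
                           config@plotHeight)
    envSamples <- readEnvSamples(config@envSamplesPath, config@verticesPath,
                                 config@plotWidth, config@plotHeight)
  }
  bdRows <- list()
  lcbdTables <- list()
  for (g in config@grainSizes) {
    stage <- sprintf("grain size %g m", g)
    res <- tryCatch({
      design <- makeGrainDesign(config@plotWidth, config@plotHeight, g)
      gc <- hellingerTransform(aggregateCommunity(stemMap, design))
      bd <- betaDiversity(gc)
      ce <- grainCentroids(gc)
      list(design = design, bd = bd, nSpecies = nrow(gc), lcbd = data.frame(
        grain = ce$grain, cx = ce$cx, cy = ce$cy, lcbd = as.numeric(lcbd(bd))))
    }, error = function(e)
      stopf("beta diversity failed at %s: %s", stage, conditionMessage(e)))
    key <- sprintf("%gm", g)
    bdRows[[key]] <- data.frame(
      grain_size = g, n_grains = nGrains(res$design),
      covered_area_ha = coveredArea(res$design),
      n_species = res$nSpecies,
      ss_total = ssTotal(res$bd), bd_total = bdTotal(res$bd))
    lcbdTables[[key]] <- res$lcbd
  }
  vp <- tryCatch(
    scaleSeriesVarpart(stemMap, envSamples, config@grainSizes,
                       nPerm = config@nPerm, alpha = config@alpha,
                       seed = config@seed, envMethod = config@envMethod),
    error = function(e)
      stopf("variation partitioning failed: %s", conditionMessage(e)))
  report <- new("StudyReport", bdTable = do.call(rbind, c(bdRows, list(make.row.names = FALSE))),
                lcbdTables = lcbdTables, partitionTable = vp$table,
                partitions = vp$partitions, selections = vp$selections,
                config = config)
  if (nzchar(config@outDir)) writeReport(report, config@outDir)
  report
}

#' Write all report tables as TSV
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if absent).
#' @return \code{dir} invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeResultTable(report@bdTable, file.path(dir, "bd_by_grain.tsv"))
  for (key in names(report@lcbdTables))
    writeResultTable(report@lcbdTables[[key]],
                     file.path(dir, sprintf("lcbd_%s.tsv", key)))
  writeResultTable(report@partitionTable, file.path(dir, "varpart.tsv"))
  writeRunConfig(report@config, file.path(dir, "config_echo.yml"))
  invisible(dir)
}

#' Render the report figures
#'
#' Three PNG figures written to \code{dir}: beta diversity against grain
#' size; one shaded LCBD map per grain size (light to dark = low to high
#' local contribution); and grouped variation-partitioning bars
#' (white = environment [a+b], black = space [c]) with significance
#' stars.  Negative adjusted fractions are floored at zero for display
#' with the raw value annotated.  Rendering always goes to files, so
#' headless sessions work unchanged.
#'
#' @param report a [StudyReport-class].
#' @param dir output directory.
#' @return Character vector of files written, invisibly.
#' @export
renderFigures <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "bd_vs_grain.png")
  grDevices::png(f, 600, 450)
  with(report@bdTable, {
    plot(grain_size, bd_total, type = "b", pch = 19,
         xlab = "Grain size (m)", ylab = expression(BD[Total]),
         main = "Beta diversity vs sampling grain")
  })
  grDevices::dev.off()
  files <- c(files, f)
  for (key in names(report@lcbdTables)) {
    tab <- report@lcbdTables[[key]]
    g <- report@bdTable$grain_size[match(key, names(report@lcbdTables))]
    f <- file.path(dir, sprintf("lcbd_map_%s.png", key))
    grDevices::png(f, 650, 500)
    rng <- range(tab$lcbd)
    shade <- if (diff(rng) > 0) (tab$lcbd - rng[1]) / diff(rng) else rep(0.5, nrow(tab))
    plot(NA, xlim = c(0, report@config@plotWidth),
         ylim = c(0, report@config@plotHeight), asp = 1,
         xlab = "x (m)", ylab = "y (m)",
         main = sprintf("LCBD, %s grains", key))
    graphics::rect(tab$cx - g / 2, tab$cy - g / 2, tab$cx + g / 2,
                   tab$cy + g / 2, col = grDevices::gray(1 - 0.9 * shade),
                   border = "white")
    grDevices::dev.off()
    files <- c(files, f)
  }
  f <- file.path(dir, "varpart_bars.png")
  grDevices::png(f, 650, 450)
  env <- subset(report@partitionTable, fraction == "ab")
  spc <- subset(report@partitionTable, fraction == "c")
  hts <- rbind(pmax(env$adjR2, 0), pmax(spc$adjR2, 0))
  bp <- graphics::barplot(hts, beside = TRUE,
                          names.arg = sprintf("%g m", env$grain_size),
                          col = c("white", "black"),
                          ylim = c(0, max(hts) * 1.3 + 0.02),
                          ylab = expression(R[adj]^2),
                          legend.text = c("environment [a+b]", "space [c]"))
  stars <- rbind(env$signif_code, spc$signif_code)
  raw <- rbind(env$adjR2, spc$adjR2)
  lab <- ifelse(raw < 0, sprintf("%s(%.3f)", stars, raw), stars)
  graphics::text(bp, hts + 0.01, lab, cex = 0.9)
  grDevices::dev.off()
  invisible(c(files, f))
}
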