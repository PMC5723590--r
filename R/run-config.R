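#' Run configuration for the end-to-end pipeline
#'
#' Everything [runAll()] needs: plot dimensions, the grain sizes to
#' analyse, permutation count and significance level, the master seed,
#' the environment-upscaling method and the output directory, plus the
#' data source (either a named simulation scenario or paths to stem-map
#' and environment TSVs).
#'
#' @slot plotWidth,plotHeight plot dimensions (m).
#' @slot grainSizes grain side lengths (m), each positive and no larger
#'   than the smaller plot dimension.
#' @slot nPerm permutations for all tests (>= 1).
#' @slot alpha significance level in (0, 1).
#' @slot seed master RNG seed.
#' @slot envMethod \code{"block_mean"} or \code{"kriging"}.
#' @slot outDir output directory ("" = do not write files).
#' @slot scenario scenario name ("" when reading from files).
#' @slot stemMapPath,envSamplesPath,verticesPath input TSV paths (""
#'   when simulating).
#' @seealso [runConfig()], [readRunConfig()]
#' @export
setClass("RunConfig",
  slots = c(plotWidth = "numeric", plotHeight = "numeric",
            grainSizes = "numeric", nPerm = "integer", alpha = "numeric",
            seed = "integer", envMethod = "character", outDir = "character",
            scenario = "character", stemMapPath = "character",
            envSamplesPath = "character", verticesPath = "character"))

setValidity("RunConfig", function(object) {
  if (any(object@grainSizes <= 0) ||
      any(object@grainSizes > min(object@plotWidth, object@plotHeight)))
    return("grain sizes must be positive and no larger than the plot")
  if (object@nPerm < 1) return("nPerm must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must lie in (0, 1)")
  if (!object@envMethod %in% c("block_mean", "kriging"))
    return("envMethod must be 'block_mean' or 'kriging'")
  if (!nzchar(object@scenario) && !nzchar(object@stemMapPath))
    return("either a scenario name or a stem-map path is required")
  TRUE
})

#' @rdname RunConfig-class
#' @param plotWidth,plotHeight,grainSizes,nPerm,alpha,seed,envMethod,outDir,scenario,stemMapPath,envSamplesPath,verticesPath
#'   see the class slots.
#' @export
runConfig <- function(plotWidth = 260, plotHeight = 200,
                      grainSizes = c(20, 30, 40, 50), nPerm = 999,
                      alpha = 0.05, seed = 1, envMethod = "block_mean",
                      outDir = "", scenario = "mixed", stemMapPath = "",
                      envSamplesPath = "", verticesPath = "") {
  new("RunConfig", plotWidth = as.numeric(plotWidth),
      plotHeight = as.numeric(plotHeight),
      grainSizes = as.numeric(grainSizes), nPerm = as.integer(nPerm),
      alpha = as.numeric(alpha), seed = as.integer(seed),
      envMethod = envMethod, outDir = outDir, scenario = scenario,
      stemMapPath = stemMapPath, envSamplesPath = envSamplesPath,
      verticesPath = verticesPath)
}

setMethod("show", "RunConfig", function(object) {
  src <- if (nzchar(object@scenario))
    sprintf("scenario '%s'", object@scenario)
  else sprintf("files (%s)", object@stemMapPath)
  cat(sprintf("RunConfig: %g x %g m plot, grains {%s} m, %d perms, alpha %g, seed %d, env '%s', source %s\n",
              object@plotWidth, object@plotHeight,
              paste(object@grainSizes, collapse = ", "), object@nPerm,
              object@alpha, object@seed, object@envMethod, src))
})

#' Read / write a run configuration as YAML
#'
#' The schema mirrors the [RunConfig-class] slots under snake_case keys
#' (\code{plot_width}, \code{grain_sizes}, \code{n_perm}, \code{alpha},
#' \code{seed}, \code{env_method}, \code{out_dir}, \code{scenario},
#' \code{stem_map}, \code{env_samples}, \code{vertices}).
#'
#' @param path YAML file path.
#' @return [readRunConfig()] returns a [RunConfig-class];
#'   [writeRunConfig()] returns \code{path} invisibly.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  runConfig(plotWidth = y$plot_width %||% 260,
            plotHeight = y$plot_height %||% 200,
            grainSizes = unlist(y$grain_sizes) %||% c(20, 30, 40, 50),
            nPerm = y$n_perm %||% 999, alpha = y$alpha %||% 0.05,
            seed = y$seed %||% 1, envMethod = y$env_method %||% "block_mean",
            outDir = y$out_dir %||% "", scenario = y$scenario %||% "",
            stemMapPath = y$stem_map %||% "",
            envSamplesPath = y$env_samples %||% "",
            verticesPath = y$vertices %||% "")
}

#' @rdname readRunConfig
#' @param config a [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(list(
    plot_width = config@plotWidth, plot_height = config@plotHeight,
    grain_sizes = config@grainSizes, n_perm = config@nPerm,
    alpha = config@alpha, seed = config@seed,
    env_method = config@envMethod, out_dir = config@outDir,
    scenario = config@scenario, stem_map = config@stemMapPath,
    env_samples = config@envSamplesPath, vertices = config@verticesPath),
    path)
  invisible(path)
}
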