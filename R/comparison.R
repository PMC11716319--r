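#' @include AllClasses.R phantoms.R volumetry.R fascia.R architecture.R
NULL

#' Build a run configuration for a pre-vs-post comparison
#'
#' One home for every stage toggle and numeric default of the pipeline. The
#' configuration is a plain named list so it serializes round-trip stable
#' through YAML (\code{\link{writeRunConfig}} / \code{\link{readRunConfig}}).
#'
#' @param stages character subset of c("volumetry", "fascia", "dti")
#' @param seed integer master seed; per-stage seeds are derived from it
#' @param volumeChanges named fractional volume changes applied by the
#'   phantom pair generator
#' @param fasciaScale fascia thickness scale factor of the phantom pair
#' @param binWidth thickness histogram bin width (mm)
#' @param pennation list describing the DTI stage input (fields
#'   \code{angleDeg}, optional \code{postAngleDeg}, \code{boxDims},
#'   \code{spacing}, \code{noiseSigma}) or NULL when the dti stage is
#'   disabled or has no input
#' @param tracking tracking parameter overrides (passed to
#'   \code{\link{trackingParams}})
#' @param outDir optional output directory; when set, stage outputs are
#'   written there
#' @return a named list of class "runConfig"
#' @export
runConfig <- function(stages = c("volumetry", "fascia"), seed = 1L,
                      volumeChanges = c(femur = -0.0222), fasciaScale = 1.09,
                      binWidth = 0.05, pennation = NULL, tracking = list(),
                      outDir = NULL) {
  stages <- match.arg(stages, c("volumetry", "fascia", "dti"),
                      several.ok = TRUE)
  structure(list(stages = stages, seed = as.integer(seed),
                 volumeChanges = volumeChanges, fasciaScale = fasciaScale,
                 binWidth = binWidth, pennation = pennation,
                 tracking = tracking, outDir = outDir),
            class = "runConfig")
}

#' Write a run configuration as YAML
#' @param config a \code{\link{runConfig}}
#' @param path YAML path
#' @return invisibly, the path
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  lst <- unclass(config)
  lst$volumeChanges <- as.list(lst$volumeChanges)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path
#' @return a \code{\link{runConfig}}
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  vc <- unlist(lst$volumeChanges)
  runConfig(stages = lst$stages, seed = lst$seed,
            volumeChanges = if (is.null(vc)) numeric(0) else vc,
            fasciaScale = lst$fasciaScale, binWidth = lst$binWidth,
            pennation = lst$pennation, tracking = lst$tracking %||% list(),
            outDir = lst$outDir)
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run a pre-vs-post comparison on a synthetic phantom pair
#'
#' Orchestrates the enabled stages on a \code{\link{makePrePostPair}} dataset
#' generated from the configuration: volumetry (per-label volumes and percent
#' changes), fascia (thickness maps and distribution shift) and, when a
#' pennate input is configured, the DTI architecture stage on matched
#' unipennate phantoms. All randomness derives from the configured seed, so a
#' rerun with the same configuration reproduces the report.
#'
#' @param config a \code{\link{runConfig}} (or a YAML path)
#' @return a \linkS4class{ComparisonReport}
#' @export
runComparison <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "runConfig"))
  seed <- config$seed

  pair <- stageTry("simulate", makePrePostPair(
    list(volumeChanges = config$volumeChanges,
         fasciaScale = config$fasciaScale), seed = seed))

  volumes <- if ("volumetry" %in% config$stages) {
    stageTry("volumetry", volumeReport(pair$pre$limb, pair$post$limb))
  } else new("VolumeReport", labels = data.frame(),
             compartments = data.frame())

  fascia <- NULL
  if ("fascia" %in% config$stages) {
    fascia <- stageTry("fascia", {
      preMap <- thicknessMap(pair$pre$fascia)
      postMap <- thicknessMap(pair$post$fascia)
      compareThickness(preMap, postMap, config$binWidth)
    })
  }

  architecture <- list()
  if ("dti" %in% config$stages) {
    if (is.null(config$pennation))
      stop("stage 'dti': no diffusion input configured (pennation is NULL)",
           call. = FALSE)
    architecture <- stageTry("dti", {
      pn <- config$pennation
      params <- do.call(trackingParams, config$tracking)
      onePhantom <- function(angle, stageSeed) {
        ph <- do.call(makePennatePhantom, c(list(pennationAngleDeg = angle),
          pn[names(pn) %in% c("boxDims", "eigenvalues", "spacing")]))
        dwi <- simulateDWI(ph$tensors, noiseSigma = pn$noiseSigma %||% 0,
                           seed = stageSeed)
        muscleArchitecture(dwi, ph$mask, params = params, seed = stageSeed)
      }
      pre <- onePhantom(pn$angleDeg, seed + 1L)
      post <- onePhantom(pn$postAngleDeg %||% pn$angleDeg, seed + 2L)
      list(muscle = list(
        pre = pre$report, post = post$report,
        deltas = list(
          pennationDeg = post$report@meanPennationDeg -
            pre$report@meanPennationDeg,
          fascicleLengthPct = percentChange(pre$report@meanFascicleLengthCm,
                                            post$report@meanFascicleLengthCm),
          pcsaPct = percentChange(pre$report@pcsaCm2, post$report@pcsaCm2))))
    })
  }

  report <- new("ComparisonReport", volumes = volumes, fascia = fascia,
                architecture = architecture,
                provenance = list(seed = seed,
                                  config = unclass(config),
                                  package = as.character(
                                    utils::packageVersion("limbarch"))))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeVolumeReport(volumes, file.path(config$outDir, "volumes.tsv"),
                      file.path(config$outDir, "volumes.json"))
    if (!is.null(fascia))
      jsonlite::write_json(
        list(meanShiftPct = fascia@meanShiftPct,
             medianShiftPct = fascia@medianShiftPct),
        file.path(config$outDir, "fascia_shift.json"), auto_unbox = TRUE)
  }
  report
}
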