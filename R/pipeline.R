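#' @include AllClasses.R utils.R registration.R segmentation.R strain.R
NULL

defaultParams <- function() {
  list(
    registration = list(ccWindowPx = 9, stepSizePx = 1.0,
                        nIterationsPerLevel = 30, nPyramidLevels = 3,
                        updateSigmaPx = 1.5, smoothingSigmaPx = 0.75,
                        convergenceTol = 0.01, invertIterations = 5),
    segmentation = list(nAngles = 96, nRadii = 64, smoothness = 1,
                        endoBand = c(0.3, 1.3), epiBandMax = 2,
                        epiMarginPx = 2, seedStride = 1),
    volumetrics = list(),
    strain = list(meanFirst = TRUE)
  )
}

#' Build a pipeline configuration
#'
#' Merges the given parameter blocks over the defaults and computes a
#' canonical hash (stable under key reordering; changes iff a value
#' changes).
#'
#' @param ... named blocks (`registration`, `segmentation`,
#'   `volumetrics`, `strain`) of parameter overrides.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  params <- utils::modifyList(defaultParams(), over)
  new("PipelineConfig", params = params, configHash = canonicalHash(params))
}

#' Read a pipeline configuration from a YAML file
#'
#' One block per pipeline stage, same structure as [pipelineConfig()].
#'
#' @param path YAML file.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

regParamsFromConfig <- function(config) {
  do.call(registrationParams, config@params$registration)
}

#' Run the full analysis pipeline on a cine study
#'
#' Stages in order: blood-pool localization, mitral-valve anchor
#' detection and base-plane fit, per-slice inverse-consistent
#' registration, contour segmentation, Simpson volumetry with base-plane
#' clipping, and mid-wall circumferential strain on the mid-ventricular
#' slice. The pipeline contains no randomness: identical input and
#' configuration yield bit-identical reports. An `AlgorithmFailure` in
#' any stage produces a report with `status = "failed"` naming the stage.
#'
#' @param series a [CineSeries-class].
#' @param config a [PipelineConfig-class].
#' @return a [ResultReport-class] with attribute `stageLog`
#'   (stage/seconds/status data.frame).
#' @export
runPipeline <- function(series, config = pipelineConfig()) {
  log <- data.frame(stage = character(0), seconds = numeric(0),
                    status = character(0))
  failedReport <- function(stage) {
    rep <- new("ResultReport", edvMl = NA_real_, esvMl = NA_real_,
               efPercent = NA_real_, edPhase = NA_real_,
               esPhase = NA_real_, volumeCurve = numeric(0),
               strainCurve = numeric(0), peakStrainPercent = NA_real_,
               peakPhase = NA_real_, midSliceIndex = NA_real_,
               contours = NULL,
               provenance = list(configHash = config@configHash,
                                 version = as.character(
                                   utils::packageVersion("cinestrain"))),
               status = "failed", failedStage = stage)
    attr(rep, "stageLog") <- log
    rep
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(expr, warning = function(w)
      invokeRestart("muffleWarning"))
    log <<- rbind(log, data.frame(stage = name,
                                  seconds = proc.time()[["elapsed"]] - t0,
                                  status = "ok"))
    val
  }
  res <- tryCatch({
    loc <- stage("localization", detectLVBloodPool(series))
    plane <- stage("base_plane", {
      mv <- detectMitralValvePoints(series)
      normal <- sliceNormal(series@shortAxis[[1]]@geometry)
      proj <- vapply(series@shortAxis, function(s)
        sum(s@geometry@origin * normal), numeric(1))
      if (proj[length(proj)] < proj[1]) normal <- -normal
      apexToBase <- if (series@sliceOrder == "apex_to_base") normal else
        -normal
      fitBasePlane(mv, apexToBase = apexToBase)
    })
    regP <- regParamsFromConfig(config)
    fieldsBySlice <- stage("registration", {
      lapply(seq_along(series@shortAxis), function(s) {
        if (loc@table$confidence[s] > 0)
          registerSliceSeries(series@shortAxis[[s]], regP)
        else NULL
      })
    })
    contours <- stage("segmentation",
                      segmentStudy(series, loc, fieldsBySlice, regP,
                                   config@params$segmentation))
    vcurve <- stage("volumetrics",
                    computeVolumeCurve(contours, plane, series))
    scurve <- stage("strain", {
      midIdx <- selectMidSlice(contours, series@sliceOrder)
      key <- paste0("s", midIdx)
      pos <- which(vapply(series@shortAxis, function(s)
        s@geometry@sliceIndex, numeric(1)) == midIdx)
      midwallStrainCurve(contours@contours[[key]], fieldsBySlice[[pos]],
                         spacing = series@shortAxis[[pos]]@geometry@pixelSpacing,
                         sliceIndex = midIdx,
                         meanFirst = isTRUE(config@params$strain$meanFirst))
    })
    rep <- new("ResultReport",
               edvMl = vcurve@edvMl, esvMl = vcurve@esvMl,
               efPercent = vcurve@efPercent, edPhase = vcurve@edPhase,
               esPhase = vcurve@esPhase, volumeCurve = vcurve@volumeMl,
               strainCurve = scurve@strainPercent,
               peakStrainPercent = scurve@peakPercent,
               peakPhase = scurve@peakPhase,
               midSliceIndex = scurve@sliceIndex, contours = contours,
               provenance = list(configHash = config@configHash,
                                 version = as.character(
                                   utils::packageVersion("cinestrain"))),
               status = "ok", failedStage = "")
    attr(rep, "stageLog") <- log
    rep
  }, AlgorithmFailure = function(e) {
    log <<- rbind(log, data.frame(stage = e$stage, seconds = NA_real_,
                                  status = "failed"))
    failedReport(e$stage)
  })
  res
}

#' Reproducibility harness: repeated pipeline runs over a series list
#'
#' Runs the pipeline `nRuns` times per series; `identicalFraction` is the
#' percentage of (non-failed) series whose peak strain is bit-identical
#' across all runs, and `pearsonR` the correlation between run-1 and
#' run-2 peak strains across series.
#'
#' @param seriesList list of [CineSeries-class].
#' @param config a [PipelineConfig-class].
#' @param nRuns number of independent runs (>= 2).
#' @param runner function(series, config) -> [ResultReport-class]; the
#'   pipeline by default (replaceable by a test double).
#' @return list: `identicalFraction` (%), `pearsonR`, `nFailed`,
#'   `peaks` (series x run matrix).
#' @export
reproducibilityCheck <- function(seriesList, config = pipelineConfig(),
                                 nRuns = 2, runner = runPipeline) {
  stopifnot(nRuns >= 2)
  peaks <- matrix(NA_real_, length(seriesList), nRuns)
  failed <- logical(length(seriesList))
  for (i in seq_along(seriesList)) {
    for (r in seq_len(nRuns)) {
      rep <- runner(seriesList[[i]], config)
      if (rep@status != "ok") { failed[i] <- TRUE; break }
      peaks[i, r] <- rep@peakStrainPercent
    }
  }
  ok <- !failed
  ident <- apply(peaks[ok, , drop = FALSE], 1, function(x)
    all(x == x[1]))
  pr <- if (sum(ok) >= 3 && stats::sd(peaks[ok, 1]) > 0 &&
            stats::sd(peaks[ok, 2]) > 0)
    pearson(peaks[ok, 1], peaks[ok, 2]) else NA_real_
  list(identicalFraction = 100 * mean(ident), pearsonR = pr,
       nFailed = sum(failed), peaks = peaks)
}
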