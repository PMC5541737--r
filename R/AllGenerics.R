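#' @include AllClasses.R
NULL

#' Number of cardiac phases
#'
#' @param x a [CineSlice-class] or [CineSeries-class].
#' @return integer phase count.
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname nPhases
setMethod("nPhases", "CineSlice", function(x) dim(x@frames)[3])

#' @rdname nPhases
setMethod("nPhases", "CineSeries", function(x) dim(x@shortAxis[[1]]@frames)[3])

#' Number of short-axis slices
#'
#' @param x a [CineSeries-class].
#' @return integer slice count.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname nSlices
setMethod("nSlices", "CineSeries", function(x) length(x@shortAxis))

#' Frames of a cine slice
#'
#' @param x a [CineSlice-class].
#' @return numeric array rows x cols x phases.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
setMethod("frames", "CineSlice", function(x) x@frames)

#' Geometry of a cine slice
#'
#' @param x a [CineSlice-class].
#' @return the [SliceGeometry-class].
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname geometry
setMethod("geometry", "CineSlice", function(x) x@geometry)

#' Short-axis slices of a study
#'
#' @param x a [CineSeries-class].
#' @return list of [CineSlice-class].
#' @export
setGeneric("shortAxis", function(x) standardGeneric("shortAxis"))

#' @rdname shortAxis
setMethod("shortAxis", "CineSeries", function(x) x@shortAxis)

#' Long-axis view of a study
#'
#' @param x a [CineSeries-class].
#' @param view `"2ch"` or `"4ch"`.
#' @return a [CineSlice-class].
#' @export
setGeneric("longAxis", function(x, view = c("2ch", "4ch"))
  standardGeneric("longAxis"))

#' @rdname longAxis
setMethod("longAxis", "CineSeries", function(x, view = c("2ch", "4ch")) {
  view <- match.arg(view)
  if (view == "2ch") x@longAxis2ch else x@longAxis4ch
})

#' Ejection fraction of a volume curve or report
#'
#' @param x a [VolumeCurve-class] or [ResultReport-class].
#' @return EF in percent.
#' @export
setGeneric("ejectionFraction", function(x) standardGeneric("ejectionFraction"))

#' @rdname ejectionFraction
setMethod("ejectionFraction", "VolumeCurve", function(x) x@efPercent)

#' @rdname ejectionFraction
setMethod("ejectionFraction", "ResultReport", function(x) x@efPercent)

#' Peak (most negative) circumferential strain
#'
#' @param x a [StrainCurve-class] or [ResultReport-class].
#' @return peak strain in percent.
#' @export
setGeneric("peakStrain", function(x) standardGeneric("peakStrain"))

#' @rdname peakStrain
setMethod("peakStrain", "StrainCurve", function(x) x@peakPercent)

#' @rdname peakStrain
setMethod("peakStrain", "ResultReport", function(x) x@peakStrainPercent)

setMethod("show", "CineSeries", function(object) {
  cat("CineSeries", sQuote(object@id), "\n")
  d <- dim(object@shortAxis[[1]]@frames)
  cat(" ", length(object@shortAxis), "short-axis slices (",
      object@sliceOrder, "), ", d[1], "x", d[2], " px, ",
      d[3], " phases\n", sep = "")
  cat("  long-axis views: 2ch, 4ch\n")
})

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet:", length(object@acceptedSlices), "accepted slices x",
      object@nPhases, "phases (endo + epi)\n")
  cat("  accepted slice range:", min(object@acceptedSlices), "..",
      max(object@acceptedSlices), "; total cost",
      format(object@totalCost, digits = 6), "\n")
})

setMethod("show", "VolumeCurve", function(object) {
  cat("VolumeCurve:", length(object@volumeMl), "phases\n")
  cat(sprintf("  EDV %.2f ml (phase %d), ESV %.2f ml (phase %d), EF %.1f%%\n",
              object@edvMl, object@edPhase, object@esvMl, object@esPhase,
              object@efPercent))
})

setMethod("show", "StrainCurve", function(object) {
  cat("StrainCurve (mid-wall circumferential):",
      length(object@strainPercent), "phases\n")
  cat(sprintf("  peak %.2f%% at phase %d (slice %d)\n",
              object@peakPercent, object@peakPhase, object@sliceIndex))
})

setMethod("show", "ResultReport", function(object) {
  cat("ResultReport [", object@status, "]\n", sep = "")
  if (object@status == "ok") {
    cat(sprintf("  EDV %.2f ml, ESV %.2f ml, EF %.1f%%\n",
                object@edvMl, object@esvMl, object@efPercent))
    cat(sprintf("  peak mid-wall strain %.2f%% at phase %d (slice %d)\n",
                object@peakStrainPercent, object@peakPhase,
                object@midSliceIndex))
  } else {
    cat("  failed at stage:", object@failedStage, "\n")
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@nSlices, "slices x", object@nPhases, "phases,",
      paste(object@imageShape, collapse = "x"), "px @",
      object@pixelSpacingMm, "mm\n")
  cat(sprintf("  endo %.1f mm, wall %.1f mm, contraction %.2f, descent %.1f mm, noise %.1f\n",
              object@endoRadiusEdMm, object@wallThicknessEdMm,
              object@peakContraction, object@valveDescentMm,
              object@noiseSigma))
})
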