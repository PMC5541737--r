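#' @include AllClasses.R utils.R
NULL

sidecarFromGeometry <- function(geom, view, nPhases) {
  list(view = view,
       slice_index = geom@sliceIndex,
       origin = geom@origin,
       row_dir = geom@rowDir,
       col_dir = geom@colDir,
       pixel_spacing = geom@pixelSpacing,
       thickness = geom@thickness,
       gap = geom@gap,
       trigger_times = (seq_len(nPhases) - 1) / nPhases)
}

geometryFromSidecar <- function(sc) {
  new("SliceGeometry",
      origin = as.numeric(sc$origin), rowDir = as.numeric(sc$row_dir),
      colDir = as.numeric(sc$col_dir),
      pixelSpacing = as.numeric(sc$pixel_spacing),
      thickness = as.numeric(sc$thickness), gap = as.numeric(sc$gap),
      sliceIndex = as.numeric(sc$slice_index %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cine study as NIfTI volumes plus JSON geometry sidecars
#'
#' One `<name>.nii.gz` (rows x cols x phases) and one `<name>.json`
#' sidecar per short-axis slice and long-axis view.
#'
#' @param series a [CineSeries-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveCineSeries <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeOne <- function(slice, name, view) {
    RNifti::writeNifti(slice@frames, file.path(dir, paste0(name, ".nii.gz")))
    sc <- sidecarFromGeometry(slice@geometry, view, dim(slice@frames)[3])
    sc$image <- paste0(name, ".nii.gz")
    writeLines(as.character(jsonlite::toJSON(sc, auto_unbox = TRUE,
                                             digits = NA)),
               file.path(dir, paste0(name, ".json")))
  }
  for (i in seq_along(series@shortAxis))
    writeOne(series@shortAxis[[i]], sprintf("sax_%02d", i - 1), "sax")
  writeOne(series@longAxis2ch, "la_2ch", "2ch")
  writeOne(series@longAxis4ch, "la_4ch", "4ch")
  meta <- list(id = series@id, slice_order = series@sliceOrder)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)),
             file.path(dir, "study.json"))
  invisible(dir)
}

# nearest-neighbor resampling in normalized cyclic cardiac time
resamplePhases <- function(frames, nTarget) {
  nIn <- dim(frames)[3]
  if (nIn == nTarget) return(frames)
  u <- (seq_len(nTarget) - 1) / nTarget
  idx <- (floor(u * nIn + 0.5) %% nIn) + 1
  frames[, , idx, drop = FALSE]
}

#' Load a cine study from disk
#'
#' Reads a study directory of NIfTI volumes with JSON geometry sidecars
#' (as written by [saveCineSeries()]). Short-axis slices are sorted along
#' the slice-normal axis and all slices are resampled by nearest neighbor
#' in normalized cardiac time to the maximum phase count across slices.
#'
#' @param path study directory.
#' @param formatHint `"auto"`, `"nifti+json"`, or `"dicom"` (DICOM input
#'   is not supported by this build and raises an error).
#' @return a [CineSeries-class].
#' @export
loadCineSeries <- function(path, formatHint = c("auto", "nifti+json",
                                                "dicom")) {
  formatHint <- match.arg(formatHint)
  if (formatHint == "dicom")
    stop("unsupported format: dicom (provide nifti+json)")
  if (!dir.exists(path)) stop("study path does not exist: ", path)
  sidecars <- setdiff(list.files(path, pattern = "\\.json$",
                                 full.names = TRUE),
                      file.path(path, "study.json"))
  # keep only geometry sidecars (other JSON, e.g. phantom truth, is not)
  sidecars <- Filter(function(f) {
    sc <- tryCatch(jsonlite::fromJSON(f), error = function(e) NULL)
    !is.null(sc$origin) && !is.null(sc$row_dir)
  }, sidecars)
  if (!length(sidecars)) stop("no geometry sidecars found in ", path)
  entries <- lapply(sidecars, function(f) {
    sc <- jsonlite::fromJSON(f)
    img <- file.path(path, sc$image %||% sub("\\.json$", ".nii.gz",
                                             basename(f)))
    fr <- as.array(RNifti::readNifti(img))
    fr <- array(as.numeric(fr), dim(fr))  # strip the niftiImage class
    if (length(dim(fr)) == 2L) fr <- array(fr, c(dim(fr), 1))
    if (length(dim(fr)) != 3L)
      stop("inconsistent in-plane shapes within a slice: ", img)
    list(sc = sc, frames = fr)
  })
  views <- vapply(entries, function(e) e$sc$view %||% "sax", character(1))
  for (v in c("2ch", "4ch"))
    if (!any(views == v)) stop("missing long-axis view: ", v)
  saxE <- entries[views == "sax"]
  if (length(saxE) < 3L) stop("need at least 3 short-axis slices")
  shapes <- vapply(saxE, function(e) paste(dim(e$frames)[1:2],
                                           collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    stop("inconsistent in-plane shapes across the short-axis stack")
  npAll <- vapply(entries, function(e) dim(e$frames)[3], numeric(1))
  npTarget <- max(npAll[views == "sax"])
  mk <- function(e, np = NULL) {
    fr <- if (is.null(np)) e$frames else resamplePhases(e$frames, np)
    new("CineSlice", frames = fr, geometry = geometryFromSidecar(e$sc))
  }
  sax <- lapply(saxE, mk, np = npTarget)
  # sort along the stack normal
  normal <- sliceNormal(sax[[1]]@geometry)
  proj <- vapply(sax, function(s) sum(s@geometry@origin * normal),
                 numeric(1))
  sax <- sax[order(proj)]
  meta <- if (file.exists(file.path(path, "study.json")))
    jsonlite::fromJSON(file.path(path, "study.json")) else list()
  new("CineSeries", shortAxis = sax,
      longAxis2ch = mk(entries[[which(views == "2ch")[1]]]),
      longAxis4ch = mk(entries[[which(views == "4ch")[1]]]),
      id = meta$id %||% basename(path),
      sliceOrder = meta$slice_order %||% "apex_to_base")
}

reportToList <- function(report) {
  list(edv_ml = report@edvMl, esv_ml = report@esvMl,
       ef_percent = report@efPercent, ed_phase = report@edPhase,
       es_phase = report@esPhase,
       peak_strain_percent = report@peakStrainPercent,
       peak_phase = report@peakPhase,
       mid_slice_index = report@midSliceIndex,
       volume_curve_ml = report@volumeCurve,
       strain_curve_percent = report@strainCurve,
       provenance = report@provenance,
       status = report@status, failed_stage = report@failedStage)
}

#' Write an analysis report
#'
#' Writes `results.json` plus a per-phase `curves.csv` (phase, volume_ml,
#' strain_percent) into `path`. Serialization is canonical: the same
#' report always produces byte-identical files.
#'
#' @param report a [ResultReport-class].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  js <- jsonlite::toJSON(reportToList(report), auto_unbox = TRUE,
                         digits = NA, null = "null")
  writeLines(as.character(js), file.path(path, "results.json"))
  n <- length(report@volumeCurve)
  curves <- data.frame(phase = seq_len(n) - 1,
                       volume_ml = report@volumeCurve,
                       strain_percent = report@strainCurve)
  utils::write.csv(curves, file.path(path, "curves.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analysis report written by [writeReport()]
#'
#' @param path directory containing `results.json`.
#' @return a [ResultReport-class] (contours are not round-tripped).
#' @export
readReport <- function(path) {
  x <- jsonlite::fromJSON(file.path(path, "results.json"))
  new("ResultReport",
      edvMl = x$edv_ml, esvMl = x$esv_ml, efPercent = x$ef_percent,
      edPhase = x$ed_phase, esPhase = x$es_phase,
      volumeCurve = as.numeric(x$volume_curve_ml),
      strainCurve = as.numeric(x$strain_curve_percent),
      peakStrainPercent = x$peak_strain_percent, peakPhase = x$peak_phase,
      midSliceIndex = x$mid_slice_index, contours = NULL,
      provenance = as.list(x$provenance), status = x$status,
      failedStage = x$failed_stage %||% "")
}
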