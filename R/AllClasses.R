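#' @import methods
NULL

#' Per-slice acquisition geometry
#'
#' Describes how a 2D short-axis or long-axis image grid maps into the
#' patient (world) coordinate frame, following the DICOM convention: the
#' world position of 0-based pixel index (row, col) is
#' `origin + row * pixelSpacing[1] * rowDir + col * pixelSpacing[2] * colDir`.
#'
#' @slot origin world position (mm) of pixel (0, 0).
#' @slot rowDir,colDir orthonormal in-plane direction vectors.
#' @slot pixelSpacing (row, col) spacing in mm.
#' @slot thickness slice thickness in mm.
#' @slot gap inter-slice gap in mm.
#' @slot sliceIndex position of the slice in its stack (0-based).
#' @export
setClass("SliceGeometry", representation(
  origin = "numeric", rowDir = "numeric", colDir = "numeric",
  pixelSpacing = "numeric", thickness = "numeric", gap = "numeric",
  sliceIndex = "numeric"
))

setValidity("SliceGeometry", function(object) {
  msg <- character()
  if (length(object@origin) != 3L) msg <- c(msg, "origin must be a 3-vector")
  if (length(object@rowDir) != 3L || length(object@colDir) != 3L)
    msg <- c(msg, "rowDir/colDir must be 3-vectors")
  if (abs(sum(object@rowDir * object@colDir)) > 1e-6)
    msg <- c(msg, "rowDir and colDir must be orthogonal (within 1e-6)")
  if (abs(sqrt(sum(object@rowDir^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(object@colDir^2)) - 1) > 1e-6)
    msg <- c(msg, "rowDir and colDir must be unit vectors")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values")
  if (object@thickness <= 0) msg <- c(msg, "thickness must be positive")
  if (object@gap < 0) msg <- c(msg, "gap must be non-negative")
  if (length(msg)) msg else TRUE
})

#' One cine slice: a 2D+time image series with geometry
#'
#' @slot frames numeric array (rows x cols x phases), finite, non-negative.
#' @slot geometry a [SliceGeometry-class].
#' @export
setClass("CineSlice", representation(
  frames = "array", geometry = "SliceGeometry"
))

setValidity("CineSlice", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be rows x cols x phases")
  else if (d[3] < 2L) msg <- c(msg, "a cine slice needs at least 2 phases")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "intensities must be finite")
  else if (any(object@frames < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A full cine CMR study: short-axis stack plus two long-axis views
#'
#' @slot shortAxis list of [CineSlice-class], ordered along the LV long
#'   axis as recorded in `sliceOrder`.
#' @slot longAxis2ch,longAxis4ch the 2-chamber and 4-chamber views.
#' @slot id study identifier.
#' @slot sliceOrder `"apex_to_base"` or `"base_to_apex"`.
#' @export
setClass("CineSeries", representation(
  shortAxis = "list", longAxis2ch = "CineSlice", longAxis4ch = "CineSlice",
  id = "character", sliceOrder = "character"
))

setValidity("CineSeries", function(object) {
  msg <- character()
  if (length(object@shortAxis) < 3L)
    msg <- c(msg, "at least 3 short-axis slices are required")
  np <- vapply(object@shortAxis, function(s) dim(s@frames)[3], numeric(1))
  if (length(unique(np)) > 1L)
    msg <- c(msg, "all short-axis slices must share n_phases")
  if (!object@sliceOrder %in% c("apex_to_base", "base_to_apex"))
    msg <- c(msg, "sliceOrder must be apex_to_base or base_to_apex")
  if (length(msg)) msg else TRUE
})

#' Dense 2D displacement field between two cardiac phases
#'
#' Displacements are in pixels; `forwardRow/forwardCol` map reference-frame
#' coordinates to target-frame coordinates (x -> x + u(x)), and
#' `inverseRow/inverseCol` map back. The pair is kept inverse-consistent by
#' the registration engine.
#'
#' @slot forwardRow,forwardCol,inverseRow,inverseCol displacement matrices.
#' @slot flagged TRUE when the registration degenerated (e.g. constant
#'   images) and a zero field was returned.
#' @export
setClass("DeformationField", representation(
  forwardRow = "matrix", forwardCol = "matrix",
  inverseRow = "matrix", inverseCol = "matrix", flagged = "logical"
))

setValidity("DeformationField", function(object) {
  msg <- character()
  dims <- list(dim(object@forwardRow), dim(object@forwardCol),
               dim(object@inverseRow), dim(object@inverseCol))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    msg <- c(msg, "all four component matrices must share a shape")
  if (!all(is.finite(object@forwardRow)) || !all(is.finite(object@forwardCol)) ||
      !all(is.finite(object@inverseRow)) || !all(is.finite(object@inverseCol)))
    msg <- c(msg, "displacements must be finite")
  if (length(msg)) msg else TRUE
})

#' Parameters of the local cross-correlation registration
#'
#' @slot ccWindowPx odd window width (px) of the local correlation.
#' @slot stepSizePx maximum displacement update per iteration (px).
#' @slot nIterationsPerLevel gradient-descent iterations per pyramid level.
#' @slot nPyramidLevels multi-resolution levels (coarse to fine).
#' @slot updateSigmaPx Gaussian sigma (px) smoothing each update (fluid-like).
#' @slot smoothingSigmaPx Gaussian sigma (px) smoothing the total field
#'   (diffusion-like regularization).
#' @slot convergenceTol mean update magnitude (px) below which a level stops.
#' @slot invertIterations fixed-point iterations of the inverse update.
#' @export
setClass("RegistrationParams", representation(
  ccWindowPx = "numeric", stepSizePx = "numeric",
  nIterationsPerLevel = "numeric", nPyramidLevels = "numeric",
  updateSigmaPx = "numeric", smoothingSigmaPx = "numeric",
  convergenceTol = "numeric", invertIterations = "numeric"
), prototype(
  ccWindowPx = 9, stepSizePx = 1.0, nIterationsPerLevel = 30,
  nPyramidLevels = 3, updateSigmaPx = 1.5, smoothingSigmaPx = 0.75,
  convergenceTol = 0.01, invertIterations = 5
))

setValidity("RegistrationParams", function(object) {
  msg <- character()
  if (object@ccWindowPx < 3 || object@ccWindowPx %% 2 != 1)
    msg <- c(msg, "ccWindowPx must be an odd integer >= 3")
  vals <- c(object@stepSizePx, object@nIterationsPerLevel,
            object@nPyramidLevels, object@smoothingSigmaPx,
            object@convergenceTol, object@invertIterations)
  if (any(vals <= 0)) msg <- c(msg, "all parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Result of LV blood-pool localization across the short-axis stack
#'
#' @slot table data.frame with one row per short-axis slice: `slice`
#'   (0-based index), `centerRow`, `centerCol` (px), `radiusPx`,
#'   `confidence` in \[0, 1\].
#' @slot masks list of reference-phase blood-pool masks (logical matrices).
#' @export
setClass("LVLocalization", representation(
  table = "data.frame", masks = "list"
))

#' Time-resolved mitral-valve base plane
#'
#' Each phase's plane is the least-squares fit to the four valve anchor
#' points (two per long-axis view); the unit normal is oriented toward the
#' apex and the plane is the set of world points x with dot(normal, x) =
#' offset.
#'
#' @slot normals n_phases x 3 matrix of unit normals.
#' @slot offsets per-phase plane offsets (mm).
#' @slot anchors 4 x 3 x n_phases array of anchor points (world mm).
#' @slot flagged per-phase flag: anchors replaced by interpolation.
#' @export
setClass("BasePlane", representation(
  normals = "matrix", offsets = "numeric", anchors = "array",
  flagged = "logical"
))

setValidity("BasePlane", function(object) {
  msg <- character()
  n <- length(object@offsets)
  if (nrow(object@normals) != n || dim(object@anchors)[3] != n)
    msg <- c(msg, "normals, offsets and anchors must share n_phases")
  if (dim(object@anchors)[1] != 4L)
    msg <- c(msg, "exactly 4 anchors per phase are required")
  nn <- sqrt(rowSums(object@normals^2))
  if (any(abs(nn - 1) > 1e-6)) msg <- c(msg, "normals must be unit length")
  if (length(msg)) msg else TRUE
})

#' Gray-level models of the LV regions
#'
#' Intensity mean and spread of the blood pool, myocardium, background
#' (air/lungs) and the blood-myocardium partial-volume class, estimated
#' from histograms of localized regions; drives the edge-possibility map.
#'
#' @slot means,sds named numeric vectors (blood, myo, bg, pv).
#' @export
setClass("RegionModels", representation(
  means = "numeric", sds = "numeric"
))

setValidity("RegionModels", function(object) {
  need <- c("blood", "myo", "bg", "pv")
  if (!all(need %in% names(object@means)) ||
      !all(need %in% names(object@sds)))
    return("means and sds must be named blood, myo, bg, pv")
  if (any(object@sds <= 0)) return("sds must be positive")
  TRUE
})

#' Polar-resampled cost image for contour extraction
#'
#' @slot cost n_angles x n_radii matrix of node costs in \[eps, 1\] (low on
#'   edges); rows are angles on a uniform grid over \[0, 2*pi).
#' @slot center (row, col) pixel coordinates of the polar origin.
#' @slot radii radius (px) of each radial bin.
#' @export
setClass("PolarImage", representation(
  cost = "matrix", center = "numeric", radii = "numeric"
))

setValidity("PolarImage", function(object) {
  msg <- character()
  if (nrow(object@cost) < 32L) msg <- c(msg, "need at least 32 angles")
  if (ncol(object@cost) != length(object@radii))
    msg <- c(msg, "radii must match cost columns")
  if (!all(is.finite(object@cost)) || any(object@cost < 0))
    msg <- c(msg, "costs must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' A closed contour sampled on a polar angular grid
#'
#' @slot radiusPx radius (px) at each angle of the uniform grid
#'   `2*pi*(0:(n-1))/n`; the curve closes between the last and first sample.
#' @slot center (row, col) pixel center.
#' @slot cost sum of traversed polar node costs.
#' @slot kind `"endo"` or `"epi"`.
#' @slot phase cardiac phase index (0-based).
#' @export
setClass("Contour", representation(
  radiusPx = "numeric", center = "numeric", cost = "numeric",
  kind = "character", phase = "numeric"
))

setValidity("Contour", function(object) {
  msg <- character()
  if (any(!is.finite(object@radiusPx)) || any(object@radiusPx <= 0))
    msg <- c(msg, "radii must be finite and positive")
  if (!object@kind %in% c("endo", "epi"))
    msg <- c(msg, "kind must be endo or epi")
  if (length(msg)) msg else TRUE
})

#' Endo- and epicardial contours for every accepted slice and phase
#'
#' @slot contours list indexed by slice (names `"s<index>"`), each a list
#'   over phases, each `list(endo = , epi = )` of [Contour-class].
#' @slot acceptedSlices 0-based indices of the contiguous accepted range.
#' @slot nPhases phases per slice.
#' @slot totalCost combined cost of the winning contour family.
#' @export
setClass("ContourSet", representation(
  contours = "list", acceptedSlices = "numeric", nPhases = "numeric",
  totalCost = "numeric"
))

#' Per-pixel Green-Lagrange strain tensor field
#'
#' Symmetric 2x2 tensor per pixel, computed from the displacement
#' gradient of a phase-0-anchored deformation field; axis x is the image
#' row direction, y the column direction.
#'
#' @slot Exx,Eyy,Exy component matrices (dimensionless).
#' @slot phase target phase index (reference is phase 0).
#' @export
setClass("StrainTensorField", representation(
  Exx = "matrix", Eyy = "matrix", Exy = "matrix", phase = "numeric"
))

setValidity("StrainTensorField", function(object) {
  if (!all(is.finite(object@Exx)) || !all(is.finite(object@Eyy)) ||
      !all(is.finite(object@Exy)))
    return("tensor components must be finite")
  TRUE
})

#' Radial/circumferential strain about a center
#'
#' Quadratic forms of the strain tensor along the local radial and
#' tangential unit vectors; undefined (NA) within 1 px of the center.
#'
#' @slot Ecc,Err component matrices.
#' @slot center (row, col) pixel center.
#' @export
setClass("PolarStrainField", representation(
  Ecc = "matrix", Err = "matrix", center = "numeric"
))

#' LV cavity volume over the cardiac cycle
#'
#' @slot volumeMl per-phase cavity volume (ml).
#' @slot edvMl,esvMl end-diastolic and end-systolic volumes (max/min).
#' @slot edPhase,esPhase 0-based phases of EDV and ESV.
#' @slot efPercent ejection fraction (EDV - ESV) / EDV * 100.
#' @export
setClass("VolumeCurve", representation(
  volumeMl = "numeric", edvMl = "numeric", esvMl = "numeric",
  edPhase = "numeric", esPhase = "numeric", efPercent = "numeric"
))

setValidity("VolumeCurve", function(object) {
  msg <- character()
  if (length(object@volumeMl) &&
      abs(object@edvMl - max(object@volumeMl)) > 1e-9)
    msg <- c(msg, "edvMl must equal max(volumeMl)")
  if (length(object@volumeMl) &&
      abs(object@esvMl - min(object@volumeMl)) > 1e-9)
    msg <- c(msg, "esvMl must equal min(volumeMl)")
  if (object@efPercent < 0 || object@efPercent >= 100)
    msg <- c(msg, "efPercent must lie in [0, 100)")
  if (length(msg)) msg else TRUE
})

#' Mean mid-wall circumferential strain over the cardiac cycle
#'
#' Values are engineering strain in percent (relative change of mid-wall
#' circumference against phase 0), derived from the Green-Lagrange tensor.
#'
#' @slot strainPercent per-phase strain (%); value at phase 0 is 0.
#' @slot peakPercent most negative value over the cycle.
#' @slot peakPhase 0-based phase of the peak.
#' @slot sliceIndex mid-ventricular slice the curve was measured on.
#' @export
setClass("StrainCurve", representation(
  strainPercent = "numeric", peakPercent = "numeric", peakPhase = "numeric",
  sliceIndex = "numeric"
))

setValidity("StrainCurve", function(object) {
  msg <- character()
  if (length(object@strainPercent) &&
      abs(object@strainPercent[1]) > 1e-9)
    msg <- c(msg, "Lagrangian strain must be 0 at the reference phase")
  if (length(msg)) msg else TRUE
})

#' Specification of the synthetic cine phantom
#'
#' Defaults emulate the acquisition the engine targets at desk scale: a
#' short-axis stack of 8 mm slices with 2 mm gap, about 2 mm in-plane
#' spacing, a bright circular blood pool inside a darker myocardial
#' annulus, raised-cosine contraction peaking at mid cycle, and long-axis
#' views whose basal (valve) edge descends during systole.
#'
#' @slot nSlices,nPhases stack size and frames per cycle.
#' @slot imageShape (rows, cols).
#' @slot pixelSpacingMm isotropic in-plane spacing (mm).
#' @slot thicknessMm,gapMm slice thickness and gap (mm).
#' @slot endoRadiusEdMm endocardial radius at end diastole (mm).
#' @slot wallThicknessEdMm myocardial wall thickness at end diastole (mm).
#' @slot peakContraction fractional mid-wall radius reduction at end
#'   systole, in (0, 0.5); 0 gives a static phantom.
#' @slot intensityBlood,intensityMyo,intensityBg region intensities
#'   (arbitrary units, blood > myo > bg).
#' @slot noiseSigma additive Gaussian noise sigma.
#' @slot valveDescentMm basal (valve) edge descent at end systole (mm).
#' @slot papillaries add dark papillary-muscle-like speckles in the pool.
#' @slot seed RNG seed for the noise.
#' @export
setClass("PhantomSpec", representation(
  nSlices = "numeric", nPhases = "numeric", imageShape = "numeric",
  pixelSpacingMm = "numeric", thicknessMm = "numeric", gapMm = "numeric",
  endoRadiusEdMm = "numeric", wallThicknessEdMm = "numeric",
  peakContraction = "numeric", intensityBlood = "numeric",
  intensityMyo = "numeric", intensityBg = "numeric", noiseSigma = "numeric",
  valveDescentMm = "numeric", papillaries = "logical", seed = "numeric"
), prototype(
  nSlices = 7, nPhases = 16, imageShape = c(96, 96), pixelSpacingMm = 2,
  thicknessMm = 8, gapMm = 2, endoRadiusEdMm = 22, wallThicknessEdMm = 10,
  peakContraction = 0.18, intensityBlood = 200, intensityMyo = 100,
  intensityBg = 20, noiseSigma = 3, valveDescentMm = 8,
  papillaries = FALSE, seed = 1
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!(object@intensityBlood > object@intensityMyo &&
        object@intensityMyo > object@intensityBg))
    msg <- c(msg, "intensities must satisfy blood > myo > bg")
  if (object@endoRadiusEdMm <= 0) msg <- c(msg, "endoRadiusEdMm must be > 0")
  if (object@wallThicknessEdMm <= 0)
    msg <- c(msg, "wallThicknessEdMm must be > 0")
  if (object@peakContraction < 0 || object@peakContraction >= 0.5)
    msg <- c(msg, "peakContraction must lie in [0, 0.5)")
  if (object@nSlices < 3) msg <- c(msg, "need at least 3 slices")
  if (object@nPhases < 2) msg <- c(msg, "need at least 2 phases")
  if (length(msg)) msg else TRUE
})

#' Analytic ground truth accompanying a generated phantom
#'
#' @slot midwallStrainTruth per-phase engineering mid-wall strain (%).
#' @slot volumeTruthMl per-phase cavity volume (ml), base-plane clipped.
#' @slot efTruthPercent analytic ejection fraction.
#' @slot lambda per-phase radial scale factor (1 at phase 0).
#' @slot basePlaneZ per-phase world z of the valve plane (mm).
#' @slot centerPx (row, col) of the LV center in short-axis images.
#' @slot endoRadiusPx,epiRadiusPx per-phase radii (px).
#' @slot anchors2ch,anchors4ch 2 x 3 x n_phases arrays of true valve
#'   anchor world coordinates.
#' @export
setClass("PhantomTruth", representation(
  midwallStrainTruth = "numeric", volumeTruthMl = "numeric",
  efTruthPercent = "numeric", lambda = "numeric", basePlaneZ = "numeric",
  centerPx = "numeric", endoRadiusPx = "numeric", epiRadiusPx = "numeric",
  anchors2ch = "array", anchors4ch = "array"
))

#' Machine-readable end-to-end analysis report
#'
#' @slot edvMl,esvMl,efPercent,edPhase,esPhase volumetric summaries.
#' @slot volumeCurve per-phase cavity volume (ml).
#' @slot strainCurve per-phase mid-wall circumferential strain (%).
#' @slot peakStrainPercent,peakPhase strain summaries.
#' @slot midSliceIndex slice the strain was measured on.
#' @slot contours the [ContourSet-class] behind the numbers.
#' @slot provenance list: configHash, package version.
#' @slot status `"ok"` or `"failed"`; `failedStage` names the stage.
#' @export
setClass("ResultReport", representation(
  edvMl = "numeric", esvMl = "numeric", efPercent = "numeric",
  edPhase = "numeric", esPhase = "numeric", volumeCurve = "numeric",
  strainCurve = "numeric", peakStrainPercent = "numeric",
  peakPhase = "numeric", midSliceIndex = "numeric", contours = "ANY",
  provenance = "list", status = "character", failedStage = "character"
))

#' Full pipeline configuration
#'
#' One parameter block per stage; the hash is a digest of the
#' canonicalized (key-sorted) parameter set, so it is stable under key
#' reordering and changes iff a value changes.
#'
#' @slot params nested named list of parameter blocks.
#' @slot configHash hex digest string.
#' @export
setClass("PipelineConfig", representation(
  params = "list", configHash = "character"
))

#' Error signalled when the automatic algorithm cannot proceed
#'
#' Mirrors the fallback path of the automated method: when the blood pool
#' cannot be found on enough slices or no admissible contour family
#' exists, an `AlgorithmFailure` condition is raised carrying the failing
#' stage.
#'
#' @param message description of the failure.
#' @param stage pipeline stage name.
#' @return a condition object (invisibly, via [stop()]).
#' @export
algorithmFailure <- function(message, stage = "unknown") {
  structure(
    class = c("AlgorithmFailure", "error", "condition"),
    list(message = message, call = sys.call(-1), stage = stage)
  )
}
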