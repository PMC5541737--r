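#' @include AllClasses.R utils.R
NULL

#' Area enclosed by a contour, in mm^2
#'
#' Shoelace (polygon) area of the Cartesian contour, scaled by the pixel
#' spacing. Polar single-valued closed paths cannot self-intersect.
#'
#' @param contour a [Contour-class].
#' @param geometry the slice's [SliceGeometry-class].
#' @return area in mm^2.
#' @export
contourArea <- function(contour, geometry) {
  xy <- contourToCartesian(contour)
  x <- xy$row * geometry@pixelSpacing[1]
  y <- xy$col * geometry@pixelSpacing[2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Cavity volume curve by Simpson stacking with base-plane clipping
#'
#' Per phase, the cavity volume is the sum over accepted slices of the
#' endocardial contour area times the slab spacing (thickness + gap),
#' each slice scaled by its in-slab fraction below the mitral-valve base
#' plane: `clamp(d / spacing + 0.5, 0, 1)`, where `d` is the signed
#' distance from the slice center to the plane (positive on the apical
#' side). EDV/ESV are the curve's max/min and EF their relative
#' difference.
#'
#' @param contours a [ContourSet-class].
#' @param plane a [BasePlane-class] with one plane per phase.
#' @param series the [CineSeries-class] the contours came from (provides
#'   the slice geometries).
#' @return a [VolumeCurve-class].
#' @export
computeVolumeCurve <- function(contours, plane, series) {
  n <- contours@nPhases
  if (length(plane@offsets) < n)
    stop("base plane missing for some phases")
  geoms <- lapply(series@shortAxis, geometry)
  byIndex <- stats::setNames(geoms, vapply(geoms, function(g)
    paste0("s", g@sliceIndex), character(1)))
  shape <- dim(series@shortAxis[[1]]@frames)[1:2]
  vol <- numeric(n)
  for (key in names(contours@contours)) {
    g <- byIndex[[key]]
    if (is.null(g)) stop("no geometry for contour slice ", key)
    spacing <- sliceSpacing(g)
    ctrW <- sliceCenterWorld(g, shape)
    fam <- contours@contours[[key]]
    for (t in seq_len(n)) {
      a <- contourArea(fam[[t]]$endo, g)
      d <- sum(plane@normals[t, ] * ctrW) - plane@offsets[t]
      frac <- clamp(d / spacing + 0.5, 0, 1)
      vol[t] <- vol[t] + a * spacing * frac / 1000
    }
  }
  ed <- which.max(vol)
  es <- which.min(vol)
  new("VolumeCurve", volumeMl = vol, edvMl = vol[ed], esvMl = vol[es],
      edPhase = ed - 1, esPhase = es - 1,
      efPercent = (vol[ed] - vol[es]) / vol[ed] * 100)
}

#' Ejection fraction from a volume curve
#'
#' @param curve a [VolumeCurve-class].
#' @return `(EDV - ESV) / EDV * 100`.
#' @export
computeEF <- function(curve) {
  if (curve@edvMl <= 0) stop("EDV must be positive")
  (curve@edvMl - curve@esvMl) / curve@edvMl * 100
}
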