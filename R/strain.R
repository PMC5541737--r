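#' @include AllClasses.R utils.R registration.R
NULL

# spacing-aware displacement gradient of a (ur, uc) field given in px
dispGradient <- function(ur, uc, spacing = c(1, 1)) {
  gr <- .cs_gradient(ur * spacing[1])
  gc <- .cs_gradient(uc * spacing[2])
  list(dxx = gr$dr / spacing[1], dxy = gr$dc / spacing[2],
       dyx = gc$dr / spacing[1], dyy = gc$dc / spacing[2])
}

#' Green-Lagrange strain tensor from a deformation field
#'
#' The displacement gradient is taken by central differences (one-sided
#' at the borders) in physical units, and the tensor is
#' `E = (G + G' + G'G) / 2` with `G` the displacement gradient — the
#' finite-deformation (Green-Lagrange) strain referenced to phase 0.
#'
#' @param field a [DeformationField-class] mapping phase 0 to phase t.
#' @param spacing (row, col) pixel spacing in mm.
#' @param phase phase index stored on the result.
#' @return a [StrainTensorField-class].
#' @export
lagrangianStrainField <- function(field, spacing = c(1, 1), phase = 0) {
  g <- dispGradient(field@forwardRow, field@forwardCol, spacing)
  Exx <- g$dxx + 0.5 * (g$dxx^2 + g$dyx^2)
  Eyy <- g$dyy + 0.5 * (g$dxy^2 + g$dyy^2)
  Exy <- 0.5 * (g$dxy + g$dyx) + 0.5 * (g$dxx * g$dxy + g$dyx * g$dyy)
  new("StrainTensorField", Exx = Exx, Eyy = Eyy, Exy = Exy, phase = phase)
}

#' Convert a strain tensor field to radial/circumferential components
#'
#' At each pixel with radial unit vector `r` and tangential unit vector
#' `t` about `center`, `Err = r'Er` and `Ecc = t'Et`; pixels within 1 px
#' of the center are masked NA.
#'
#' @param tensor a [StrainTensorField-class].
#' @param center (row, col) 0-based pixel center.
#' @return a [PolarStrainField-class].
#' @export
polarStrain <- function(tensor, center) {
  nr <- nrow(tensor@Exx); nc <- ncol(tensor@Exx)
  if (center[1] < 0 || center[1] > nr - 1 ||
      center[2] < 0 || center[2] > nc - 1)
    stop("center lies outside the image")
  dr <- matrix(seq_len(nr) - 1, nr, nc) - center[1]
  dc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) - center[2]
  rho <- sqrt(dr^2 + dc^2)
  rr <- dr / pmax(rho, 1e-12)
  rc <- dc / pmax(rho, 1e-12)
  Err <- rr^2 * tensor@Exx + 2 * rr * rc * tensor@Exy + rc^2 * tensor@Eyy
  # tangential unit vector (-rc, rr)
  Ecc <- rc^2 * tensor@Exx - 2 * rr * rc * tensor@Exy + rr^2 * tensor@Eyy
  Err[rho < 1] <- NA_real_
  Ecc[rho < 1] <- NA_real_
  new("PolarStrainField", Ecc = Ecc, Err = Err, center = center)
}

#' Mid-ventricular slice of a contoured study
#'
#' The middle index of the contiguous accepted range; an even count is
#' broken toward the base.
#'
#' @param contours a [ContourSet-class].
#' @param sliceOrder `"apex_to_base"` (base at the higher index) or
#'   `"base_to_apex"`.
#' @return the 0-based slice index.
#' @export
selectMidSlice <- function(contours, sliceOrder = "apex_to_base") {
  acc <- range(contours@acceptedSlices)
  mid <- (acc[1] + acc[2]) / 2
  if (sliceOrder == "apex_to_base") ceiling(mid) else floor(mid)
}

#' Mean mid-wall circumferential strain curve
#'
#' The mid-wall centerline is fixed at phase 0 as
#' `r_mid(theta) = (r_endo(theta) + r_epi(theta)) / 2` on the polar
#' angular grid; these material points stay the Lagrangian reference. Per
#' phase, the mean circumferential Green-Lagrange strain over the
#' centerline pixels is converted to the reported engineering convention
#' `strain% = (sqrt(1 + 2 Ecc) - 1) * 100` (the relative circumference
#' change of the mid-wall ring).
#'
#' @param family per-phase contour list for the mid slice (from
#'   [segmentSlice()]).
#' @param fields per-phase [DeformationField-class] list for that slice.
#' @param spacing (row, col) pixel spacing in mm.
#' @param sliceIndex 0-based slice index stored on the curve.
#' @param meanFirst convert the mean Ecc (default) rather than averaging
#'   converted per-pixel strains; the difference is second order.
#' @return a [StrainCurve-class].
#' @export
midwallStrainCurve <- function(family, fields, spacing = c(1, 1),
                               sliceIndex = 0, meanFirst = TRUE) {
  n <- length(family)
  stopifnot(length(fields) == n)
  endo0 <- family[[1]]$endo
  epi0 <- family[[1]]$epi
  center <- endo0@center
  th <- polarAngles(length(endo0@radiusPx))
  rMid <- (endo0@radiusPx + epi0@radiusPx) / 2
  rows <- center[1] + rMid * sin(th)
  cols <- center[2] + rMid * cos(th)
  strain <- numeric(n)
  for (t in seq_len(n)) {
    tens <- lagrangianStrainField(fields[[t]], spacing, phase = t - 1)
    pol <- polarStrain(tens, center)
    ecc <- .cs_sample_bilinear(ifelse(is.na(pol@Ecc), NaN, pol@Ecc),
                               rows, cols)
    keep <- is.finite(ecc)
    if (mean(keep) < 0.8)
      stop("more than 20% of centerline samples fall outside the valid ",
           "strain region")
    if (meanFirst) {
      m <- mean(ecc[keep])
      strain[t] <- (sqrt(pmax(1 + 2 * m, 0)) - 1) * 100
    } else {
      strain[t] <- mean((sqrt(pmax(1 + 2 * ecc[keep], 0)) - 1) * 100)
    }
  }
  strain[1] <- 0  # exact Lagrangian reference
  pk <- which.min(strain)
  new("StrainCurve", strainPercent = strain, peakPercent = strain[pk],
      peakPhase = pk - 1, sliceIndex = sliceIndex)
}

#' Eulerian circumferential strain curve (comparison utility)
#'
#' Accumulates incremental circumferential strains: for each consecutive
#' phase pair the incremental displacement field is derived from the
#' phase-0-anchored family, its small-strain tensor is evaluated on the
#' tracked centerline points, and the mean increments are summed. Nearly
#' equal to the Lagrangian curve for small deformations, diverging for
#' large ones.
#'
#' @param family per-phase contour list for the slice.
#' @param fields per-phase [DeformationField-class] list.
#' @param spacing (row, col) pixel spacing in mm.
#' @return per-phase strain in percent (phase 0 is 0).
#' @export
eulerianStrainCurve <- function(family, fields, spacing = c(1, 1)) {
  n <- length(fields)
  endo0 <- family[[1]]$endo
  epi0 <- family[[1]]$epi
  center <- endo0@center
  th <- polarAngles(length(endo0@radiusPx))
  rMid <- (endo0@radiusPx + epi0@radiusPx) / 2
  r0 <- center[1] + rMid * sin(th)
  c0 <- center[2] + rMid * cos(th)
  out <- numeric(n)
  acc <- 0
  for (t in seq_len(n - 1)) {
    inc <- incrementDisp(fields, t - 1)
    g <- dispGradient(inc$ur, inc$uc, spacing)
    exx <- g$dxx
    eyy <- g$dyy
    exy <- 0.5 * (g$dxy + g$dyx)
    # tracked material points at phase t-1
    rT <- r0 + .cs_sample_bilinear(fields[[t]]@forwardRow, r0, c0)
    cT <- c0 + .cs_sample_bilinear(fields[[t]]@forwardCol, r0, c0)
    dr <- rT - center[1]
    dc <- cT - center[2]
    rho <- pmax(sqrt(dr^2 + dc^2), 1e-12)
    rr <- dr / rho
    rc <- dc / rho
    eccInc <- rc^2 * .cs_sample_bilinear(exx, rT, cT) -
      2 * rr * rc * .cs_sample_bilinear(exy, rT, cT) +
      rr^2 * .cs_sample_bilinear(eyy, rT, cT)
    acc <- acc + mean(eccInc) * 100
    out[t + 1] <- acc
  }
  out
}
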